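# Independent oracles used by the test suite.  These deliberately avoid
# the package's code paths: the nick scan is a shifted-vector window
# comparison, and the alignment oracle enumerates every monotone pairing
# and scores it from the documented formula.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force sliding-window scan of both strands: position = 0-based
# window start; windows containing N never match
brute_nick_scan <- function(seq, motif = "GCTCTTC") {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(data.frame(position = integer(0),
                               strand = character(0)))
  x <- strsplit(seq, "")[[1]]
  hit_at <- function(pat) {
    p <- strsplit(pat, "")[[1]]
    ok <- rep(TRUE, n - m + 1)
    for (k in seq_len(m)) ok <- ok & x[k:(n - m + k)] == p[k]
    which(ok) - 1L
  }
  top <- hit_at(motif)
  bot <- hit_at(revcomp_chr(motif))
  out <- data.frame(position = c(top, bot),
                    strand = c(rep("top", length(top)),
                               rep("bottom", length(bot))),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

# plant a motif (top) or its reverse complement (bottom) at 0-based pos
plant_motif <- function(seq, pos, strand, motif = "GCTCTTC") {
  ins <- if (strand == "top") motif else revcomp_chr(motif)
  paste0(substr(seq, 1, pos), ins,
         substr(seq, pos + nchar(ins) + 1, nchar(seq)))
}

# score one monotone pairing exactly as documented for align_molecule():
# natural-log likelihood ratio against a random-genome label process
oracle_score_pairing <- function(u, L, v, R, tel0, i, j, par) {
  lam <- par$site_density
  cpb <- lam * (1 - par$extra_rate)
  miss_pen <- -log(par$miss_rate); extra_pen <- -log(par$extra_rate)
  t <- length(i)
  if (any(diff(i) - 1 > par$max_skip) || any(diff(j) - 1 > par$max_skip))
    return(-Inf)
  x <- diff(u[i]); y <- diff(v[j])
  sdv <- sqrt((par$rel_sd * y)^2 + par$sd_floor^2)
  z <- (x - y) / sdv
  S <- sum(log(1 - par$miss_rate) - log(sdv) - 0.5 * log(2 * pi) -
           pmin(z^2 / 2, par$sv_cap) - log(lam) -
           miss_pen * (diff(j) - 1) - extra_pen * (diff(i) - 1))
  # head
  off <- v[j[1]] - u[i[1]]
  S <- S - miss_pen * sum(v >= max(0, off) & v < v[j[1]])
  for (k in seq_len(i[1] - 1)) {
    w <- u[k] + off
    if (w >= 0) S <- S - extra_pen
    else if (tel0 && w >= -par$max_tract) S <- S - extra_pen
  }
  if (off < 0) {
    beyond <- if (tel0) max(0, -off - par$max_tract) else -off
    S <- S - cpb * beyond
  }
  # tail
  off2 <- v[j[t]] - u[i[t]]
  hi <- min(R, L + off2)
  S <- S - miss_pen * sum(v > v[j[t]] & v <= hi)
  if (i[t] < length(u)) for (k in (i[t] + 1):length(u)) {
    w <- u[k] + off2
    if (w <= R) S <- S - extra_pen
    else if (!tel0 && w <= R + par$max_tract) S <- S - extra_pen
  }
  if (L + off2 > R) {
    over <- L + off2 - R
    beyond <- if (tel0) over else max(0, over - par$max_tract)
    S <- S - cpb * beyond
  }
  S + cpb * L
}

# exhaustive maximum over all monotone pairings (>= 2 pairs), both
# orientations.  For speed, scoring is vectorized over all site
# combinations for a fixed label combination; the scalar scorer above is
# the readable reference and is cross-checked against this one in a test.
oracle_best_score <- function(labels, L, v, R, tel0, par) {
  lam <- par$site_density
  cpb <- lam * (1 - par$extra_rate)
  miss_pen <- -log(par$miss_rate); extra_pen <- -log(par$extra_rate)
  m <- length(v)
  nv_lt <- function(x) findInterval(x - 1e-9, v)   # #{v < x}
  nv_le <- function(x) findInterval(x, v)          # #{v <= x}
  best <- -Inf
  for (u in list(labels, L - rev(labels))) {
    n <- length(u)
    for (t in 2:min(n, m)) {
      ci <- utils::combn(n, t)
      cj <- utils::combn(m, t)
      okj <- apply(cj, 2, function(j) all(diff(j) - 1 <= par$max_skip))
      cj <- cj[, okj, drop = FALSE]
      if (!ncol(cj)) next
      VJ <- matrix(v[cj], nrow = t)
      y <- VJ[-1, , drop = FALSE] - VJ[-t, , drop = FALSE]
      sdv <- sqrt((par$rel_sd * y)^2 + par$sd_floor^2)
      miss_int <- colSums(matrix(cj[-1, , drop = FALSE] -
                                 cj[-t, , drop = FALSE] - 1, nrow = t - 1))
      for (a in seq_len(ncol(ci))) {
        i <- ci[, a]
        if (any(diff(i) - 1 > par$max_skip)) next
        x <- diff(u[i])
        z <- (x - y) / sdv
        S <- colSums((log(1 - par$miss_rate) - log(sdv) -
                      0.5 * log(2 * pi) - pmin(z^2 / 2, par$sv_cap) -
                      log(lam)) * 1) -
          miss_pen * miss_int - extra_pen * sum(diff(i) - 1)
        # head
        off <- VJ[1, ] - u[i[1]]
        S <- S - miss_pen * ((cj[1, ] - 1) - nv_lt(pmax(0, off)))
        if (i[1] > 1) for (k in seq_len(i[1] - 1)) {
          w <- u[k] + off
          chg <- w >= 0 | (tel0 & w >= -par$max_tract)
          S <- S - extra_pen * chg
        }
        beyond <- ifelse(off < 0,
                         if (tel0) pmax(0, -off - par$max_tract) else -off,
                         0)
        S <- S - cpb * beyond
        # tail
        off2 <- VJ[t, ] - u[i[t]]
        hi <- pmin(R, L + off2)
        S <- S - miss_pen * (nv_le(hi) - cj[t, ])
        if (i[t] < n) for (k in (i[t] + 1):n) {
          w <- u[k] + off2
          chg <- w <= R | (!tel0 & w <= R + par$max_tract)
          S <- S - extra_pen * chg
        }
        over <- pmax(0, L + off2 - R)
        beyond2 <- if (tel0) over else pmax(0, over - par$max_tract)
        S <- S - cpb * beyond2
        S <- S + cpb * L
        mx <- max(S)
        if (mx > best) best <- mx
      }
    }
  }
  best
}

# quick synthetic haplotype: sites at ~`spacing` with a telomere tract
synthetic_hap <- function(id, backbone_len = 400000, tract = 9000,
                          spacing = 9300, arm = "p", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gaps <- pmax(stats::rexp(ceiling(3 * backbone_len / spacing),
                           1 / spacing), 3000)
  s <- cumsum(gaps); s <- s[s < backbone_len - 100]
  if (arm == "p")
    haplotype_truth(id, tract + backbone_len, tract + s, tract, arm)
  else
    haplotype_truth(id, tract + backbone_len, backbone_len - s, tract,
                    arm)
}
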