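# Reference-anchored consensus maps, haplotype partitioning, SV calls and
# trio transmission checks.
#
# Label projection: each molecule's labels are carried into reference
# coordinates through its alignment, piecewise-linearly between matched
# pairs and with slope 1 beyond them, so overhanging labels (telomeric
# extension, gap content) land at consistent reference coordinates across
# molecules.  Projected positions are used for clustering; *sizes* of SV
# calls are always measured in the molecule metric (mean measured length
# between consensus sites), because interpolation erases size deltas.

# Project all oriented label positions (and the molecule span) of one
# aligned molecule into reference coordinates.  With a reference given,
# labels whose projected coordinate is unreliable are dropped from the
# `labels`/`oriented` output (kept in `all_labels`):
#  - end-segment labels extrapolated into the reference body (an unbridged
#    alignment, e.g. one that did not cross a large insertion, projects a
#    displaced stub there) or beyond the centromeric end; labels inside a
#    reference gap interval or beyond the telomeric end are genuine novel
#    content (gap fill, telomeric extension) and are kept;
#  - interior unmatched labels inside a large-residual (SV) interval,
#    whose interpolated coordinate is compressed and meaningless.
# The claimed span (used for site-presence voting) extends beyond the
# outermost matched pair only through reference-site-free territory (gap
# intervals, beyond the ends): an unlabeled end segment stops vouching at
# the first reference site it failed to match, so a molecule whose end is
# displaced (unbridged stub) or made of novel label-free DNA (tandem
# array, insertion) casts no false "absent" votes.
project_molecule <- function(mol, aln, ref = NULL, outlier_resid = 5000) {
  n <- length(mol$labels)
  fwd <- aln$orientation == "forward"
  u <- if (fwd) mol$labels else mol$length - rev(mol$labels)
  oi <- if (fwd) aln$pairs$label else n + 1L - aln$pairs$label
  p <- aln$pairs$label_pos_oriented
  v <- aln$pairs$site_pos
  k <- length(p)
  proj <- function(x) {
    ifelse(x <= p[1], v[1] - (p[1] - x),
      ifelse(x >= p[k], v[k] + (x - p[k]),
        stats::approx(p, v, xout = x, ties = "ordered")$y))
  }
  lab <- proj(u)
  keep <- rep(TRUE, n)
  span <- proj(c(0, mol$length))
  if (!is.null(ref) && n > 0) {
    tel0 <- ref_tel_at_start(ref)
    in_gap <- function(x) nrow(ref$gaps) > 0 &&
      any(x >= ref$gaps[, 1] & x < ref$gaps[, 2])
    matched <- seq_len(n) %in% oi
    resid <- aln$residuals$residual
    for (t in seq_len(n)) {
      if (matched[t]) next
      if (u[t] < p[1] || u[t] > p[k]) {           # extrapolated end label
        beyond_tel <- if (tel0) lab[t] < 0 else lab[t] > ref$length
        if (!beyond_tel && !in_gap(lab[t])) keep[t] <- FALSE
      } else if (k >= 2) {                        # interior unmatched
        seg <- findInterval(u[t], p)              # in (p[seg], p[seg+1])
        if (seg >= 1 && seg < k &&
            abs(resid[seg]) > outlier_resid) keep[t] <- FALSE
      }
    }
    if (any(!keep & u < p[1])) span[1] <- v[1]
    if (any(!keep & u > p[k])) span[2] <- v[k]
    before <- ref$sites[ref$sites < v[1] - 1]
    if (length(before)) span[1] <- max(span[1], max(before) + 1)
    after <- ref$sites[ref$sites > v[k] + 1]
    if (length(after)) span[2] <- min(span[2], min(after) - 1)
  }
  list(labels = lab[keep], oriented = u[keep], all_labels = lab,
       span = span)
}

# single-linkage 1-D clustering: split sorted positions at gaps > tol
cluster_1d <- function(pos, ids, tol) {
  o <- order(pos); pos <- pos[o]; ids <- ids[o]
  if (!length(pos)) return(list())
  grp <- cumsum(c(1, diff(pos) > tol))
  lapply(split(seq_along(pos), grp), function(i)
    list(center = mean(pos[i]), pos = pos[i], ids = ids[i],
         support = length(unique(ids[i]))))
}

#' Build a reference-anchored consensus map from aligned molecules
#'
#' Projects every molecule label into reference coordinates via its
#' alignment (overhanging labels included), clusters the projected
#' positions (1-D single linkage, tolerance `cluster_tol`), and retains
#' clusters supported by at least `min_support` molecules and
#' `min_support_frac` of the molecules spanning the position.  The
#' consensus extends beyond the reference ends where molecules do:
#' `extension_length` is the overshoot of the most distal retained site
#' beyond the telomeric reference end.
#'
#' @param alignments named list of `om_alignment` (e.g. from
#'   [align_molecules()]).
#' @param mols the `molecule_set` (or list of molecules) they came from.
#' @param ref the reference map.
#' @param cluster_tol bp tolerance for clustering projected labels;
#'   proportional to the sizing SD at typical inter-site spacing.  Default
#'   1500.
#' @param min_support minimum molecules per retained site.  Default 3.
#' @param min_support_frac minimum fraction of spanning molecules.  Default
#'   0.3 (tolerates the 10% label miss rate with margin).
#' @return an object of class `consensus_map`: `tel_id`, `haplotype`,
#'   `sites` (reference-coordinate positions, possibly negative or beyond
#'   the reference length), `support`, `spanning`, `interval_len` (mean
#'   measured molecule-metric length between consecutive sites),
#'   `extension_length`, `members`.
#' @export
build_consensus <- function(alignments, mols, ref, cluster_tol = 1500,
                            min_support = 3, min_support_frac = 0.3) {
  ml <- if (inherits(mols, "molecule_set")) mols$molecules else mols
  names(ml) <- vapply(ml, `[[`, character(1), "id")
  alignments <- Filter(is_alignment, alignments)
  if (length(alignments) < min_support) {
    out <- structure(list(tel_id = ref$id, haplotype = NA_character_,
                          sites = numeric(0), support = integer(0),
                          spanning = integer(0), interval_len = numeric(0),
                          extension_length = 0, members = character(0)),
                     class = "consensus_map")
    attr(out, "status") <- "no_consensus"
    return(out)
  }

  projs <- lapply(names(alignments), function(id)
    project_molecule(ml[[id]], alignments[[id]], ref))
  names(projs) <- names(alignments)
  pos <- unlist(lapply(projs, `[[`, "labels"))
  ids <- rep(names(projs),
             vapply(projs, function(p) length(p$labels), integer(1)))
  cl <- cluster_1d(pos, ids, cluster_tol)
  spans <- t(vapply(projs, `[[`, numeric(2), "span"))

  centers <- vapply(cl, `[[`, numeric(1), "center")
  support <- vapply(cl, `[[`, integer(1), "support")
  spanning <- vapply(centers, function(p)
    sum(spans[, 1] <= p - cluster_tol & spans[, 2] >= p + cluster_tol),
    integer(1))
  keep <- support >= min_support &
    support >= min_support_frac * pmax(spanning, 1)
  cl <- cl[keep]
  centers <- centers[keep]; support <- support[keep]
  spanning <- spanning[keep]

  # measured molecule-metric length between consecutive consensus sites
  interval_len <- numeric(max(0, length(cl) - 1))
  if (length(cl) >= 2) {
    for (k in seq_len(length(cl) - 1)) {
      vals <- measured_intervals(cl[[k]], cl[[k + 1]], projs, cluster_tol)
      interval_len[k] <- if (length(vals)) stats::median(vals)
                         else centers[k + 1] - centers[k]
    }
  }

  ext <- if (ref_tel_at_start(ref)) max(0, -min(centers, Inf))
         else max(0, max(centers, -Inf) - ref$length)
  if (!length(centers)) ext <- 0

  structure(list(tel_id = ref$id, haplotype = NA_character_,
                 sites = centers, support = support, spanning = spanning,
                 interval_len = interval_len, extension_length = ext,
                 members = names(alignments)),
            class = "consensus_map")
}

# molecule-metric distances between two clusters, over molecules with a
# label within tol of each cluster center (a molecule that missed one of
# the two labels cannot measure the interval)
measured_intervals <- function(cla, clb, projs, tol = 1500) {
  common <- intersect(unique(cla$ids), unique(clb$ids))
  out <- vapply(common, function(id) {
    pr <- projs[[id]]
    ia <- which.min(abs(pr$labels - cla$center))
    ib <- which.min(abs(pr$labels - clb$center))
    if (abs(pr$labels[ia] - cla$center) > tol ||
        abs(pr$labels[ib] - clb$center) > tol) return(NA_real_)
    abs(pr$oriented[ib] - pr$oriented[ia])
  }, numeric(1))
  out[!is.na(out)]
}

#' Partition aligned molecules into haplotype groups
#'
#' Candidate discriminant features are auto-proposed from bimodality:
#' a projected label cluster supported by 20--80% of spanning molecules
#' becomes a `site_presence` feature; a measured interval between two
#' well-supported consensus sites whose per-molecule lengths are bimodal
#' with modes separated by at least `min_mode_sep` becomes an
#' `interval_length` feature.  Molecules are assigned by majority vote over
#' their observed features (feature polarities aligned first); groups below
#' `min_members` are discarded.  One group = homozygous, two =
#' heterozygous.
#'
#' @inheritParams build_consensus
#' @param min_members minimum molecules per haplotype group.  Default 5.
#' @param presence_range support-fraction window calling a site
#'   heterozygous.  Default `c(0.2, 0.8)`, symmetric around 50% and robust
#'   to the 10% FN/FP label rates.
#' @param min_mode_sep minimum separation of interval-length modes, bp.
#'   Default 10000.
#' @param fn_rate assumed label false-negative rate.  A candidate
#'   heterozygous site must be missing from more molecules than the FN
#'   rate can plausibly explain (binomial tail < 0.005), so ordinary sites
#'   with an unlucky run of missed labels do not masquerade as haplotype
#'   features.  Default 0.1, the platform rate.
#' @return list of `haplotype_group` objects: `haplotype` (id), `features`
#'   (data frame), `members`, `consensus` (a [build_consensus()] map for
#'   the group), `warning` (TRUE when molecule feature vectors conflict
#'   beyond error-rate expectation).
#' @export
cluster_haplotypes <- function(alignments, mols, ref, min_members = 5,
                               presence_range = c(0.2, 0.8),
                               min_mode_sep = 10000, cluster_tol = 1500,
                               min_support = 3, min_support_frac = 0.3,
                               fn_rate = 0.1) {
  ml <- if (inherits(mols, "molecule_set")) mols$molecules else mols
  names(ml) <- vapply(ml, `[[`, character(1), "id")
  alignments <- Filter(is_alignment, alignments)
  if (!length(alignments)) return(list())
  mids <- names(alignments)
  one_group <- function() {
    cons <- build_consensus(alignments, ml, ref, cluster_tol,
                            min_support, min_support_frac)
    cons$haplotype <- "1"
    list(structure(list(haplotype = "1",
                        features = empty_features(), members = mids,
                        consensus = cons, warning = FALSE),
                   class = "haplotype_group"))
  }
  if (length(alignments) < 2 * min_members) return(one_group())

  projs <- lapply(mids, function(id)
    project_molecule(ml[[id]], alignments[[id]], ref))
  names(projs) <- mids
  pos <- unlist(lapply(projs, `[[`, "labels"))
  ids <- rep(mids, vapply(projs, function(p) length(p$labels), integer(1)))
  cl <- cluster_1d(pos, ids, cluster_tol)
  spans <- t(vapply(projs, `[[`, numeric(2), "span"))

  centers <- vapply(cl, `[[`, numeric(1), "center")
  support <- vapply(cl, `[[`, integer(1), "support")
  spanning <- vapply(centers, function(p)
    sum(spans[, 1] <= p - cluster_tol & spans[, 2] >= p + cluster_tol),
    integer(1))

  feats <- list()   # each: list(type, position/ref interval, assign fn data)

  # site-presence candidates: het-like support fraction, too many absences
  # for the label miss rate alone to explain, and within the reference
  # body (projections beyond the ends are extrapolated over the telomere
  # tract and unreliable; gap intervals are inside [0, length) and remain
  # eligible)
  het <- which(spanning >= 2 * min_members &
               centers >= 0 & centers <= ref$length &
               support / spanning >= presence_range[1] &
               support / spanning <= presence_range[2] &
               stats::pbinom(support, spanning, 1 - fn_rate) < 0.005)
  for (k in het) {
    p <- centers[k]
    has <- vapply(projs, function(pr)
      length(pr$labels) > 0 && min(abs(pr$labels - p)) <= cluster_tol,
      logical(1))
    obs <- ifelse(spans[, 1] <= p - cluster_tol &
                  spans[, 2] >= p + cluster_tol, has, NA)
    feats[[length(feats) + 1]] <- list(
      type = "site_presence", position = p, modes = c(0, 1),
      weight = 3, obs = as.numeric(obs))
  }

  # interval-length candidates.  Bimodality is detected per interval
  # between consecutive confident sites; each candidate region is then
  # expanded by one confident site on either side before the feature is
  # measured, so the value is insensitive to which interval a particular
  # alignment placed the size residual in (a spurious label near an SV
  # can shift it by one interval).  Overlapping candidates merge.
  conf <- which(support >= 0.8 * spanning & support >= min_members)
  if (length(conf) >= 2) {
    cand <- list()
    for (t in seq_len(length(conf) - 1)) {
      vals <- measured_intervals(cl[[conf[t]]], cl[[conf[t + 1]]], projs,
                                 cluster_tol)
      if (length(vals) < 2 * min_members) next
      if (!is.null(split_bimodal(vals, min_members, min_mode_sep)))
        cand[[length(cand) + 1]] <- c(t, t + 1)
    }
    if (length(cand)) {
      ranges <- do.call(rbind, cand)
      ranges <- ranges[order(ranges[, 1]), , drop = FALSE]
      merged <- list(); cur <- ranges[1, ]
      for (r in seq_len(nrow(ranges))[-1]) {
        if (ranges[r, 1] <= cur[2]) cur[2] <- max(cur[2], ranges[r, 2])
        else { merged[[length(merged) + 1]] <- cur; cur <- ranges[r, ] }
      }
      merged[[length(merged) + 1]] <- cur
      for (rg in merged) {
        for (expand in c(1, 0)) {
          a <- conf[max(1, rg[1] - expand)]
          b <- conf[min(length(conf), rg[2] + expand)]
          vals <- measured_intervals(cl[[a]], cl[[b]], projs, cluster_tol)
          if (length(vals) < 2 * min_members) next
          sp <- split_bimodal(vals, min_members, min_mode_sep)
          if (is.null(sp)) next
          common <- intersect(unique(cl[[a]]$ids), unique(cl[[b]]$ids))
          obs <- rep(NA_real_, length(mids))
          obs[match(common, mids)] <- as.numeric(vals > sp$cut)
          feats[[length(feats) + 1]] <- list(
            type = "interval_length",
            position = centers[a], position_end = centers[b],
            modes = sp$modes, weight = min(sp$quality, 10), obs = obs)
          break
        }
      }
    }
  }

  if (!length(feats)) return(one_group())

  # align feature polarities to the most-observed feature, then majority vote
  F <- do.call(cbind, lapply(feats, `[[`, "obs"))
  nobs <- colSums(!is.na(F))
  refc <- which.max(nobs)
  for (j in seq_len(ncol(F))) {
    if (j == refc) next
    both <- !is.na(F[, j]) & !is.na(F[, refc])
    if (sum(both) >= 3 && mean(F[both, j] == F[both, refc]) < 0.5) {
      F[, j] <- 1 - F[, j]
      feats[[j]]$modes <- rev(feats[[j]]$modes)
      feats[[j]]$flipped <- TRUE
    }
  }
  # quality-weighted majority vote; features that disagree with the
  # resulting partition beyond error-rate expectation are spurious (e.g. a
  # noisy cluster that slipped through the candidate filters) and are
  # pruned
  W <- vapply(feats, `[[`, numeric(1), "weight")
  repeat {
    WM <- matrix(W, nrow(F), ncol(F), byrow = TRUE)
    WM[is.na(F)] <- 0
    vote <- rowSums(WM * F, na.rm = TRUE) / rowSums(WM)
    assign <- ifelse(is.nan(vote), NA, as.integer(vote > 0.5))
    if (ncol(F) == 1) break
    agree <- vapply(seq_len(ncol(F)), function(j) {
      ok <- !is.na(F[, j]) & !is.na(assign)
      if (!sum(ok)) return(1)
      mean(F[ok, j] == assign[ok])
    }, numeric(1))
    if (min(agree) >= 0.7) break
    worst <- which.min(agree)
    F <- F[, -worst, drop = FALSE]
    feats <- feats[-worst]
    W <- W[-worst]
  }
  conflict <- rowMeans(F != ifelse(is.na(assign), NA, assign), na.rm = TRUE)

  groups <- list()
  for (g in 0:1) {
    sel <- which(!is.na(assign) & assign == g)
    if (length(sel) < min_members) next
    gids <- mids[sel]
    cons <- build_consensus(alignments[gids], ml, ref, cluster_tol,
                            min_support, min_support_frac)
    fdf <- data.frame(
      type = vapply(feats, `[[`, character(1), "type"),
      position = vapply(feats, `[[`, numeric(1), "position"),
      value = vapply(feats, function(f) f$modes[g + 1], numeric(1)))
    groups[[length(groups) + 1]] <- structure(
      list(haplotype = NA_character_, features = fdf, members = gids,
           consensus = cons,
           warning = mean(conflict[sel], na.rm = TRUE) > 0.3),
      class = "haplotype_group")
  }
  if (!length(groups)) return(one_group())
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  groups <- groups[order(-sizes)]
  for (i in seq_along(groups)) {
    groups[[i]]$haplotype <- as.character(i)
    groups[[i]]$consensus$haplotype <- as.character(i)
  }
  groups
}

empty_features <- function()
  data.frame(type = character(0), position = numeric(0), value = numeric(0))

# largest-gap split of 1-D values into two modes; NULL when not bimodal.
# `quality` is the inter-mode gap over the pooled within-mode SD: a crisp
# biological size difference scores high, a split polluted by alignment
# path variation scores low.
split_bimodal <- function(x, min_members, min_sep) {
  xs <- sort(x)
  n <- length(xs)
  lo <- min_members; hi <- n - min_members
  if (lo > hi) return(NULL)
  gaps <- diff(xs)
  k <- lo - 1 + which.max(gaps[lo:hi])
  m1 <- mean(xs[1:k]); m2 <- mean(xs[(k + 1):n])
  if (m2 - m1 < min_sep) return(NULL)
  pooled <- sqrt((sum((xs[1:k] - m1)^2) + sum((xs[(k + 1):n] - m2)^2)) /
                 max(1, n - 2))
  list(cut = (xs[k] + xs[k + 1]) / 2, modes = c(m1, m2),
       quality = (xs[k + 1] - xs[k]) / (pooled + 1))
}

#' Call structural variants from a consensus map
#'
#' Compares a consensus map against the reference: anchor sites are
#' mutual-nearest consensus/reference site pairs within `match_tol`;
#' between consecutive anchors, the measured molecule-metric span minus the
#' reference span, when at least `min_size` in magnitude, is called as an
#' insertion (positive) or deletion (negative).  Consensus sites inside
#' reference gap intervals become `gap_fill` calls with their delineated
#' extent, and a positive telomeric extension becomes a `distal_extension`
#' call.  Codes follow the field's tabulation: `g` for gap-related calls,
#' `sv` for large insertions/deletions; [annotate_haplotype_codes()] adds
#' `h` where calls differ between haplotype groups.
#'
#' @param consensus a `consensus_map`.
#' @param ref the reference map.
#' @param min_size minimum insertion/deletion size, bp.  Default 20000
#'   (large-SV convention).
#' @param match_tol anchor matching tolerance, bp.  Default 3000.
#' @return data frame of class `sv_calls`: `tel_id`, `type`, `position`,
#'   `size`, `haplotype`, `support`, `code`.
#' @export
call_svs <- function(consensus, ref, min_size = 20000, match_tol = 3000) {
  stopifnot(inherits(consensus, "consensus_map"),
            inherits(ref, "reference_map"))
  rows <- list()
  cs <- consensus$sites
  vs <- ref$sites
  if (length(cs) >= 2 && length(vs) >= 1) {
    near_r <- vapply(cs, function(p) which.min(abs(vs - p)), integer(1))
    near_c <- vapply(vs, function(p) which.min(abs(cs - p)), integer(1))
    anchor <- which(abs(vs[near_r] - cs) <= match_tol &
                    near_c[near_r] == seq_along(cs))
    if (length(anchor) >= 2) {
      for (t in seq_len(length(anchor) - 1)) {
        i <- anchor[t]; j <- anchor[t + 1]
        measured <- sum(consensus$interval_len[i:(j - 1)])
        refspan <- vs[near_r[j]] - vs[near_r[i]]
        delta <- measured - refspan
        if (abs(delta) >= min_size) {
          rows[[length(rows) + 1]] <- data.frame(
            tel_id = consensus$tel_id,
            type = if (delta > 0) "insertion" else "deletion",
            position = vs[near_r[i]], size = abs(delta),
            haplotype = consensus$haplotype,
            support = min(consensus$support[c(i, j)]), code = "sv",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (nrow(ref$gaps)) {
    for (g in seq_len(nrow(ref$gaps))) {
      inside <- cs[cs >= ref$gaps[g, 1] & cs < ref$gaps[g, 2]]
      if (length(inside)) {
        rows[[length(rows) + 1]] <- data.frame(
          tel_id = consensus$tel_id, type = "gap_fill",
          position = ref$gaps[g, 1], size = diff(range(inside)),
          haplotype = consensus$haplotype,
          support = min(consensus$support[match(inside, cs)]),
          code = "g", stringsAsFactors = FALSE)
      }
    }
  }
  if (consensus$extension_length > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      tel_id = consensus$tel_id, type = "distal_extension",
      position = if (ref_tel_at_start(ref)) 0 else ref$length,
      size = consensus$extension_length,
      haplotype = consensus$haplotype,
      support = if (length(consensus$support)) consensus$support[
        if (ref_tel_at_start(ref)) 1 else length(consensus$support)] else 0L,
      code = "g", stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tel_id = character(0), type = character(0),
               position = numeric(0), size = numeric(0),
               haplotype = character(0), support = integer(0),
               code = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("sv_calls", "data.frame"))
}

#' Mark haplotype-specific SV calls
#'
#' Combines per-haplotype-group call sets; a call absent from any other
#' group (no call of the same type within `pos_tol` and within 2x in size)
#' gets `h` prefixed to its code (`h+sv`, `h+g`).
#'
#' @param group_calls list of `sv_calls` data frames, one per haplotype
#'   group.
#' @param pos_tol positional matching tolerance, bp.  Default 15000.
#' @return combined `sv_calls` data frame.
#' @export
annotate_haplotype_codes <- function(group_calls, pos_tol = 15000) {
  if (length(group_calls) >= 2) {
    for (g in seq_along(group_calls)) {
      calls <- group_calls[[g]]
      if (!nrow(calls)) next
      for (r in seq_len(nrow(calls))) {
        shared <- vapply(group_calls[-g], function(other) {
          any(other$type == calls$type[r] &
              abs(other$position - calls$position[r]) <= pos_tol &
              abs(other$size - calls$size[r]) <=
                pmax(10000, 0.2 * calls$size[r]))
        }, logical(1))
        if (!all(shared))
          calls$code[r] <- paste0("h+", calls$code[r])
      }
      group_calls[[g]] <- calls
    }
  }
  out <- do.call(rbind, group_calls)
  if (is.null(out))
    out <- data.frame(tel_id = character(0), type = character(0),
                      position = numeric(0), size = numeric(0),
                      haplotype = character(0), support = integer(0),
                      code = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("sv_calls", "data.frame"))
}

# monotone two-pointer matching of two sorted site lists within tol;
# returns index pairs
match_sites <- function(a, b, tol) {
  i <- 1; j <- 1; ia <- integer(0); ib <- integer(0)
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tol) { ia <- c(ia, i); ib <- c(ib, j); i <- i + 1; j <- j + 1 }
    else if (d < 0) i <- i + 1
    else j <- j + 1
  }
  cbind(ia, ib)
}

# Discordance between two consensus maps, restricted to their common
# extent: each unmatched site counts 1, and each pair of consecutive
# matched sites whose measured (molecule-metric) spans differ by more than
# max(int_tol, 10%) counts 1.  Site positions alone cannot distinguish
# insertion/array haplotypes — their novel content is label-free or
# projected onto reference coordinates — so the interval term carries the
# size differences.  `shared` is the classical shared-site fraction over
# the common extent.
map_discordance <- function(A, B, tol = 3000, int_tol = 6000) {
  a <- A$sites; b <- B$sites
  if (!length(a) || !length(b))
    return(list(discordance = Inf, shared = 0))
  lo <- max(min(a), min(b)); hi <- min(max(a), max(b))
  ka <- which(a >= lo - tol & a <= hi + tol)
  kb <- which(b >= lo - tol & b <= hi + tol)
  m <- match_sites(a[ka], b[kb], tol)
  disc <- (length(ka) - nrow(m)) + (length(kb) - nrow(m))
  if (nrow(m) >= 2) {
    for (t in seq_len(nrow(m) - 1)) {
      ia <- ka[m[t, 1]]:(ka[m[t + 1, 1]] - 1)
      ib <- kb[m[t, 2]]:(kb[m[t + 1, 2]] - 1)
      la <- sum(A$interval_len[ia]); lb <- sum(B$interval_len[ib])
      if (abs(la - lb) > max(int_tol, 0.1 * max(la, lb)))
        disc <- disc + 1
    }
  }
  shared <- if (length(ka) + length(kb) > 0)
    2 * nrow(m) / (length(ka) + length(kb)) else 0
  list(discordance = disc, shared = shared)
}

#' Check trio inheritance of haplotype groups
#'
#' Matches each child haplotype to the parental haplotype with the most
#' similar consensus map, under the Mendelian constraint that one child
#' haplotype comes from each parent.  Similarity combines shared sites
#' (within `match_tol`) with agreement of the measured molecule-metric
#' interval lengths, so insertion/array haplotypes — whose site
#' *positions* look reference-like — are still told apart.  Inconsistency
#' is flagged when the best parental match still leaves more than
#' `max_discordance` discordant sites/intervals or shares fewer than
#' `min_shared` of its sites.
#'
#' @param child,parent1,parent2 lists of `haplotype_group` (or
#'   `consensus_map`) objects, 1--2 per individual.
#' @param match_tol site matching tolerance, bp.  Default 3000.
#' @param min_shared minimum shared-site fraction for a valid match.
#'   Default 0.8.
#' @param max_discordance maximum discordant sites/intervals for a valid
#'   match.  Default 1 (one consensus artifact tolerated).
#' @return list with `assignment` (data frame: child_hap, parent,
#'   parent_hap, shared, discordance), `consistent`, `ambiguous` (TRUE
#'   when an alternative assignment fits equally well, e.g. parents
#'   homozygous for the same allele).
#' @export
trio_consistency <- function(child, parent1, parent2, match_tol = 3000,
                             min_shared = 0.8, max_discordance = 1) {
  get_cons <- function(g)
    if (inherits(g, "haplotype_group")) g$consensus else g
  cs <- lapply(child, get_cons)
  ps <- list(parent1 = lapply(parent1, get_cons),
             parent2 = lapply(parent2, get_cons))
  stopifnot(length(cs) >= 1, length(cs) <= 2)

  best_in <- function(cons, parent) {
    d <- lapply(ps[[parent]], map_discordance, A = cons, tol = match_tol)
    disc <- vapply(d, `[[`, numeric(1), "discordance")
    k <- which.min(disc)
    list(hap = k, discordance = disc[k], shared = d[[k]]$shared,
         tie = sum(disc <= disc[k]) > 1)
  }

  if (length(cs) == 2) {
    oA <- list(best_in(cs[[1]], "parent1"), best_in(cs[[2]], "parent2"))
    oB <- list(best_in(cs[[1]], "parent2"), best_in(cs[[2]], "parent1"))
    dA <- oA[[1]]$discordance + oA[[2]]$discordance
    dB <- oB[[1]]$discordance + oB[[2]]$discordance
    use_A <- dA <= dB
    o <- if (use_A) oA else oB
    parents <- if (use_A) c("parent1", "parent2") else c("parent2", "parent1")
    assignment <- data.frame(
      child_hap = c(1, 2), parent = parents,
      parent_hap = vapply(o, `[[`, integer(1), "hap"),
      shared = vapply(o, `[[`, numeric(1), "shared"),
      discordance = vapply(o, `[[`, numeric(1), "discordance"),
      stringsAsFactors = FALSE)
    ambiguous <- dA == dB || any(vapply(o, `[[`, logical(1), "tie"))
  } else {
    o <- list(best_in(cs[[1]], "parent1"), best_in(cs[[1]], "parent2"))
    assignment <- data.frame(
      child_hap = c(1, 1), parent = c("parent1", "parent2"),
      parent_hap = vapply(o, `[[`, integer(1), "hap"),
      shared = vapply(o, `[[`, numeric(1), "shared"),
      discordance = vapply(o, `[[`, numeric(1), "discordance"),
      stringsAsFactors = FALSE)
    ambiguous <- any(vapply(o, `[[`, logical(1), "tie"))
  }
  consistent <- all(assignment$shared >= min_shared &
                    assignment$discordance <= max_discordance)
  list(assignment = assignment, consistent = consistent,
       ambiguous = ambiguous)
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf(
    "consensus_map %s (hap %s): %d sites from %d molecules, extension %.0f bp\n",
    x$tel_id, x$haplotype, length(x$sites), length(x$members),
    x$extension_length))
  invisible(x)
}

#' @export
print.haplotype_group <- function(x, ...) {
  cat(sprintf("haplotype_group %s: %d molecules, %d feature(s)%s\n",
              x$haplotype, length(x$members), nrow(x$features),
              if (isTRUE(x$warning)) " [conflicting features]" else ""))
  invisible(x)
}
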