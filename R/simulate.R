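# Synthetic diploid subtelomeres and nick-labeled single molecules.
#
# Sequence-level construction: a subtelomere is a terminal (TTAGGG)n tract
# (motif-free by construction), followed by segmentally duplicated SRE
# blocks (shared across subtelomeres via a deterministic block registry) and
# a 1-copy region.  Haplotype variants are realized as sequence edits.
# Molecule-level simulation then needs only the haplotype truth (length +
# true site positions), never the sequence itself.

# evaluate expr with a temporary RNG stream, restoring the caller's stream
with_preserved_rng <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic 31-bit hash of an identifier
hash_id <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

BASES <- c("A", "C", "G", "T")

# random sequence with all motif occurrences (both strands) destroyed
random_seq_nomotif <- function(len, motif) {
  x <- sample(BASES, len, replace = TRUE)
  if (len < nchar(motif)) return(x)
  mid <- (nchar(motif) + 1L) %/% 2L
  for (pass in 1:10) {
    s <- paste(x, collapse = "")
    occ <- in_silico_nick(s, motif)$position
    if (!length(occ)) break
    for (p in occ) {
      i <- p + mid
      x[i] <- sample(setdiff(BASES, x[i]), 1)
    }
  }
  x
}

# random sequence with nick motifs planted at ~exponential spacing (mean
# `spacing` bp, random strand); spacing = Inf gives a motif-free sequence.
# Planted sites keep a minimum separation (default 3 kb): nanochannel
# imaging cannot resolve closer labels, and it keeps backbones free of
# accidental inverted nick pairs — INP breakage scenarios plant their loci
# deliberately via haplotype_truth(inp_positions =).
random_labeled_seq <- function(len, spacing, motif = "GCTCTTC",
                               min_sep = 3000) {
  x <- random_seq_nomotif(len, motif)
  if (is.finite(spacing) && len > nchar(motif) + 10) {
    pos <- cumsum(stats::rexp(ceiling(3 * len / spacing) + 5, 1 / spacing))
    pos <- floor(pos[pos < len - nchar(motif) - 1])
    pos <- pos[c(TRUE, diff(pos) > max(min_sep, 3 * nchar(motif)))]
    rcm <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    for (p in pos) {
      ins <- if (stats::runif(1) < 0.5) motif else rcm
      x[(p + 1):(p + nchar(ins))] <- strsplit(ins, "")[[1]]
    }
  }
  paste(x, collapse = "")
}

# registry-backed deterministic sequence for a named element (SRE blocks,
# insertion alleles, tandem-array units shared across specs/individuals)
block_seq <- function(id, len, spacing, motif = "GCTCTTC") {
  with_preserved_rng(hash_id(id), random_labeled_seq(len, spacing, motif))
}

telomere_tract <- function(len) {
  if (len <= 0) return("")
  substr(strrep("TTAGGG", ceiling(len / 6)), 1, len)
}

#' Specify a synthetic diploid subtelomere
#'
#' Describes the architecture from which [build_diploid_subtelomere()]
#' realizes sequences: per-haplotype telomere tract lengths, an ordered
#' layout of SRE paralogy blocks (block ids are shared across specs, so two
#' subtelomeres listing the same block id receive identical sequence —
#' segmental duplication), a 1-copy region, and per-haplotype variant edits.
#'
#' @param id telomere identifier (e.g. `"15q"`).
#' @param arm `"p"` or `"q"`.
#' @param tract length-2 numeric: (TTAGGG)n tract length per haplotype, bp.
#' @param blocks `data.frame(block, length)` shared by both haplotypes, or a
#'   list of two such data frames for haplotype-specific SRE layouts.
#'   Default: three 40 kb blocks `sre_a`, `sre_b`, `sre_c`.
#' @param one_copy_length length of the unique (non-duplicated) region
#'   centromeric of the SREs, bp.  Default 150000.
#' @param edits list with elements `h1` and/or `h2`; each a list of edits:
#'   `list(type = "insertion", position =, size =, ins_id =)`,
#'   `list(type = "deletion", position =, size =)`,
#'   `list(type = "nick_site_loss", position =)`,
#'   `list(type = "tandem_array", position =, unit_length =, copies =,
#'   unit_id =)`.  Positions are bp offsets into the (unedited) backbone,
#'   i.e. 0 = centromeric end of the telomere tract.  `ins_id`/`unit_id`
#'   key the inserted sequence in the shared registry, so the same allele
#'   can recur across individuals (e.g. in a trio).
#' @param site_spacing mean spacing of planted nick sites, bp.  Default
#'   9300, the genome-average Nt.BspQI site density.
#' @param ref_gaps gap intervals (backbone bp) masked in the *reference*
#'   map only: the haplotype sequences have real (site-bearing) content
#'   there, emulating an NNN assembly gap.
#' @param distal_unrepresented bp of telomere-adjacent backbone absent from
#'   the reference (the reference starts this many bp centromeric of the
#'   true tract start).
#' @param distal_offset_known if FALSE the reference map's `distal_offset`
#'   is recorded as unknown, so telomere estimates are flagged as
#'   gap-haplotype overestimates.
#' @param inp_max_gap max bp separation for inverted-nick-pair detection.
#' @param seed construction seed.
#' @return an object of class `subtelomere_spec`.
#' @export
subtelomere_spec <- function(id, arm = c("p", "q"),
                             tract = c(9000, 9000), blocks = NULL,
                             one_copy_length = 150000, edits = list(),
                             site_spacing = 9300, ref_gaps = NULL,
                             distal_unrepresented = 0,
                             distal_offset_known = TRUE,
                             inp_max_gap = 1000, seed = 1) {
  arm <- match.arg(arm)
  stopifnot(length(tract) == 2, all(tract >= 0), one_copy_length > 0,
            site_spacing > 0, distal_unrepresented >= 0)
  if (is.null(blocks))
    blocks <- data.frame(block = c("sre_a", "sre_b", "sre_c"),
                         length = c(40000, 40000, 40000),
                         stringsAsFactors = FALSE)
  if (is.data.frame(blocks)) blocks <- list(blocks, blocks)
  stopifnot(length(blocks) == 2)
  for (h in 1:2) {
    for (e in edits[[paste0("h", h)]]) {
      if (!e$type %in% c("insertion", "deletion", "nick_site_loss",
                         "tandem_array"))
        stop("unknown edit type: ", e$type)
      if (is.null(e$position) || e$position < 0)
        stop("edit positions must be non-negative")
    }
  }
  structure(list(id = id, arm = arm, tract = as.numeric(tract),
                 blocks = blocks, one_copy_length = one_copy_length,
                 edits = edits, site_spacing = site_spacing,
                 ref_gaps = ref_gaps,
                 distal_unrepresented = distal_unrepresented,
                 distal_offset_known = distal_offset_known,
                 inp_max_gap = inp_max_gap, seed = as.integer(seed)),
            class = "subtelomere_spec")
}

#' Haplotype truth for molecule simulation
#'
#' Minimal description of one haplotype as the simulator sees it: total
#' length, true (strand-collapsed) nick-site positions, telomere tract
#' length and INP breakage loci.  [build_diploid_subtelomere()] produces
#' these from sequence; they can equally be constructed arithmetically for
#' controlled experiments.
#'
#' @param id haplotype identifier.
#' @param length total haplotype length (tract included), bp.
#' @param sites true site positions in haplotype coordinates, bp.
#' @param tract_length (TTAGGG)n tract length, bp; the tract sits at the
#'   telomeric end (coordinate 0 for p-arms, `length` for q-arms).
#' @param arm `"p"` or `"q"`.
#' @param inp_positions positions of inverted-nick-pair break loci, bp.
#' @return an object of class `telo_haplotype`.
#' @export
haplotype_truth <- function(id, length, sites, tract_length = 0,
                            arm = c("p", "q"),
                            inp_positions = numeric(0)) {
  arm <- match.arg(arm)
  sites <- sort(unique(as.numeric(sites)))
  stopifnot(length > 0, tract_length >= 0, tract_length <= length,
            all(sites >= 0 & sites < length))
  structure(list(id = id, length = as.numeric(length), sites = sites,
                 tract_length = as.numeric(tract_length), arm = arm,
                 inp_positions = as.numeric(inp_positions)),
            class = "telo_haplotype")
}

# apply one edit to a backbone string; returns the edited string
apply_edit <- function(seq, e, spec, hap, motif) {
  pos <- e$position
  if (pos > nchar(seq)) stop("edit position beyond sequence end")
  if (e$type == "insertion") {
    key <- if (!is.null(e$ins_id)) e$ins_id else
      paste(spec$id, hap, "ins", pos, sep = ":")
    ins <- block_seq(paste0("ins:", key), e$size, spec$site_spacing, motif)
    paste0(substr(seq, 1, pos), ins, substr(seq, pos + 1, nchar(seq)))
  } else if (e$type == "deletion") {
    if (pos + e$size > nchar(seq)) stop("deletion extends beyond sequence")
    paste0(substr(seq, 1, pos), substr(seq, pos + e$size + 1, nchar(seq)))
  } else if (e$type == "tandem_array") {
    key <- if (!is.null(e$unit_id)) e$unit_id else
      paste(spec$id, "unit", pos, sep = ":")
    unit <- block_seq(paste0("unit:", key), e$unit_length, Inf, motif)
    paste0(substr(seq, 1, pos), strrep(unit, e$copies),
           substr(seq, pos + 1, nchar(seq)))
  } else if (e$type == "nick_site_loss") {
    lo <- max(0, pos - 10000); hi <- min(nchar(seq), pos + 10000)
    win <- substr(seq, lo + 1, hi)
    occ <- in_silico_nick(win, motif)
    if (!nrow(occ)) stop("no nick site within 10 kb of position ", pos)
    p <- occ$position[which.min(abs(occ$position + lo - pos))] + lo
    mid <- p + (nchar(motif) + 1L) %/% 2L  # middle base, 0-based window
    swap <- c(A = "C", C = "A", G = "T", T = "G")
    for (repl in c(swap[substr(seq, mid + 1, mid + 1)], BASES)) {
      if (repl == substr(seq, mid + 1, mid + 1)) next
      cand <- seq
      substr(cand, mid + 1, mid + 1) <- repl
      chk <- in_silico_nick(substr(cand, p + 1 - 10, p + 20), motif)
      if (!nrow(chk)) return(cand)
    }
    stop("could not disrupt nick site at ", p)
  } else stop("unknown edit type ", e$type)
}

#' Realize a diploid subtelomere from a spec
#'
#' Builds the two haplotype sequences (telomere tract + SRE blocks + 1-copy
#' region, with per-haplotype edits), the truth maps used by
#' [simulate_molecules()], and the *reference* nick map that molecules are
#' aligned against (the unedited backbone, with any `ref_gaps` masked and
#' any `distal_unrepresented` bp trimmed from the telomeric end).
#'
#' @param spec a [subtelomere_spec()].
#' @param motif nicking motif; default `"GCTCTTC"`.
#' @return a list of class `diploid_subtelomere` with elements `spec`,
#'   `reference` (a [build_reference_map()] object), `reference_sequence`,
#'   and `haplotypes`: per haplotype a list `(hap, sequence, truth, map)`
#'   where `truth` is a [haplotype_truth()] and `map` the nick map of the
#'   edited backbone in backbone coordinates.
#' @export
build_diploid_subtelomere <- function(spec, motif = "GCTCTTC") {
  stopifnot(inherits(spec, "subtelomere_spec"))
  set.seed(spec$seed)

  backbones <- lapply(1:2, function(h) {
    b <- spec$blocks[[h]]
    parts <- mapply(function(id, len)
      block_seq(paste0("block:", id), len, spec$site_spacing, motif),
      b$block, b$length)
    paste0(paste(parts, collapse = ""),
           block_seq(paste0(spec$id, ":onecopy"), spec$one_copy_length,
                     spec$site_spacing, motif))
  })
  ref_backbone <- backbones[[1]]

  haplotypes <- lapply(1:2, function(h) {
    seq <- backbones[[h]]
    ed <- spec$edits[[paste0("h", h)]]
    if (!is.null(ed)) {
      ord <- order(vapply(ed, `[[`, numeric(1), "position"),
                   decreasing = TRUE)
      for (e in ed[ord]) seq <- apply_edit(seq, e, spec, h, motif)
    }
    full <- paste0(telomere_tract(spec$tract[h]), seq)
    if (spec$arm == "q")
      full <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(full)))
    stranded <- in_silico_nick(full, motif)
    inp <- detect_inp(stranded, spec$inp_max_gap)
    truth <- haplotype_truth(
      id = paste0(spec$id, ".h", h), length = nchar(full),
      sites = unique(stranded$position),
      tract_length = spec$tract[h], arm = spec$arm,
      inp_positions = (inp$left_position + inp$right_position) / 2)
    bb <- if (spec$arm == "q")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    else seq
    map <- build_reference_map(paste0(spec$id, ".h", h), sequence = bb,
                               arm = spec$arm, motif = motif)
    list(hap = h, sequence = full, truth = truth, map = map)
  })

  d <- spec$distal_unrepresented
  ref_seq <- if (d > 0) substr(ref_backbone, d + 1, nchar(ref_backbone))
             else ref_backbone
  gaps <- spec$ref_gaps
  if (!is.null(gaps) && d > 0)
    gaps <- lapply(gaps, function(g) pmax(g - d, 0))
  if (spec$arm == "q") {
    ref_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref_seq)))
    if (!is.null(gaps)) {
      L <- nchar(ref_seq)
      gaps <- lapply(gaps, function(g) c(L - g[2], L - g[1]))
    }
  }
  reference <- build_reference_map(
    spec$id, sequence = ref_seq, arm = spec$arm, gaps = gaps,
    distal_offset = if (spec$distal_offset_known) d else NA,
    motif = motif)

  structure(list(spec = spec, motif = motif, reference = reference,
                 reference_sequence = ref_seq, haplotypes = haplotypes),
            class = "diploid_subtelomere")
}

#' Construct a single molecule
#'
#' @param id molecule identifier.
#' @param length molecule length, bp.
#' @param labels ordered label positions in molecule coordinates, bp
#'   (strictly increasing, in `[0, length)`).
#' @return an object of class `molecule`.
#' @export
molecule <- function(id, length, labels = numeric(0)) {
  labels <- as.numeric(labels)
  stopifnot(length > 0, all(labels >= 0), all(labels < length),
            !is.unsorted(labels, strictly = TRUE))
  structure(list(id = as.character(id), length = as.numeric(length),
                 labels = labels), class = "molecule")
}

#' Simulate nick-labeled single molecules from diploid haplotypes
#'
#' Draws molecules until the target coverage is reached.  Each molecule
#' picks a haplotype at random, a log-normal length truncated at
#' `min_molecule_length`, and a uniform genomic placement; fragments are
#' clipped at the chromosome ends, so terminal fragments retain the full
#' telomere tract distal of their start.  Each spanned true site is labeled
#' with probability `1 - fn_rate`; spurious labels are added as a Poisson
#' process; every inter-label segment (ends included) receives independent
#' sizing noise of SD `sqrt((sizing_rel_sd * seg)^2 + sizing_abs_sd^2)`;
#' molecules spanning an INP locus break there with
#' `inp_break_probability`; finally each molecule is reversed with
#' probability 1/2.  Hidden truth (haplotype, origin interval, orientation,
#' pre-noise label counts) is recorded per molecule.
#'
#' @param haplotypes a list of [haplotype_truth()] objects, or a
#'   `diploid_subtelomere` from [build_diploid_subtelomere()].
#' @param params a [sim_params()].
#' @return an object of class `molecule_set`: list with `molecules` (list
#'   of [molecule()]), `truth` (data frame: id, hap, start, end, reversed,
#'   n_true, n_kept, n_fp), `genome_length`, `params`.
#' @export
simulate_molecules <- function(haplotypes, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (inherits(haplotypes, "diploid_subtelomere"))
    haplotypes <- lapply(haplotypes$haplotypes, `[[`, "truth")
  if (inherits(haplotypes, "telo_haplotype")) haplotypes <- list(haplotypes)
  stopifnot(length(haplotypes) >= 1,
            all(vapply(haplotypes, inherits, logical(1), "telo_haplotype")))
  if (!is.null(params$seed)) set.seed(params$seed)

  genome_len <- sum(vapply(haplotypes, `[[`, numeric(1), "length"))
  target <- params$coverage * genome_len
  mols <- vector("list", ceiling(target / params$min_molecule_length) + 8)
  tr <- vector("list", length(mols))
  nmol <- 0L; tot <- 0; attempts <- 0L
  max_attempts <- 200L * (length(mols) + 10L)

  while (tot < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    hi <- sample.int(length(haplotypes), 1)
    H <- haplotypes[[hi]]
    len <- stats::rlnorm(1, log(params$length_median), params$length_sdlog)
    if (len < params$min_molecule_length) next
    s <- stats::runif(1, -len, H$length)
    fs <- max(0, s); fe <- min(s + len, H$length)
    # shear breaks do not fall inside the telomere repeat tract: a
    # terminal molecule retains the full tract distal of its start
    if (H$arm == "p" && fs > 0 && fs < H$tract_length) fs <- 0
    if (H$arm == "q" && fe < H$length &&
        fe > H$length - H$tract_length) fe <- H$length
    if (fe - fs < params$min_molecule_length) next

    # INP-mediated double-strand breaks split the fragment
    cuts <- H$inp_positions[H$inp_positions > fs & H$inp_positions < fe]
    if (length(cuts))
      cuts <- cuts[stats::runif(length(cuts)) < params$inp_break_probability]
    bounds <- c(fs, sort(cuts), fe)

    for (p in seq_len(length(bounds) - 1)) {
      ps <- bounds[p]; pe <- bounds[p + 1]
      flen <- pe - ps
      if (flen < params$min_molecule_length) next
      # stop before overshooting the coverage target by more than it helps
      if (tot + flen - target > target - tot) { tot <- target; break }
      nmol <- nmol + 1L
      id <- sprintf("mol%05d", nmol)
      m <- simulate_one_molecule(id, H, ps, pe, params)
      mols[[nmol]] <- m$molecule
      tr[[nmol]] <- m$truth
      tot <- tot + flen
    }
  }

  truth <- do.call(rbind, tr[seq_len(nmol)])
  if (is.null(truth))
    truth <- data.frame(id = character(0), hap = character(0),
                        start = numeric(0), end = numeric(0),
                        reversed = logical(0), n_true = integer(0),
                        n_kept = integer(0), n_fp = integer(0))
  structure(list(molecules = mols[seq_len(nmol)], truth = truth,
                 genome_length = genome_len, params = params),
            class = "molecule_set")
}

simulate_one_molecule <- function(id, H, fs, fe, params) {
  flen <- fe - fs
  spanned <- H$sites[H$sites >= fs & H$sites < fe]
  kept <- spanned[stats::runif(length(spanned)) >= params$fn_rate]
  n_fp <- if (params$fp_mode == "per_true_label")
    stats::rpois(1, params$fp_rate * length(spanned))
  else stats::rpois(1, params$fp_rate * flen)
  fps <- if (n_fp > 0) stats::runif(n_fp, fs, fe) else numeric(0)
  labs <- sort(unique(c(kept, fps))) - fs

  seg <- diff(c(0, labs, flen))
  sdv <- sqrt((params$sizing_rel_sd * seg)^2 + params$sizing_abs_sd^2)
  if (any(sdv > 0)) seg <- pmax(seg + stats::rnorm(length(seg), 0, sdv), 1)
  cum <- cumsum(seg)
  nlen <- cum[length(cum)]
  nlabs <- cum[-length(cum)]

  reversed <- stats::runif(1) < 0.5
  if (reversed && length(nlabs)) nlabs <- nlen - rev(nlabs)
  list(molecule = molecule(id, nlen, nlabs),
       truth = data.frame(id = id, hap = H$id, start = fs, end = fe,
                          reversed = reversed, n_true = length(spanned),
                          n_kept = length(kept), n_fp = n_fp,
                          stringsAsFactors = FALSE))
}

#' @export
print.molecule_set <- function(x, ...) {
  nlab <- vapply(x$molecules, function(m) length(m$labels), integer(1))
  cat(sprintf(
    "molecule_set: %d molecules, %.1fx coverage of %.0f bp, %.1f labels/molecule\n",
    length(x$molecules),
    sum(vapply(x$molecules, `[[`, numeric(1), "length")) / x$genome_length,
    x$genome_length, mean(nlab)))
  invisible(x)
}
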