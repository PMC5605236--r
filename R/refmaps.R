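#' In-silico nicking digest of a sequence
#'
#' Scans a nucleotide sequence for occurrences of a nicking-endonuclease
#' recognition motif on both strands.  Top-strand sites are occurrences of
#' the motif itself; bottom-strand sites are occurrences of its reverse
#' complement.  Site coordinates are 0-based positions of the motif window
#' start on the top strand (plus `nick_offset`); any window containing `N`
#' yields no site, so assembly gaps are label-free.
#'
#' @param sequence nucleotide string over `{A,C,G,T,N}` (or a
#'   [Biostrings::DNAString]).
#' @param motif recognition sequence over `{A,C,G,T}`, length >= 4.  Default
#'   `"GCTCTTC"`, the canonical Nt.BspQI recognition sequence.
#' @param nick_offset bp added to the motif window start to place the site
#'   coordinate.  Default 0; at map-scale (kb) resolution the exact nick
#'   offset is immaterial.
#' @return a `data.frame` of class `nick_sites` with columns `position`
#'   (0-based bp) and `strand` (`"top"`/`"bottom"`), sorted by position.
#' @examples
#' in_silico_nick("AAGCTCTTCAATTGAAGAGCAA")
#' @export
in_silico_nick <- function(sequence, motif = "GCTCTTC", nick_offset = 0) {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0)
    stop("'motif' must be a non-empty nucleotide string")
  motif <- toupper(motif)
  if (nchar(motif) < 4) stop("'motif' must have length >= 4")
  if (grepl("[^ACGT]", motif))
    stop("'motif' may contain only A, C, G, T")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("'sequence' may contain only A, C, G, T, N")
  empty <- data.frame(position = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (nchar(sequence) < nchar(motif))
    return(structure(empty, class = c("nick_sites", "data.frame")))

  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(motif, subj)) - 1L
  rcm <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  rev <- Biostrings::start(Biostrings::matchPattern(rcm, subj)) - 1L
  out <- data.frame(
    position = c(fwd, rev) + nick_offset,
    strand = c(rep("top", length(fwd)), rep("bottom", length(rev))),
    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("nick_sites", "data.frame"))
}

#' Detect inverted nick pairs (INP loci)
#'
#' Two closely-spaced nick sites on opposite strands nick both strands of
#' the duplex and cause double-strand breaks, fragmenting molecules at the
#' locus.  This reports every *adjacent* pair of sites (consecutive in
#' position order) on opposite strands separated by at most `max_gap` bp.
#'
#' @param sites a `nick_sites` data frame (columns `position`, `strand`),
#'   sorted by position.
#' @param max_gap maximum bp separation (> 0).
#' @return a `data.frame` of class `inp_loci` with columns `left_position`,
#'   `left_strand`, `right_position`, `right_strand`, `gap`.
#' @export
detect_inp <- function(sites, max_gap) {
  stopifnot(is.data.frame(sites),
            all(c("position", "strand") %in% names(sites)),
            is.numeric(max_gap), max_gap > 0)
  if (is.unsorted(sites$position))
    stop("'sites' must be sorted by position")
  empty <- data.frame(left_position = numeric(0), left_strand = character(0),
                      right_position = numeric(0), right_strand = character(0),
                      gap = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(sites)
  if (n < 2) return(structure(empty, class = c("inp_loci", "data.frame")))
  l <- seq_len(n - 1); r <- l + 1L
  gap <- sites$position[r] - sites$position[l]
  hit <- sites$strand[l] != sites$strand[r] & gap <= max_gap
  out <- data.frame(left_position = sites$position[l][hit],
                    left_strand = sites$strand[l][hit],
                    right_position = sites$position[r][hit],
                    right_strand = sites$strand[r][hit],
                    gap = gap[hit], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("inp_loci", "data.frame"))
}

#' Build a reference nick map
#'
#' Converts a reference sequence (or a pre-computed site list) into the
#' strand-collapsed ordered nick map used for molecule alignment.  The
#' imaging system cannot distinguish strands, so only positions are kept
#' (deduplicated); sites falling inside assembly gap intervals are removed,
#' since a gap ("NNN") carries no sequence content and hence no labels.
#'
#' @param id reference/telomere identifier, e.g. `"15q"`.
#' @param sequence nucleotide string; digested with `motif` if given.
#' @param sites numeric site positions (bp) or a `nick_sites` data frame;
#'   used when `sequence` is NULL (then `length` is required).
#' @param length reference length in bp.
#' @param arm `"p"` (telomere at coordinate 0) or `"q"` (telomere at
#'   coordinate `length`).
#' @param gaps list of `[start, end)` bp intervals with no sequence content
#'   (each a length-2 numeric), or a 2-column matrix.
#' @param distal_offset bp between the map's telomeric end and the true
#'   start of the (TTAGGG)n tract, or `"unknown"`/`NA` when the reference is
#'   incomplete at the telomeric side.  Telomere-length estimates made
#'   against a map with unknown distal offset are flagged as overestimates.
#' @param motif,nick_offset passed to [in_silico_nick()] when digesting.
#' @return an object of class `reference_map`: a list with elements `id`,
#'   `length`, `sites` (strictly increasing bp positions), `arm`, `gaps`
#'   (2-column matrix) and `distal_offset` (bp or `NA`).
#' @export
build_reference_map <- function(id, sequence = NULL, sites = NULL,
                                length = NULL, arm = c("p", "q"),
                                gaps = NULL, distal_offset = 0,
                                motif = "GCTCTTC", nick_offset = 0) {
  arm <- match.arg(arm)
  if (!is.null(sequence)) {
    if (is(sequence, "DNAString")) sequence <- as.character(sequence)
    length <- nchar(sequence)
    sites <- in_silico_nick(sequence, motif, nick_offset)$position
  } else {
    if (is.data.frame(sites)) sites <- sites$position
    if (is.null(length)) stop("'length' is required when 'sites' are given")
  }
  length <- as.numeric(length)
  sites <- sort(unique(as.numeric(sites)))          # strand-collapse
  if (any(sites < 0 | sites >= length) && length > 0)
    stop("site positions must lie in [0, length)")

  if (is.null(gaps)) gaps <- matrix(numeric(0), ncol = 2)
  if (is.list(gaps)) gaps <- do.call(rbind, lapply(gaps, as.numeric))
  gaps <- matrix(as.numeric(gaps), ncol = 2)
  colnames(gaps) <- c("start", "end")
  if (nrow(gaps)) {
    if (any(gaps[, 1] >= gaps[, 2]))
      stop("gap intervals must satisfy start < end")
    if (any(gaps[, 1] < 0 | gaps[, 2] > length))
      stop("gap intervals must lie within [0, length)")
    o <- order(gaps[, 1]); gaps <- gaps[o, , drop = FALSE]
    if (nrow(gaps) > 1 &&
        any(gaps[-1, 1] < gaps[-nrow(gaps), 2]))
      stop("gap intervals must not overlap")
    in_gap <- vapply(sites, function(p)
      any(p >= gaps[, 1] & p < gaps[, 2]), logical(1))
    sites <- sites[!in_gap]
  }

  if (is.character(distal_offset) || is.na(distal_offset)) {
    if (is.character(distal_offset) && !identical(distal_offset, "unknown"))
      stop("'distal_offset' must be numeric, NA or \"unknown\"")
    distal_offset <- NA_real_
  } else {
    distal_offset <- as.numeric(distal_offset)
    if (distal_offset < 0 || distal_offset > length)
      stop("'distal_offset' must lie in [0, length] when known")
  }

  structure(list(id = as.character(id), length = length, sites = sites,
                 arm = arm, gaps = gaps, distal_offset = distal_offset),
            class = "reference_map")
}

# telomeric end of the reference at coordinate 0?
ref_tel_at_start <- function(ref) ref$arm == "p"

#' @export
print.reference_map <- function(x, ...) {
  d <- if (is.na(x$distal_offset)) "unknown" else
    sprintf("%.0f bp", x$distal_offset)
  cat(sprintf(
    "reference_map '%s' (%s-arm): %.0f bp, %d sites, %d gap(s), distal offset %s\n",
    x$id, x$arm, x$length, length(x$sites), nrow(x$gaps), d))
  invisible(x)
}
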