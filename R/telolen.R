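#' Estimate single-telomere length from one aligned molecule
#'
#' The (TTAGGG)n tract carries no nicking motif, so a telomere-terminal
#' molecule overhangs the reference's telomeric end by its tract length.
#' The estimate takes the matched pair nearest the telomeric end (the raw
#' first label may be a false positive) and computes
#' `molecule distance from that label to the telomeric molecule end` minus
#' `reference distance from the matched site to the telomeric reference
#' end`.  For a p-arm molecule entering telomere-first this is
#' `label_pos - site_pos`; reversed, `molecule_length - label_pos -
#' site_pos`; q-arms are symmetric about the reference terminus.  A known
#' `distal_offset` (bp between the reference's telomeric end and the true
#' tract start) is subtracted; when it is unknown the estimate is flagged
#' `gap_haplotype_overestimate` (it exceeds the true tract length by up to
#' the local inter-site spacing).  Negative raw values (terminal reference
#' site distal of the molecule end under sizing noise) clamp to 0 with a
#' flag.
#'
#' @param mol the [molecule()].
#' @param alignment its `om_alignment` (must have passed the confidence
#'   threshold and [anchor_check()]; callers enforce anchoring).  A
#'   `no_alignment` marker or NULL yields NULL (estimate refused).
#' @param ref the reference map; `ref$arm` must be known.
#' @param fp_allowance tolerated unmatched labels per bp of overhang before
#'   flagging `overhang_labels_present`.  Default 1e-4 (one per 10 kb), the
#'   expectation for random false-positive labels in the tract.
#' @param terminal_slack only telomere-terminal molecules measure a
#'   telomere: molecules whose telomeric end falls short of the reference's
#'   telomeric end by more than this many bp (interior fragments) are
#'   refused.  Default 1500, a few sizing SDs.
#' @return one-row data frame of class `telomere_estimate`: `molecule_id`,
#'   `tel_id`, `haplotype` (NA; fill from haplotype groups), `length`
#'   (bp), `orientation`, `gap_haplotype_overestimate`,
#'   `overhang_labels_present`, `clamped` — or `NULL` when `alignment` is
#'   `NULL` (estimate refused, not an error).
#' @export
estimate_telomere_length <- function(mol, alignment, ref,
                                     fp_allowance = 1e-4,
                                     terminal_slack = 1500) {
  if (!is_alignment(alignment)) return(NULL)
  stopifnot(inherits(mol, "molecule"),
            inherits(ref, "reference_map"))
  tel0 <- ref_tel_at_start(ref)
  pr <- alignment$pairs
  k <- if (tel0) which.min(pr$site_pos) else which.max(pr$site_pos)
  m_star <- pr$label_pos[k]
  r_star <- pr$site_pos[k]

  # which end of the molecule is telomeric, in original coordinates
  tel_mol_start <- (tel0 && alignment$orientation == "forward") ||
                   (!tel0 && alignment$orientation == "reverse")
  dist_mol <- if (tel_mol_start) m_star else mol$length - m_star
  dist_ref <- if (tel0) r_star else ref$length - r_star

  raw <- dist_mol - dist_ref
  if (raw < -terminal_slack) return(NULL)   # interior fragment
  gap_flag <- is.na(ref$distal_offset)
  if (!gap_flag) raw <- raw - ref$distal_offset
  clamped <- raw < 0
  len <- max(0, raw)

  # unmatched labels distal of the telomere-proximal matched pair
  n_over <- if (tel_mol_start) sum(mol$labels < m_star)
            else sum(mol$labels > m_star)
  over_flag <- n_over > max(0, len) * fp_allowance

  structure(data.frame(
    molecule_id = mol$id, tel_id = ref$id, haplotype = NA_character_,
    length = len, orientation = alignment$orientation,
    gap_haplotype_overestimate = gap_flag,
    overhang_labels_present = over_flag, clamped = clamped,
    stringsAsFactors = FALSE),
    class = c("telomere_estimate", "data.frame"))
}

#' Estimate telomere lengths for a set of aligned molecules
#'
#' Applies the single-molecule estimator to every alignment that passes
#' the 1-copy anchor check, optionally attaching haplotype assignments.
#'
#' @param mols `molecule_set` or list of molecules.
#' @param alignments named list of alignments (from [align_molecules()]).
#' @param ref reference map.
#' @param one_copy_interval `[start, end)` 1-copy anchoring interval; when
#'   given, unanchored alignments are refused.
#' @param groups optional list of `haplotype_group`; member molecules get
#'   the group's haplotype id.
#' @param fp_allowance,terminal_slack see [estimate_telomere_length()].
#' @return data frame of class `telomere_estimate`, one row per estimated
#'   molecule.
#' @export
estimate_telomere_lengths <- function(mols, alignments, ref,
                                      one_copy_interval = NULL,
                                      groups = NULL, fp_allowance = 1e-4,
                                      terminal_slack = 1500) {
  ml <- if (inherits(mols, "molecule_set")) mols$molecules else mols
  names(ml) <- vapply(ml, `[[`, character(1), "id")
  rows <- list()
  for (id in names(alignments)) {
    aln <- alignments[[id]]
    if (!is_alignment(aln)) next
    if (!is.null(one_copy_interval) &&
        !anchor_check(aln, ref, one_copy_interval)) next
    est <- estimate_telomere_length(ml[[id]], aln, ref, fp_allowance,
                                    terminal_slack)
    if (!is.null(est)) rows[[length(rows) + 1]] <- est
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    structure(data.frame(molecule_id = character(0), tel_id = character(0),
                         haplotype = character(0), length = numeric(0),
                         orientation = character(0),
                         gap_haplotype_overestimate = logical(0),
                         overhang_labels_present = logical(0),
                         clamped = logical(0), stringsAsFactors = FALSE),
              class = c("telomere_estimate", "data.frame"))
  if (!is.null(groups)) {
    for (g in groups)
      out$haplotype[out$molecule_id %in% g$members] <- g$haplotype
  }
  rownames(out) <- NULL
  structure(out, class = c("telomere_estimate", "data.frame"))
}

#' Aggregate telomere estimates per telomere and haplotype
#'
#' Arithmetic mean, sample SD (n-1 denominator; NA for single-molecule
#' groups) and molecule count per (telomere, haplotype) group; a group
#' carries the gap flag (reported as an asterisk in summary tables) when
#' any member estimate was made against a reference with unknown distal
#' offset.
#'
#' @param estimates a `telomere_estimate` data frame.
#' @param by grouping columns.  Default `c("tel_id", "haplotype")`.
#' @return data frame of class `telomere_summary`: grouping columns plus
#'   `mean` (bp), `sd` (bp), `n`, `gap`.
#' @export
aggregate_lengths <- function(estimates, by = c("tel_id", "haplotype")) {
  stopifnot(is.data.frame(estimates))
  if (!nrow(estimates))
    return(structure(data.frame(tel_id = character(0),
                                haplotype = character(0),
                                mean = numeric(0), sd = numeric(0),
                                n = integer(0), gap = logical(0)),
                     class = c("telomere_summary", "data.frame")))
  key <- interaction(lapply(estimates[by], addNA, ifany = TRUE),
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(estimates, key), function(g) {
    out <- g[1, by, drop = FALSE]
    out$mean <- mean(g$length)
    out$sd <- if (nrow(g) >= 2) stats::sd(g$length) else NA_real_
    out$n <- nrow(g)
    out$gap <- any(g$gap_haplotype_overestimate)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("telomere_summary", "data.frame"))
}

#' @export
print.telomere_summary <- function(x, ...) {
  if (!nrow(x)) { cat("telomere_summary: empty\n"); return(invisible(x)) }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s%s hap %s: %.1f kb %s (n=%d)\n",
                x$tel_id[i], if (isTRUE(x$gap[i])) "*" else "",
                x$haplotype[i], x$mean[i] / 1000,
                if (is.na(x$sd[i])) "" else
                  sprintf("± %.1f kb", x$sd[i] / 1000), x$n[i]))
  }
  invisible(x)
}
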