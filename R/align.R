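#' Align a molecule's nick-label pattern to a reference map
#'
#' Finds the maximum-score monotone matching between the molecule's ordered
#' label positions and the reference's ordered nick sites, over both
#' orientations and all placements, by dynamic programming.
#'
#' The score is a log-likelihood ratio (natural-log units) of the placement
#' hypothesis against a random-genome label process of density
#' `params$site_density`: each matched inter-label interval contributes a
#' Gaussian log-likelihood of the molecule/reference length discrepancy
#' under the sizing model (half-squared z-scores capped at `params$sv_cap`,
#' so one large insertion or deletion costs a flat outlier penalty instead
#' of vetoing the placement); spanned-but-unlabeled reference sites cost
#' `-log(miss_rate)`; unexplained labels cost `-log(extra_rate)`; and every
#' bp of molecule extent explained by the placement earns
#' `site_density*(1-extra_rate)`, so a long label-free telomere overhang is
#' itself evidence for a telomeric placement.  Molecule ends may overhang
#' the reference freely; an overhang beyond the *centromeric* reference end
#' is neutral (the genome continues there), while an overhang beyond the
#' telomeric end is treated as (TTAGGG)n tract — clean extent credited,
#' spurious labels charged — up to `params$max_tract` bp.
#'
#' Confidence is `max(0, score)`: the evidence, in natural-log units, that
#' the molecule belongs to this locus rather than being a random genomic
#' molecule.  Placement *uniqueness* within segmentally duplicated
#' subtelomeres is the separate concern of [anchor_check()], mirroring the
#' field's practice of filtering on an alignment-quality score and on
#' 1-copy anchoring independently.  Equal-score alignments are resolved in
#' favor of more matched pairs, then forward orientation.
#'
#' @param mol a [molecule()].
#' @param ref a [build_reference_map()] object.
#' @param params a [scoring_params()].
#' @return an object of class `om_alignment`, or a `no_alignment` object
#'   when none is reported (`$reason` is `"unalignable"` for molecules
#'   with fewer than 2 labels, `"no_alignment"` when no 2-pair matching
#'   exists, `"low_confidence"` below `params$min_confidence`).
#'   The alignment has fields `molecule_id`, `ref_id`, `orientation`
#'   (`"forward"`/`"reverse"`), `pairs` (data frame: `label` = original
#'   label index, `site` = reference site index, `label_pos` = original
#'   label bp, `label_pos_oriented`, `site_pos`), `offset` (reference bp of
#'   oriented molecule coordinate 0), `score`, `confidence`, `residuals`
#'   (per matched interval: `ref_start`, `ref_end`, `mol_len`, `ref_len`,
#'   `residual` with positive = molecule longer than reference),
#'   `mol_length`, `n_labels`.
#' @export
align_molecule <- function(mol, ref, params = scoring_params()) {
  stopifnot(inherits(mol, "molecule"), inherits(ref, "reference_map"),
            inherits(params, "scoring_params"))
  n <- length(mol$labels)
  if (n < 2 || length(ref$sites) < 2)
    return(no_alignment("unalignable", mol$id, ref$id))

  tel0 <- ref_tel_at_start(ref)
  lam <- params$site_density
  args <- list(v = ref$sites, R = ref$length, tel_at_start = tel0,
               rel_sd = params$rel_sd, sd_floor = params$sd_floor,
               lambda = lam, clean_per_bp = lam * (1 - params$extra_rate),
               miss_pen = -log(params$miss_rate),
               extra_pen = -log(params$extra_rate),
               match_logp = log(1 - params$miss_rate),
               max_skip = params$max_skip, sv_cap = params$sv_cap,
               max_tract = params$max_tract)

  orient <- list(forward = mol$labels,
                 reverse = mol$length - rev(mol$labels))
  dp <- lapply(orient, function(u)
    do.call(.dp_align_cpp, c(list(u = u, L = mol$length), args)))

  sc <- vapply(dp, function(r)
    if (is.na(r$score)) -Inf else r$score, numeric(1))
  if (all(!is.finite(sc)))
    return(no_alignment("no_alignment", mol$id, ref$id))
  # tie-break: higher score, then more pairs, then forward
  best_o <- if (sc[1] >= sc[2] - 1e-9 &&
                (sc[1] > sc[2] + 1e-9 ||
                 dp$forward$npairs >= dp$reverse$npairs)) 1L else 2L
  best <- dp[[best_o]]
  u <- orient[[best_o]]
  pr <- best$pairs
  k <- nrow(pr)
  confidence <- max(0, best$score)

  # map oriented label indices back to the original molecule
  lab_orig <- if (best_o == 1L) pr[, 1] else n + 1L - pr[, 1]
  pairs <- data.frame(label = lab_orig, site = pr[, 2],
                      label_pos = mol$labels[lab_orig],
                      label_pos_oriented = u[pr[, 1]],
                      site_pos = ref$sites[pr[, 2]])
  res <- if (k >= 2) {
    i <- 2:k
    data.frame(ref_start = pairs$site_pos[i - 1], ref_end = pairs$site_pos[i],
               mol_len = pairs$label_pos_oriented[i] -
                 pairs$label_pos_oriented[i - 1],
               ref_len = pairs$site_pos[i] - pairs$site_pos[i - 1])
  } else data.frame(ref_start = numeric(0), ref_end = numeric(0),
                    mol_len = numeric(0), ref_len = numeric(0))
  res$residual <- res$mol_len - res$ref_len

  out <- structure(list(
    molecule_id = mol$id, ref_id = ref$id,
    orientation = c("forward", "reverse")[best_o],
    pairs = pairs, offset = ref$sites[pr[1, 2]] - u[pr[1, 1]],
    score = best$score, confidence = confidence,
    residuals = res, mol_length = mol$length, n_labels = n),
    class = "om_alignment")
  if (confidence < params$min_confidence)
    return(no_alignment("low_confidence", mol$id, ref$id, confidence))
  out
}

no_alignment <- function(reason, molecule_id = NA, ref_id = NA,
                         confidence = NA_real_) {
  structure(list(reason = reason, molecule_id = molecule_id,
                 ref_id = ref_id, confidence = confidence),
            class = "no_alignment")
}

#' Test whether an object is a reported alignment
#' @param x any object.
#' @return TRUE for `om_alignment` objects, FALSE otherwise (including
#'   `no_alignment` markers and NULL).
#' @export
is_alignment <- function(x) inherits(x, "om_alignment")

#' Align every molecule of a set
#'
#' @param mols a `molecule_set` (or list of [molecule()]).
#' @param ref reference map.
#' @param params scoring parameters.
#' @return named list of `om_alignment` objects (molecules without a
#'   reported alignment are omitted); attributes `n_input` and `n_aligned`.
#' @export
align_molecules <- function(mols, ref, params = scoring_params()) {
  ml <- if (inherits(mols, "molecule_set")) mols$molecules else mols
  alns <- lapply(ml, align_molecule, ref = ref, params = params)
  names(alns) <- vapply(ml, `[[`, character(1), "id")
  keep <- vapply(alns, is_alignment, logical(1))
  structure(alns[keep], n_input = length(ml), n_aligned = sum(keep))
}

#' Check 1-copy anchoring of an alignment
#'
#' Molecules must extend into unique (1-copy) subtelomeric DNA to guarantee
#' chromosome-specific assignment; an alignment is anchored when at least
#' one matched reference site lies within the 1-copy interval.
#'
#' @param alignment an `om_alignment`.
#' @param ref reference map (unused beyond validation; kept for interface
#'   symmetry).
#' @param one_copy_interval `[start, end)` bp interval of 1-copy DNA on the
#'   reference.
#' @return logical.
#' @export
anchor_check <- function(alignment, ref, one_copy_interval) {
  if (!is_alignment(alignment)) return(FALSE)
  stopifnot(length(one_copy_interval) == 2)
  any(alignment$pairs$site_pos >= one_copy_interval[1] &
      alignment$pairs$site_pos < one_copy_interval[2])
}

#' Detect outlier (indel) intervals in an alignment
#'
#' Reports every matched interval whose sizing residual (molecule length
#' minus reference length, spanning any run of skipped sites) exceeds
#' `min_size` in magnitude.  Positive `size_delta` = insertion in the
#' molecule relative to the reference.
#'
#' @param alignment an `om_alignment`.
#' @param min_size minimum |residual| in bp.  Default 5000.
#' @return data frame of class `outlier_intervals`: `ref_start`, `ref_end`,
#'   `size_delta`, `molecule_id`.
#' @export
detect_outliers <- function(alignment, min_size = 5000) {
  stopifnot(inherits(alignment, "om_alignment"), min_size > 0)
  r <- alignment$residuals
  hit <- abs(r$residual) > min_size
  out <- data.frame(ref_start = r$ref_start[hit], ref_end = r$ref_end[hit],
                    size_delta = r$residual[hit],
                    molecule_id = rep(alignment$molecule_id, sum(hit)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("outlier_intervals", "data.frame"))
}

#' Shuffled-site decoy maps for confidence calibration
#'
#' Generates decoy references by permuting the inter-site spacings of a
#' real reference map (fixed seed derived from the map id), used to verify
#' that random molecules essentially never reach the reported-alignment
#' confidence threshold.
#'
#' @param ref reference map.
#' @param n number of decoys.
#' @return list of `reference_map` objects.
#' @export
decoy_maps <- function(ref, n = 5) {
  stopifnot(inherits(ref, "reference_map"), n >= 1)
  with_preserved_rng(hash_id(paste0("decoy:", ref$id)), {
    lapply(seq_len(n), function(k) {
      gaps <- diff(c(0, ref$sites))
      sites <- cumsum(sample(gaps))
      build_reference_map(paste0(ref$id, ".decoy", k), sites = sites,
                          length = ref$length, arm = ref$arm,
                          distal_offset = ref$distal_offset)
    })
  })
}

#' @export
print.om_alignment <- function(x, ...) {
  cat(sprintf(
    "om_alignment: %s -> %s (%s), %d pairs, offset %.0f, score %.1f, confidence %.1f\n",
    x$molecule_id, x$ref_id, x$orientation, nrow(x$pairs), x$offset,
    x$score, x$confidence))
  invisible(x)
}
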