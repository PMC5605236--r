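#' Alignment scoring parameters
#'
#' Parameters of the likelihood-ratio scoring model used by
#' [align_molecule()].  Matched inter-label intervals contribute a Gaussian
#' log-likelihood of the molecule/reference length discrepancy under the
#' sizing model `sd(y) = sqrt((rel_sd*y)^2 + sd_floor^2)`; spanned-but-
#' unlabeled reference sites cost `-log(miss_rate)`; unexplained molecule
#' labels cost `-log(extra_rate)`; and the molecule's extent explained by the
#' placement earns `site_density*(1-extra_rate)` per bp relative to a
#' random-genome label process of density `site_density`.
#'
#' @param rel_sd relative sizing standard deviation per interval (matches the
#'   simulator's `sizing_rel_sd`).  Default 0.03.
#' @param sd_floor absolute sizing noise floor in bp.  Default 250, the
#'   typical single-molecule measurement SD for molecules in this size range.
#' @param site_density expected nick sites per bp in a random genomic
#'   region.  Default 1/9300: the Nt.BspQI motif occurs on average every
#'   9.3 kb in the human genome (documented here as strand-collapsed map
#'   density; the simulator uses the same default spacing).
#' @param miss_rate probability a spanned reference site carries no label
#'   (false-negative rate).  Default 0.1.
#' @param extra_rate expected spurious labels per true label
#'   (false-positive rate).  Default 0.1.
#' @param max_skip maximum consecutive skipped sites or labels between two
#'   matched pairs.  Default 8.
#' @param sv_cap cap on the half-squared sizing z-score charged to a single
#'   interval, so that one large insertion/deletion does not destroy an
#'   otherwise concordant alignment.  Default 10 (intervals with |z| > 4.47
#'   are charged a flat outlier cost and surface in [detect_outliers()]).
#' @param min_confidence minimum placement confidence (natural-log
#'   likelihood-ratio units) for an alignment to be reported.  Default 20,
#'   the exclusion threshold used in the field for single-molecule telomere
#'   measurements; the confidence scale is this package's own (see
#'   vignette).
#' @param min_pairs minimum matched pairs.  Default 2.
#' @param max_tract maximum plausible (TTAGGG)n tract length, bp.  A
#'   molecule overhang beyond the telomeric reference end is credited as
#'   unlabeled tract only up to this length; beyond it (and beyond the
#'   centromeric end) the reference cannot evaluate the molecule and the
#'   overhang scores neutral.  Default 50000.
#' @param n_decoys number of shuffled-site decoy maps used by
#'   [decoy_maps()] for confidence-threshold calibration.  Default 5.
#'
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(rel_sd = 0.03, sd_floor = 250,
                           site_density = 1 / 9300,
                           miss_rate = 0.1, extra_rate = 0.1,
                           max_skip = 8, sv_cap = 10,
                           min_confidence = 20, min_pairs = 2,
                           max_tract = 50000, n_decoys = 5) {
  stopifnot(rel_sd >= 0, sd_floor >= 0, rel_sd + sd_floor > 0,
            site_density > 0,
            miss_rate > 0, miss_rate < 1,
            extra_rate > 0, extra_rate < 1,
            max_skip >= 0, sv_cap > 0,
            min_confidence >= 0, min_pairs >= 2, max_tract >= 0)
  structure(list(rel_sd = rel_sd, sd_floor = sd_floor,
                 site_density = site_density,
                 miss_rate = miss_rate, extra_rate = extra_rate,
                 max_skip = as.integer(max_skip), sv_cap = sv_cap,
                 min_confidence = min_confidence,
                 min_pairs = as.integer(min_pairs),
                 max_tract = max_tract,
                 n_decoys = as.integer(n_decoys)),
            class = "scoring_params")
}

#' Molecule simulation parameters
#'
#' Error characteristics and sampling settings for [simulate_molecules()].
#' Defaults are the study conditions of the emulated platform: 10%
#' false-negative and 10% false-positive label rates, molecules of at least
#' 150 kb, length-proportional sizing noise of order a few hundred bp, and
#' random molecule orientation.
#'
#' @param coverage target fold-depth (total molecule length over genome
#'   length).  Default 30.
#' @param min_molecule_length minimum molecule length in bp (shorter
#'   fragments are not imaged/used).  Default 150000.
#' @param length_median median of the log-normal molecule length
#'   distribution, bp.  Default 250000.
#' @param length_sdlog log-scale SD of the length distribution.  Default
#'   0.35.
#' @param fn_rate probability a true spanned site is unlabeled.  Default
#'   0.1.
#' @param fp_rate spurious-label rate; interpretation set by `fp_mode`.
#'   Default 0.1.
#' @param fp_mode `"per_true_label"` (default): expected spurious labels =
#'   `fp_rate` x true spanned sites, i.e. one spurious label per ten true
#'   labels.  `"per_bp"`: `fp_rate` is spurious labels per bp.
#' @param sizing_rel_sd relative SD of the multiplicative per-interval
#'   sizing noise.  Default 0.03.
#' @param sizing_abs_sd absolute per-interval noise floor, bp.  Default 250.
#' @param inp_break_probability probability that a molecule spanning an
#'   inverted-nick-pair locus is broken there.  Default 0.9.
#' @param seed integer seed; if non-NULL the simulation is bit-reproducible.
#'
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(coverage = 30, min_molecule_length = 150000,
                       length_median = 250000, length_sdlog = 0.35,
                       fn_rate = 0.1, fp_rate = 0.1,
                       fp_mode = c("per_true_label", "per_bp"),
                       sizing_rel_sd = 0.03, sizing_abs_sd = 250,
                       inp_break_probability = 0.9, seed = NULL) {
  fp_mode <- match.arg(fp_mode)
  stopifnot(coverage > 0, min_molecule_length >= 0,
            length_median > 0, length_sdlog >= 0,
            fn_rate >= 0, fn_rate <= 1, fp_rate >= 0,
            sizing_rel_sd >= 0, sizing_abs_sd >= 0,
            inp_break_probability >= 0, inp_break_probability <= 1)
  structure(list(coverage = coverage,
                 min_molecule_length = min_molecule_length,
                 length_median = length_median, length_sdlog = length_sdlog,
                 fn_rate = fn_rate, fp_rate = fp_rate, fp_mode = fp_mode,
                 sizing_rel_sd = sizing_rel_sd, sizing_abs_sd = sizing_abs_sd,
                 inp_break_probability = inp_break_probability,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_params")
}
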