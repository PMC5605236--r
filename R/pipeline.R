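#' Run the subtelomere analysis pipeline on a molecule set
#'
#' Aligns molecules to the reference, filters on confidence and 1-copy
#' anchoring, builds the overall and per-haplotype consensus maps, calls
#' structural variants (with haplotype codes), and estimates telomere
#' lengths per molecule and per haplotype.
#'
#' @param reference a `reference_map`.
#' @param mols a `molecule_set` (or list of [molecule()]).
#' @param one_copy_interval `[start, end)` bp interval of 1-copy DNA used
#'   for anchoring.
#' @param scoring [scoring_params()].
#' @param sv_min_size minimum size for insertion/deletion calls, bp.
#' @param min_members minimum molecules per haplotype group.
#' @param outdir if non-NULL, all outputs (XMAP, consensus CMAPs, SV BED,
#'   haplotype table, telomere TSVs, manifest) are written there.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic given the molecules).
#' @return list of class `telo_run`: `alignments`, `anchored` (ids),
#'   `consensus`, `groups`, `sv_calls`, `estimates`, `summaries`, `stats`.
#' @export
run_subtelomere_pipeline <- function(reference, mols, one_copy_interval,
                                     scoring = scoring_params(),
                                     sv_min_size = 20000, min_members = 5,
                                     outdir = NULL, seed = NULL) {
  ml <- if (inherits(mols, "molecule_set")) mols$molecules else mols
  names(ml) <- vapply(ml, `[[`, character(1), "id")

  alns <- align_molecules(ml, reference, scoring)
  anchored <- names(alns)[vapply(alns, anchor_check, logical(1),
                                 ref = reference,
                                 one_copy_interval = one_copy_interval)]
  aln_a <- alns[anchored]

  consensus <- build_consensus(aln_a, ml, reference)
  groups <- cluster_haplotypes(aln_a, ml, reference,
                               min_members = min_members)
  group_calls <- lapply(groups, function(g)
    call_svs(g$consensus, reference, min_size = sv_min_size))
  svs <- annotate_haplotype_codes(group_calls)

  estimates <- estimate_telomere_lengths(ml, aln_a, reference,
                                         one_copy_interval = NULL,
                                         groups = groups)
  summaries <- aggregate_lengths(estimates)

  stats <- data.frame(
    tel_id = reference$id, molecules_in = length(ml),
    aligned = length(alns), anchored = length(anchored),
    haplotypes = length(groups), sv_calls = nrow(svs),
    estimates = nrow(estimates),
    status = if (length(anchored) == 0) "nd" else "ok")
  message(sprintf(
    "[%s] %d molecules in, %d aligned, %d anchored, %d haplotype(s), %d SV call(s), %d telomere estimate(s)",
    reference$id, length(ml), length(alns), length(anchored),
    length(groups), nrow(svs), nrow(estimates)))

  out <- structure(list(reference = reference, alignments = alns,
                        anchored = anchored, consensus = consensus,
                        groups = groups, sv_calls = svs,
                        estimates = estimates, summaries = summaries,
                        stats = stats), class = "telo_run")
  if (!is.null(outdir)) write_run(out, mols, outdir, scoring, seed)
  out
}

write_run <- function(run, mols, outdir, scoring, seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  id <- run$reference$id
  write_cmap(run$reference, file.path(outdir, paste0(id, ".ref.cmap")))
  if (inherits(mols, "molecule_set")) {
    write_bnx(mols, file.path(outdir, paste0(id, ".molecules.bnx")))
    write_molecule_truth(mols, file.path(outdir, paste0(id, ".truth.tsv")))
  }
  write_xmap(run$alignments, file.path(outdir, paste0(id, ".xmap")))
  for (g in run$groups)
    write_cmap(g$consensus,
               file.path(outdir, sprintf("%s.hap%s.cmap", id, g$haplotype)))
  write_sv_bed(run$sv_calls, file.path(outdir, paste0(id, ".sv.bed")))
  memb <- do.call(rbind, lapply(run$groups, function(g)
    data.frame(molecule_id = g$members, haplotype = g$haplotype)))
  if (is.null(memb))
    memb <- data.frame(molecule_id = character(0), haplotype = character(0))
  write.table(memb, file.path(outdir, paste0(id, ".haplotypes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_estimates_tsv(run$estimates,
                      file.path(outdir, paste0(id, ".telomere.tsv")))
  write_summary_tsv(run$summaries,
                    file.path(outdir, paste0(id, ".telomere_summary.tsv")))

  cfg <- tempfile(); saveRDS(scoring, cfg)
  manifest <- list(
    telomere = id, seed = if (is.null(seed)) "none" else seed,
    config_hash = unname(tools::md5sum(cfg)),
    files = list.files(outdir, pattern = paste0("^", id, "\\.")),
    stats = as.list(run$stats))
  unlink(cfg)
  yaml::write_yaml(manifest, file.path(outdir, paste0(id, ".manifest.yaml")))
  invisible(outdir)
}

#' Simulate a preset scenario and run the pipeline on it
#'
#' @param scenario a `telo_scenario` from [scenario_preset()].
#' @param seed simulation seed (overrides the scenario's).
#' @param ... passed to [run_subtelomere_pipeline()].
#' @return list with `mols` (the simulated `molecule_set`, fixture
#'   molecules appended) and `run` (the `telo_run`).
#' @export
run_scenario <- function(scenario, seed = NULL, ...) {
  stopifnot(inherits(scenario, "telo_scenario"))
  params <- scenario$params
  if (!is.null(seed)) params$seed <- as.integer(seed)
  mols <- simulate_molecules(scenario$haplotypes, params)
  if (length(scenario$extra_molecules)) {
    mols$molecules <- c(mols$molecules, scenario$extra_molecules)
  }
  run <- run_subtelomere_pipeline(scenario$reference, mols,
                                  scenario$one_copy_interval,
                                  seed = params$seed, ...)
  list(mols = mols, run = run)
}
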