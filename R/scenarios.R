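# Preset simulation scenarios reproducing the study designs the package is
# validated on: the worked telomere-length example, a three-haplotype
# subtelomere with a discriminating nick site, a reference-gap subtelomere,
# a macrosatellite tandem array with different allele lengths, and a large
# telomere-adjacent insertion.

#' Preset simulation scenarios
#'
#' Returns a fully realized scenario: reference map, haplotype truths (and
#' sequences where the scenario is sequence-realized), simulation
#' parameters, the 1-copy anchoring interval, and any deterministic fixture
#' molecules the scenario prescribes.
#'
#' Available presets:
#' \describe{
#'   \item{`fig5_worked_example`}{Schematic 5p-style reference with sites at
#'     12, 37 and 162 kb and a 13 kb telomere tract; emits the 205 kb
#'     3-label molecule in both orientations among the fixtures.}
#'   \item{`fig2_15q_three_haplotypes`}{15q-style diploid in which one
#'     haplotype lacks a nick site present in the other.}
#'   \item{`fig3_6p_gap`}{6p-style reference with a 60 kb NNN gap and an
#'     unknown telomeric offset; haplotypes differ inside the gap.}
#'   \item{`d4z4_array`}{Macrosatellite tandem array of a motif-free
#'     3.3 kb unit, 12 vs 19 copies (~40 vs ~62 kb alleles).}
#'   \item{`fig1_50kb_insertion`}{50 kb telomere-adjacent insertion on one
#'     haplotype.}
#'   \item{`gap_overestimate`}{Homozygous telomere with 10 kb of
#'     telomere-adjacent sequence missing from the reference and the distal
#'     offset recorded as unknown.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed used for construction and as the default
#'   simulation seed.
#' @return a list of class `telo_scenario` with elements `name`,
#'   `reference`, `haplotypes` (list of [haplotype_truth()]), `build` (the
#'   `diploid_subtelomere`, when sequence-realized), `params`,
#'   `one_copy_interval`, `extra_molecules`.
#' @export
scenario_preset <- function(name = c("fig5_worked_example",
                                     "fig2_15q_three_haplotypes",
                                     "fig3_6p_gap", "d4z4_array",
                                     "fig1_50kb_insertion",
                                     "gap_overestimate"),
                            seed = 1) {
  name <- match.arg(name)
  seed <- as.integer(seed)

  if (name == "fig5_worked_example") {
    ref <- build_reference_map("5p", sites = c(12000, 37000, 162000),
                               length = 200000, arm = "p",
                               distal_offset = 0)
    truth <- haplotype_truth("5p.h1", length = 213000,
                             sites = 13000 + c(12000, 37000, 162000),
                             tract_length = 13000, arm = "p")
    return(structure(list(
      name = name, reference = ref, haplotypes = list(truth, truth),
      build = NULL,
      params = sim_params(coverage = 10, fn_rate = 0, fp_rate = 0,
                          sizing_rel_sd = 0, sizing_abs_sd = 0,
                          seed = seed),
      one_copy_interval = c(100000, 200000),
      extra_molecules = list(
        molecule("fig5_forward", 205000, c(25000, 50000, 175000)),
        molecule("fig5_reverse", 205000, c(30000, 155000, 180000)))),
      class = "telo_scenario"))
  }

  spec <- switch(name,
    fig2_15q_three_haplotypes = subtelomere_spec(
      "15q", tract = c(9000, 7000),
      edits = list(h1 = list(list(type = "nick_site_loss",
                                  position = 62000))),
      seed = seed),
    fig3_6p_gap = subtelomere_spec(
      "6p", tract = c(12000, 12000),
      ref_gaps = list(c(10000, 70000)),
      distal_unrepresented = 10000, distal_offset_known = FALSE,
      edits = list(h2 = list(list(type = "insertion", position = 40000,
                                  size = 25000))),
      seed = seed),
    d4z4_array = subtelomere_spec(
      "d4z4", tract = c(8000, 8000),
      edits = list(
        h1 = list(list(type = "tandem_array", position = 100000,
                       unit_length = 3300, copies = 12,
                       unit_id = "d4z4_unit")),
        h2 = list(list(type = "tandem_array", position = 100000,
                       unit_length = 3300, copies = 19,
                       unit_id = "d4z4_unit"))),
      seed = seed),
    fig1_50kb_insertion = subtelomere_spec(
      "19p", tract = c(9000, 9000),
      edits = list(h1 = list(list(type = "insertion", position = 20000,
                                  size = 50000))),
      seed = seed),
    gap_overestimate = subtelomere_spec(
      "gap", tract = c(9000, 9000),
      distal_unrepresented = 10000, distal_offset_known = FALSE,
      seed = seed))

  build <- build_diploid_subtelomere(spec)
  structure(list(
    name = name, reference = build$reference,
    haplotypes = lapply(build$haplotypes, `[[`, "truth"),
    build = build, params = sim_params(seed = seed),
    one_copy_interval = c(120000, build$reference$length),
    extra_molecules = list()), class = "telo_scenario")
}

#' Simulated trio of diploid individuals for transmission checks
#'
#' Three diploid individuals over one subtelomere sharing a common block
#' registry: parent 1 carries haplotypes A and B (B has a 30 kb insertion),
#' parent 2 carries C and A (C lacks a nick site), and the child inherits B
#' from parent 1 and C from parent 2.
#'
#' @param seed construction seed.
#' @return list with `individuals` (named list of `diploid_subtelomere`),
#'   `transmission` (truth: which parental haplotype each child haplotype
#'   came from), `one_copy_interval`.
#' @export
trio_scenario <- function(seed = 1) {
  hapA <- list()                                   # reference-like
  hapB <- list(list(type = "insertion", position = 80000, size = 30000,
                    ins_id = "trio_insB"))
  hapC <- list(list(type = "nick_site_loss", position = 62000))
  mk <- function(e1, e2) build_diploid_subtelomere(subtelomere_spec(
    "15q", tract = c(9000, 9000), edits = list(h1 = e1, h2 = e2),
    seed = seed))
  list(individuals = list(parent1 = mk(hapA, hapB),
                          parent2 = mk(hapC, hapA),
                          child = mk(hapB, hapC)),
       transmission = list(child_h1 = c(parent = "parent1", hap = "h2"),
                           child_h2 = c(parent = "parent2", hap = "h1")),
       one_copy_interval = c(120000, 270000))
}
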