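fig5_setup <- function() {
  list(ref = build_reference_map("5p", sites = c(12000, 37000, 162000),
                                 length = 200000, arm = "p",
                                 distal_offset = 0),
       fwd = molecule("fwd", 205000, c(25000, 50000, 175000)),
       rev = molecule("rev", 205000, c(30000, 155000, 180000)))
}

test_that("the worked-example telomere length is 13 kb in both orientations", {
  s <- fig5_setup()
  af <- align_molecule(s$fwd, s$ref)
  ef <- estimate_telomere_length(s$fwd, af, s$ref)
  expect_equal(ef$length, 25000 - 12000)           # 13 kb
  expect_equal(ef$orientation, "forward")

  ar <- align_molecule(s$rev, s$ref)
  er <- estimate_telomere_length(s$rev, ar, s$ref)
  expect_equal(er$length, 205000 - 180000 - 12000) # 13 kb
  expect_equal(er$orientation, "reverse")

  expect_false(ef$gap_haplotype_overestimate)
  expect_false(ef$overhang_labels_present)
})

test_that("a molecule whose first label sits on the first site has zero overhang", {
  ref <- build_reference_map("r", sites = c(12000, 37000, 162000),
                             length = 200000, arm = "p", distal_offset = 0)
  m <- molecule("m", 195000, c(12000, 37000, 162000))
  a <- align_molecule(m, ref)
  e <- estimate_telomere_length(m, a, ref)
  expect_equal(e$length, 0)
  expect_false(e$clamped)
})

test_that("q-arm estimates mirror the p-arm formula about the reference terminus", {
  ref <- build_reference_map("5q", sites = c(38000, 163000, 188000),
                             length = 200000, arm = "q", distal_offset = 0)
  # telomere enters last: labels at sites + 13 kb tract at the high end
  m <- molecule("m", 205000, c(30000, 155000, 180000))
  a <- align_molecule(m, ref)
  e <- estimate_telomere_length(m, a, ref)
  expect_equal(e$length, 13000)
})

test_that("estimates are refused for unanchored or low-confidence alignments and interior fragments", {
  s <- fig5_setup()
  expect_null(estimate_telomere_length(s$fwd, NULL, s$ref))
  # interior fragment: telomeric end far centromeric of the origin
  m2 <- molecule("i", 150000, c(37000, 162000) - 30000)
  a2 <- align_molecule(m2, s$ref, scoring_params(min_confidence = 0))
  if (is_alignment(a2)) expect_null(estimate_telomere_length(m2, a2, s$ref))
})

test_that("estimates aggregate to mean, sample SD and count per haplotype", {
  est <- structure(data.frame(
    molecule_id = c("a", "b", "c", "d"),
    tel_id = "5p", haplotype = c("1", "1", "1", "2"),
    length = c(10000, 12000, 14000, 8000),
    orientation = "forward",
    gap_haplotype_overestimate = c(FALSE, FALSE, FALSE, TRUE),
    overhang_labels_present = FALSE, clamped = FALSE,
    stringsAsFactors = FALSE),
    class = c("telomere_estimate", "data.frame"))
  s <- aggregate_lengths(est)
  g1 <- s[s$haplotype == "1", ]
  expect_equal(g1$mean, 12000)
  expect_equal(g1$sd, 2000)
  expect_equal(g1$n, 3L)
  expect_false(g1$gap)
  g2 <- s[s$haplotype == "2", ]
  expect_equal(g2$n, 1L)
  expect_true(is.na(g2$sd))
  expect_true(g2$gap)
  expect_identical(nrow(aggregate_lengths(est[0, ])), 0L)
})

test_that("simulated molecules over a 9 kb tract recover the tract length", {
  spec <- subtelomere_spec("t", tract = c(9000, 9000), seed = 401)
  b <- build_diploid_subtelomere(spec)
  ms <- simulate_molecules(b, sim_params(coverage = 35, seed = 402))
  alns <- align_molecules(ms, b$reference)
  est <- estimate_telomere_lengths(ms, alns, b$reference,
                                   one_copy_interval = c(120000, 270000))
  expect_gte(nrow(est), 30)
  expect_lt(abs(mean(est$length) - 9000),
            3 * sd(est$length) / sqrt(nrow(est)))
})

test_that("every estimate is invariant under molecule reversal", {
  spec <- subtelomere_spec("t", tract = c(9000, 7000), seed = 403)
  b <- build_diploid_subtelomere(spec)
  ms <- simulate_molecules(b, sim_params(coverage = 20, seed = 404))
  alns <- align_molecules(ms, b$reference)
  est <- estimate_telomere_lengths(ms, alns, b$reference,
                                   one_copy_interval = c(120000, 270000))
  ml <- ms$molecules
  names(ml) <- vapply(ml, `[[`, character(1), "id")
  for (id in est$molecule_id) {
    m <- ml[[id]]
    mr <- molecule(id, m$length, m$length - rev(m$labels))
    ar <- align_molecule(mr, b$reference)
    er <- estimate_telomere_length(mr, ar, b$reference)
    expect_equal(er$length, est$length[est$molecule_id == id],
                 tolerance = 1e-9)
  }
})

test_that("an unknown distal offset flags and overestimates by the unrepresented distance", {
  spec <- subtelomere_spec("gap", tract = c(9000, 9000),
                           distal_unrepresented = 10000,
                           distal_offset_known = FALSE, seed = 405)
  b <- build_diploid_subtelomere(spec)
  ms <- simulate_molecules(b, sim_params(coverage = 60,
                                         length_median = 350000,
                                         seed = 406))
  alns <- align_molecules(ms, b$reference)
  est <- estimate_telomere_lengths(ms, alns, b$reference,
                                   one_copy_interval = c(120000, 270000))
  expect_true(all(est$gap_haplotype_overestimate))
  # the law concerns molecules that truly contain the chromosome end
  term <- ms$truth$id[ms$truth$start == 0]
  e <- est$length[est$molecule_id %in% term]
  expect_gt(length(e), 30)
  expect_lt(abs(mean(e) - (9000 + 10000)), 1000)
})

test_that("negative overhangs clamp to zero with a flag", {
  ref <- build_reference_map("r", sites = c(2000, 30000, 60000, 90000),
                             length = 100000, arm = "p", distal_offset = 0)
  # first matched site slightly distal of the molecule start
  m <- molecule("m", 89500, c(1000, 29000, 59000, 89000))
  a <- align_molecule(m, ref, scoring_params(min_confidence = 0))
  e <- estimate_telomere_length(m, a, ref)
  expect_equal(e$length, 0)
  expect_true(e$clamped)
})

test_that("spurious labels in the overhang beyond the allowance are flagged", {
  ref <- build_reference_map("r", sites = c(30000, 60000, 120000),
                             length = 150000, arm = "p", distal_offset = 0)
  # 25 kb overhang with three unmatched labels in it (> 1 per 10 kb)
  m <- molecule("m", 160000, c(3000, 9000, 15000, 55000, 85000, 145000))
  a <- align_molecule(m, ref, scoring_params(min_confidence = 0))
  e <- estimate_telomere_length(m, a, ref)
  expect_equal(e$length, 25000)
  expect_true(e$overhang_labels_present)
})
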