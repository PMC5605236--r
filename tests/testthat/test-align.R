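fig5_ref <- function() build_reference_map(
  "5p", sites = c(12000, 37000, 162000), length = 200000, arm = "p",
  distal_offset = 0)

test_that("the worked-example molecule aligns forward with pairs (1,1),(2,2),(3,3)", {
  ref <- fig5_ref()
  m <- molecule("m", 205000, c(25000, 50000, 175000))
  a <- align_molecule(m, ref)
  expect_s3_class(a, "om_alignment")
  expect_equal(a$orientation, "forward")
  expect_equal(a$pairs$label, 1:3)
  expect_equal(a$pairs$site, 1:3)
  expect_gte(a$confidence, 20)
})

test_that("the reversed worked-example molecule aligns in reverse to sites 162/37/12", {
  ref <- fig5_ref()
  m <- molecule("m", 205000, c(30000, 155000, 180000))
  a <- align_molecule(m, ref)
  expect_s3_class(a, "om_alignment")
  expect_equal(a$orientation, "reverse")
  # label 1 (30 kb) matches the most centromeric site (162 kb)
  expect_equal(a$pairs$site_pos[a$pairs$label == 1], 162000)
  expect_equal(a$pairs$site_pos[a$pairs$label == 3], 12000)
  expect_gte(a$confidence, 20)
})

test_that("dynamic programming equals exhaustive pairing enumeration on random instances", {
  set.seed(201)
  par <- scoring_params(min_confidence = 0)
  n_cases <- 220
  for (case in seq_len(n_cases)) {
    n <- sample(2:8, 1); m <- sample(2:12, 1)
    R <- 150000
    v <- sort(sample(seq(2000, R - 2000, by = 500), m))
    L <- runif(1, 50000, 250000)
    labs <- sort(runif(n, 0, L * 0.98))
    while (any(diff(labs) < 50)) labs <- sort(runif(n, 0, L * 0.98))
    tel0 <- runif(1) < 0.5
    ref <- build_reference_map("r", sites = v, length = R,
                               arm = if (tel0) "p" else "q")
    a <- align_molecule(molecule("m", L, labs), ref, par)
    got <- if (is_alignment(a)) a$score else -Inf
    want <- oracle_best_score(labs, L, v, R, tel0, par)
    if (!is.finite(want)) expect_false(is_alignment(a))
    else expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("alignment score and matched sites are invariant under molecule reversal", {
  set.seed(202)
  h <- synthetic_hap("h", seed = 203)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  ms <- simulate_molecules(list(h), sim_params(coverage = 4, seed = 204))
  par <- scoring_params(min_confidence = 0)
  for (m in head(ms$molecules, 10)) {
    a <- align_molecule(m, ref, par)
    mr <- molecule(m$id, m$length, m$length - rev(m$labels))
    ar <- align_molecule(mr, ref, par)
    expect_equal(a$score, ar$score, tolerance = 1e-9)
    expect_equal(sort(a$pairs$site), sort(ar$pairs$site))
    expect_true(a$orientation != ar$orientation)
  }
})

test_that("noise-free molecules with >= 5 labels recover their true placement and orientation", {
  h <- synthetic_hap("h", seed = 205)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  ms <- simulate_molecules(list(h), sim_params(
    coverage = 25, fn_rate = 0, fp_rate = 0,
    sizing_rel_sd = 0, sizing_abs_sd = 0, seed = 206))
  n_ok <- 0; n_tot <- 0
  for (k in seq_along(ms$molecules)) {
    m <- ms$molecules[[k]]
    if (length(m$labels) < 5) next
    n_tot <- n_tot + 1
    a <- align_molecule(m, ref)
    tr <- ms$truth[k, ]
    if (is_alignment(a) &&
        (a$orientation == "reverse") == tr$reversed &&
        abs(a$offset - (tr$start - h$tract_length)) < 2000)
      n_ok <- n_ok + 1
  }
  expect_gt(n_tot, 30)
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("sizing noise does not increase the expected score of true alignments", {
  h <- synthetic_hap("h", seed = 207)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  p0 <- sim_params(coverage = 10, fn_rate = 0, fp_rate = 0,
                   sizing_rel_sd = 0, sizing_abs_sd = 0, seed = 208)
  p1 <- sim_params(coverage = 10, fn_rate = 0, fp_rate = 0, seed = 208)
  sc <- function(p) {
    ms <- simulate_molecules(list(h), p)
    mean(vapply(align_molecules(ms, ref), `[[`, numeric(1), "score"))
  }
  expect_gte(sc(p0), sc(p1))
})

test_that("anchor_check tests matched sites against the 1-copy interval", {
  ref <- build_reference_map("r", sites = c(10000, 50000, 140000, 180000),
                             length = 300000)
  m <- molecule("m", 200000, c(11000, 51000, 141000, 181000) - 1000)
  a <- align_molecule(m, ref, scoring_params(min_confidence = 0))
  expect_true(is_alignment(a))
  # matched sites all within [0, 120k) SRE region -> not anchored there
  expect_false(anchor_check(a, ref, c(200000, 300000)))
  expect_true(anchor_check(a, ref, c(140000, 300000)))   # half-open start
  expect_false(anchor_check(a, ref, c(180001, 300000)))
  expect_false(anchor_check(NULL, ref, c(0, 1)))
})

test_that("detect_outliers recovers planted insertion and deletion sizes", {
  set.seed(209)
  # irregular spacing: a deletion cannot re-lock onto a shifted phase
  v <- cumsum(pmax(rexp(45, 1 / 9300), 3000)) + 10000
  v <- round(v[v < 390000])
  ref <- build_reference_map("r", sites = v, length = 400000)
  # noise-free molecule from a haplotype with a 50 kb insertion after site 10
  ins_at <- v[10] + (v[11] - v[10]) / 2
  hap_sites <- c(v[v <= ins_at], v[v > ins_at] + 50000)
  m <- molecule("m", max(hap_sites) + 5000, hap_sites)
  a <- align_molecule(m, ref, scoring_params(min_confidence = 0))
  out <- detect_outliers(a, min_size = 20000)
  expect_equal(nrow(out), 1L)
  expect_equal(out$size_delta, 50000, tolerance = 1e-6)
  expect_equal(out$ref_start, v[10])

  # concordant molecule: no outliers
  m0 <- molecule("m0", max(v) + 5000, v)
  a0 <- align_molecule(m0, ref, scoring_params(min_confidence = 0))
  expect_identical(nrow(detect_outliers(a0, 5000)), 0L)

  # simulated 35 kb deletion under default sizing noise
  del_sites <- c(v[v < v[20]], v[v >= v[20] + 35000] - 35000)
  h <- haplotype_truth("d", 400000 - 35000 + 5000, del_sites,
                       tract_length = 0)
  ms <- simulate_molecules(list(h), sim_params(
    coverage = 6, fn_rate = 0, fp_rate = 0, seed = 210))
  hits <- c()
  for (k in seq_along(ms$molecules)) {
    tr <- ms$truth[k, ]
    if (tr$start > v[19] - 20000 || tr$end < v[20] + 45000) next
    a <- align_molecule(ms$molecules[[k]], ref,
                        scoring_params(min_confidence = 0))
    out <- detect_outliers(a, min_size = 20000)
    expect_gte(nrow(out), 1)
    hits <- c(hits, out$size_delta[which.max(abs(out$size_delta))])
  }
  expect_gt(length(hits), 2)
  expect_lt(abs(mean(hits) + 35000), 3 * 0.03 * 45000)
})

test_that("molecules with fewer than 2 labels or weak patterns are not reported", {
  ref <- fig5_ref()
  a0 <- align_molecule(molecule("m", 100000, 50000), ref)
  expect_false(is_alignment(a0))
  expect_equal(a0$reason, "unalignable")

  # a short 2-label molecule carries too little evidence for threshold 20
  a1 <- align_molecule(molecule("m", 30000, c(5000, 21000)), ref)
  expect_false(is_alignment(a1))
  expect_equal(a1$reason, "low_confidence")
})

test_that("random molecules essentially never reach the confidence threshold (decoy calibration)", {
  set.seed(211)
  h <- synthetic_hap("h", seed = 212)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  decoys <- decoy_maps(ref, 3)
  n_pass <- 0; n_tot <- 0
  for (rep in 1:120) {
    L <- runif(1, 150000, 350000)
    labs <- sort(runif(rpois(1, L / 9300), 0, L))
    if (length(labs) < 2 || any(diff(labs) < 10)) next
    m <- molecule(paste0("r", rep), L, labs)
    for (d in decoys) {
      n_tot <- n_tot + 1
      if (is_alignment(align_molecule(m, d))) n_pass <- n_pass + 1
    }
  }
  expect_gt(n_tot, 200)
  expect_lte(n_pass / n_tot, 0.001 + 3 * sqrt(0.001 / n_tot))
})
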