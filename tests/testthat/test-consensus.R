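noise_free_params <- function(coverage, seed)
  sim_params(coverage = coverage, fn_rate = 0, fp_rate = 0,
             sizing_rel_sd = 0, sizing_abs_sd = 0, seed = seed)

test_that("noise-free molecules from one haplotype reproduce the truth map exactly", {
  h <- synthetic_hap("h", seed = 301)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  ms <- simulate_molecules(list(h), noise_free_params(30, 302))
  alns <- align_molecules(ms, ref)
  cons <- build_consensus(alns, ms, ref)
  matched <- vapply(cons$sites, function(p) min(abs(ref$sites - p)),
                    numeric(1))
  expect_true(all(matched < 1e-6))
  # every well-covered reference site is recovered
  covered <- ref$sites[ref$sites > 20000 & ref$sites < ref$length - 20000]
  rec <- vapply(covered, function(p) min(abs(cons$sites - p)), numeric(1))
  expect_true(all(rec < 1e-6))
})

test_that("telomere-adjacent sequence absent from the reference is recovered as distal extension", {
  spec <- subtelomere_spec("17q", tract = c(10000, 10000),
                           distal_unrepresented = 130000,
                           distal_offset_known = FALSE,
                           one_copy_length = 200000, seed = 303)
  b <- build_diploid_subtelomere(spec)
  ms <- simulate_molecules(b, sim_params(coverage = 40,
                                         length_median = 300000,
                                         seed = 304))
  alns <- align_molecules(ms, b$reference)
  cons <- build_consensus(alns, ms, b$reference)
  # the most distal nick site sits one site-spacing short of the full 130 kb
  expect_gt(cons$extension_length, 130000 - 15000)
  expect_lt(cons$extension_length, 130000 + 5000)
  svs <- call_svs(cons, b$reference)
  expect_true("distal_extension" %in% svs$type)
  expect_equal(svs$code[svs$type == "distal_extension"], "g")
})

test_that("consensus site error shrinks with support as an average of projections", {
  h <- synthetic_hap("h", seed = 305)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  ms <- simulate_molecules(list(h), sim_params(coverage = 40, fn_rate = 0,
                                               fp_rate = 0, seed = 306))
  alns <- align_molecules(ms, ref)
  cons <- build_consensus(alns, ms, ref)
  near <- vapply(cons$sites, function(p) which.min(abs(ref$sites - p)),
                 integer(1))
  err <- cons$sites - ref$sites[near]
  # per-molecule projected positions scatter by a few hundred bp; the
  # consensus averages over `support` molecules
  per_mol_sd <- 600
  lim <- 3 * per_mol_sd / sqrt(pmax(cons$support, 1))
  expect_lt(sqrt(mean(err^2)), max(lim))
  expect_true(mean(abs(err) <= lim) > 0.9)
})

test_that("consensus built from molecules simulated off a consensus recovers it", {
  h <- synthetic_hap("h", seed = 307)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  ms <- simulate_molecules(list(h), sim_params(coverage = 30, seed = 308))
  cons1 <- build_consensus(align_molecules(ms, ref), ms, ref)
  # treat the consensus as truth and resimulate
  h2 <- haplotype_truth("c", h$length, cons1$sites + h$tract_length,
                        h$tract_length)
  ms2 <- simulate_molecules(list(h2), sim_params(coverage = 30, seed = 309))
  cons2 <- build_consensus(align_molecules(ms2, ref), ms2, ref)
  common <- vapply(cons2$sites, function(p) min(abs(cons1$sites - p)),
                   numeric(1))
  expect_gt(mean(common < 1500), 0.95)     # no spurious sites, tight match
})

test_that("a haplotype lacking one nick site splits molecules on site presence", {
  sc <- scenario_preset("fig2_15q_three_haplotypes", seed = 310)
  res <- run_scenario(sc, seed = 310)
  groups <- res$run$groups
  expect_length(groups, 2)
  f <- groups[[1]]$features
  expect_true("site_presence" %in% f$type)
  # the discriminating site sits where the nick_site_loss edit was planted
  expect_lt(abs(f$position[f$type == "site_presence"][1] - 62000), 10000)
  vals <- vapply(groups, function(g)
    g$features$value[g$features$type == "site_presence"][1], numeric(1))
  expect_setequal(vals, c(0, 1))
})

test_that("a homozygous simulation yields a single haplotype group", {
  h <- synthetic_hap("h", seed = 311)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  ms <- simulate_molecules(list(h, h), sim_params(coverage = 25, seed = 312))
  alns <- align_molecules(ms, ref)
  groups <- cluster_haplotypes(alns, ms, ref)
  expect_length(groups, 1)
  expect_equal(sort(groups[[1]]$members), sort(names(alns)))
})

test_that("tandem-array alleles of 12 vs 19 copies split on interval length with ~40 and ~62 kb modes", {
  sc <- scenario_preset("d4z4_array", seed = 313)
  res <- run_scenario(sc, seed = 313)
  groups <- res$run$groups
  expect_length(groups, 2)
  # recovered interval modes differ by the array lengths (array + flank)
  iv <- vapply(groups, function(g)
    g$features$value[g$features$type == "interval_length"][1], numeric(1))
  expect_equal(abs(diff(iv)), 7 * 3300, tolerance = 0.15)
  # assignment accuracy vs simulator truth
  tr <- res$mols$truth
  acc <- sum(vapply(groups, function(g)
    max(table(tr$hap[match(g$members, tr$id)])), numeric(1)))
  tot <- sum(vapply(groups, function(g) length(g$members), numeric(1)))
  expect_gte(acc / tot, 0.95)
})

test_that("call_svs reports nothing for a concordant consensus", {
  h <- synthetic_hap("h", seed = 314)
  ref <- build_reference_map("r", sites = h$sites - h$tract_length,
                             length = h$length - h$tract_length)
  ms <- simulate_molecules(list(h), sim_params(coverage = 25, seed = 315))
  cons <- build_consensus(align_molecules(ms, ref), ms, ref)
  expect_identical(nrow(call_svs(cons, ref)), 0L)
})

test_that("insertion and deletion call sizes are calibrated on random planted SVs", {
  set.seed(316)
  n_cases <- 50
  errs <- numeric(0); spans <- numeric(0)
  for (case in seq_len(n_cases)) {
    h0 <- synthetic_hap(paste0("h", case), backbone_len = 300000,
                        seed = 316 + case)
    ref <- build_reference_map("r", sites = h0$sites - h0$tract_length,
                               length = h0$length - h0$tract_length)
    size <- runif(1, 20000, 150000)
    at <- runif(1, 60000, 200000)
    v <- h0$sites
    is_del <- runif(1) < 0.5 && size < 60000
    if (is_del) {
      sites <- c(v[v < at], v[v >= at + size] - size)
      len <- h0$length - size
      size <- -size
    } else {
      sites <- c(v[v < at], v[v >= at] + size)
      len <- h0$length + size
    }
    h <- haplotype_truth("v", len, sites, h0$tract_length)
    ms <- simulate_molecules(list(h), sim_params(coverage = 22, seed = case))
    cons <- build_consensus(align_molecules(ms, ref), ms, ref)
    calls <- call_svs(cons, ref, min_size = 15000)
    calls <- calls[calls$type %in% c("insertion", "deletion"), ]
    if (nrow(calls) == 0) { errs <- c(errs, abs(size)); next }
    got <- calls$size[which.max(calls$size)] *
      ifelse(calls$type[which.max(calls$size)] == "deletion", -1, 1)
    errs <- c(errs, abs(got - size))
    spans <- c(spans, abs(size) + 15000)
  }
  # mean absolute size error within twice the sizing SD of the spanned
  # interval
  expect_lt(mean(errs), mean(2 * 0.03 * (abs(spans) + 10000)))
})

test_that("haplotype-specific calls carry the h code and shared codes stay plain", {
  calls1 <- structure(data.frame(
    tel_id = "t", type = c("insertion", "gap_fill"),
    position = c(50000, 150000), size = c(50000, 30000),
    haplotype = "1", support = c(10L, 8L), code = c("sv", "g"),
    stringsAsFactors = FALSE), class = c("sv_calls", "data.frame"))
  calls2 <- structure(data.frame(
    tel_id = "t", type = "gap_fill",
    position = 150000, size = 32000,
    haplotype = "2", support = 9L, code = "g",
    stringsAsFactors = FALSE), class = c("sv_calls", "data.frame"))
  out <- annotate_haplotype_codes(list(calls1, calls2))
  expect_equal(out$code[out$type == "insertion"], "h+sv")
  expect_equal(out$code[out$type == "gap_fill"], c("g", "g"))
  expect_true(all(unlist(strsplit(out$code, "\\+")) %in% c("g", "h", "sv")))
  # single group: no h codes at all
  out1 <- annotate_haplotype_codes(list(calls1))
  expect_false(any(grepl("h", out1$code)))
})

test_that("trio transmission is recovered on a simulated trio", {
  tr <- trio_scenario(seed = 1)
  runs <- lapply(names(tr$individuals), function(nm) {
    b <- tr$individuals[[nm]]
    ms <- simulate_molecules(b, sim_params(coverage = 25,
                                           seed = sum(utf8ToInt(nm))))
    run_subtelomere_pipeline(b$reference, ms, tr$one_copy_interval)
  })
  names(runs) <- names(tr$individuals)
  expect_length(runs$child$groups, 2)
  tc <- trio_consistency(runs$child$groups, runs$parent1$groups,
                         runs$parent2$groups)
  expect_true(tc$consistent)
  expect_false(tc$ambiguous)
  # identify child groups by the discriminating nick site: the insertion
  # carrier (B, site present) must come from parent1, the missing-site
  # carrier (C) from parent2
  site_val <- vapply(runs$child$groups, function(g) {
    v <- g$features$value[g$features$type == "site_presence"]
    if (length(v)) v[1] else NA_real_
  }, numeric(1))
  expect_equal(tc$assignment$parent[which(site_val == 1)], "parent1")
  expect_equal(tc$assignment$parent[which(site_val == 0)], "parent2")
})

test_that("trio edge cases: indistinguishable parents and planted violations", {
  mk_cons <- function(sites, iv = diff(sites)) structure(
    list(tel_id = "t", haplotype = "1", sites = sites,
         support = rep(10L, length(sites)),
         spanning = rep(10L, length(sites)),
         interval_len = iv, extension_length = 0, members = character(0)),
    class = "consensus_map")
  a <- mk_cons(c(10000, 30000, 55000, 90000))
  # both parents homozygous for the same allele: consistent but ambiguous
  tc <- trio_consistency(list(a), list(a, a), list(a, a))
  expect_true(tc$consistent)
  expect_true(tc$ambiguous)
  # child haplotype absent from both parents: inconsistency flagged
  b <- mk_cons(c(10000, 30000, 45000, 62000, 90000))
  d <- mk_cons(c(10000, 41000, 77000, 95000))
  tc2 <- trio_consistency(list(b), list(a, a), list(d, d))
  expect_false(tc2$consistent)
})
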