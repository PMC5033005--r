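test_that("degenerate rates and determinism behave as contracted", {
  cfg <- sim_config(n_probes = 30, sites_per_probe = 5, het_parentA = 0,
                    seed = 5)
  truth <- simulate_parents(cfg)
  gut <- panel_samples(truth$panel, "parentA")
  for (s in gut) {
    expect_true(all(truth$copies[, s, 1L] == 0L | truth$copies[, s, 2L] == 0L))
  }

  cfg2 <- sim_config(n_probes = 30, sites_per_probe = 5, seed = 17)
  t1 <- form_hybrids(simulate_parents(cfg2))
  t2 <- form_hybrids(simulate_parents(cfg2))
  expect_identical(t1$copies, t2$copies)
  expect_identical(t1$sites, t2$sites)
  # bit-identical VCF under the same config
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_vcf(simulate_reads(t1), f1)
  write_vcf(simulate_reads(t2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reciprocally fixed sites occur at the configured rate", {
  n <- 10000L
  cfg <- sim_config(n_probes = 1000, sites_per_probe = 10, d_fixed = 0.05,
                    n_parentA = 1, n_parentB = 1, n_hybrid3x = 0,
                    n_hybrid6x = 0, seed = 23)
  truth <- simulate_parents(cfg)
  observed <- nrow(truth_diagnostic_sites(truth))
  expected <- n * 0.05
  sd4 <- 4 * sqrt(n * 0.05 * 0.95)
  expect_gt(observed, expected - sd4)
  expect_lt(observed, expected + sd4)
})

test_that("copy counts are conserved and hybrids have the expected dosage", {
  sim <- small_sim(29, n_probes = 50, sites_per_probe = 4)
  truth <- sim$truth
  tot <- rowSums(truth$copies, dims = 2L)
  for (i in seq_len(nrow(truth$panel))) {
    expect_true(all(tot[, truth$panel$sample_id[i]] == truth$panel$ploidy[i]))
  }
  # at reciprocally fixed sites a triploid carries 1 parentA : 2 parentB
  td <- truth_diagnostic_sites(truth)
  a_idx <- ifelse(td$a_is_ref, 1L, 2L)
  for (s in panel_samples(truth$panel, "hybrid3x")) {
    cpA <- truth$copies[cbind(td$site, match(s, truth$samples), a_idx)]
    expect_true(all(cpA == 1L))
  }
  for (s in panel_samples(truth$panel, "hybrid6x")) {
    cpA <- truth$copies[cbind(td$site, match(s, truth$samples), a_idx)]
    expect_true(all(cpA == 2L))
  }
})

test_that("a hexaploid with no events is exactly its doubled triploid", {
  cfg <- sim_config(n_probes = 40, sites_per_probe = 5, seed = 31,
                    n_hybrid3x = 2, n_hybrid6x = 2)
  truth <- form_hybrids(simulate_parents(cfg))
  expect_identical(truth$copies[, "per-1", ], 2L * truth$copies[, "rob-1", ])
  expect_identical(truth$copies[, "per-2", ], 2L * truth$copies[, "rob-2", ])
  expect_equal(nrow(truth$events), 0L)
})

test_that("events change exactly the targeted copies and are logged", {
  base <- sim_config(n_probes = 140, sites_per_probe = 5, d_fixed = 0.3,
                     seed = 37)
  t0 <- form_hybrids(simulate_parents(base))
  span <- terminal_informative_span(t0, "rob-1", "LG01", 10)
  ev <- event_spec("single_copy_conversion", "per-1", chrom = "LG01",
                   start = span$start, end = span$end, allele = "ref")
  cfg <- sim_config(n_probes = 140, sites_per_probe = 5, d_fixed = 0.3,
                    seed = 37, events = list(ev))
  t1 <- form_hybrids(simulate_parents(cfg))
  # diff the truth before/after: every changed cell is inside the span,
  # belongs to per-1, and moved exactly one copy to the reference allele
  delta <- t1$copies - t0$copies
  changed <- which(delta != 0, arr.ind = TRUE)
  expect_true(all(t1$samples[changed[, 2]] == "per-1"))
  in_span <- t0$sites$chrom == "LG01" & t0$sites$pos >= span$start &
    t0$sites$pos <= span$end
  expect_true(all(in_span[changed[, 1]]))
  d1 <- delta[, "per-1", 1L]; d2 <- delta[, "per-1", 2L]
  expect_true(all(d1 %in% c(0L, 1L)) && all(d2 %in% c(0L, -1L)))
  expect_identical(d1, -d2)
  expect_equal(sort(unique(t1$events$pos)),
               sort(t0$sites$pos[d1 != 0]))
  # events targeting a non-hybrid sample are refused
  bad <- sim_config(n_probes = 140, sites_per_probe = 5, d_fixed = 0.3,
                    seed = 37,
                    events = list(event_spec("single_copy_conversion",
                                             "gut-1", chrom = "LG01",
                                             start = 1, end = 100)))
  expect_error(form_hybrids(simulate_parents(bad)), "non-hybrid")
})

test_that("read fractions converge to copy fractions at high depth", {
  cfg <- sim_config(n_probes = 60, sites_per_probe = 5, depth_mean = 5000,
                    bias = 1, error = 0, seed = 41,
                    n_parentA = 1, n_parentB = 1, n_hybrid3x = 1,
                    n_hybrid6x = 1)
  sim <- simulate_panel(cfg)
  f_obs <- ref_freq(sim$adm)
  for (s in sim$adm$samples) {
    cp <- sim$truth$copies[, s, ]
    f_true <- cp[, 1L] / rowSums(cp)
    expect_lt(mean(abs(f_obs[, s] - f_true)), 0.01)
    expect_lt(max(abs(f_obs[, s] - f_true)), 0.05)
  }
})

test_that("capture bias follows the closed-form odds model", {
  # GGLLLL at a diagnostic site whose reference is the parentA allele:
  # expected parentA read fraction (2*beta) / (2*beta + 4)
  cfg <- sim_config(n_probes = 400, sites_per_probe = 5, d_fixed = 0.6,
                    het_parentA = 0, het_parentB = 0, depth_mean = 400,
                    bias = 2, error = 0, seed = 43,
                    n_parentA = 1, n_parentB = 1, n_hybrid3x = 1,
                    n_hybrid6x = 1)
  sim <- simulate_panel(cfg)
  td <- truth_diagnostic_sites(sim$truth)
  ef <- expected_allele_fraction(sim$truth, "per-1")
  ref_sites <- td$site[td$a_is_ref]
  alt_sites <- td$site[!td$a_is_ref]
  expect_equal(unique(ef[ref_sites, 1L]), (2 * 2) / (2 * 2 + 4))
  expect_equal(unique(ef[alt_sites, 2L]), 2 / (2 + 4 * 2))
  # realized read fractions agree with the model expectation
  f_obs <- ref_freq(sim$adm)[, "per-1"]
  expect_lt(abs(mean(f_obs[ref_sites]) - 0.5), 0.01)
  # zero-depth config yields an all-zero matrix via lambda -> 0 limit
  cfg0 <- sim_config(n_probes = 10, sites_per_probe = 2, depth_mean = 1e-9,
                     seed = 2, n_parentA = 1, n_parentB = 1,
                     n_hybrid3x = 0, n_hybrid6x = 0)
  expect_true(all(simulate_panel(cfg0)$adm$depth == 0L))
})

test_that("truth tables agree with brute-force scans of the copy counts", {
  sim <- small_sim(47, n_probes = 60, sites_per_probe = 5)
  truth <- sim$truth
  het <- truth_het_fraction(truth)
  for (s in c("gut-1", "lut-2", "rob-3", "per-4")) {
    cp <- truth$copies[, s, ]
    expect_equal(unname(het[s]), mean(cp[, 1] > 0 & cp[, 2] > 0))
  }
  td <- truth_diagnostic_sites(truth)
  brute <- vapply(seq_len(nrow(truth$sites)), function(i) {
    gut <- truth$copies[i, panel_samples(truth$panel, "parentA"), ]
    lut <- truth$copies[i, panel_samples(truth$panel, "parentB"), ]
    all(gut[, 2] == 0) && all(lut[, 1] == 0) ||
      all(gut[, 1] == 0) && all(lut[, 2] == 0)
  }, logical(1))
  expect_identical(td$site, which(brute))

  d <- withr::local_tempdir()
  emit_truth_tables(truth, d)
  expect_equal(read_table(file.path(d, "truth_het.tsv"))$truth_het,
               unname(het), tolerance = 1e-10)
  expect_equal(nrow(read_table(file.path(d, "truth_diagnostic_sites.tsv"))),
               nrow(td))
  # empty event log still writes a header-only table
  expect_named(read_table(file.path(d, "truth_events.tsv")),
               c("kind", "sample", "chrom", "pos", "allele", "copies_changed"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_probes = 10, sites_per_probe = 2), "seed")
  expect_error(sim_config(seed = 1, d_fixed = 0.5, het_parentA = 0.2,
                          het_parentB = 0.2), "exceeds 1")
  expect_error(sim_config(seed = 1, error = 0.6), "error")
  expect_error(sim_config(seed = 1, bias = 0), "bias")
})
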