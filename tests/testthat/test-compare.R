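cmp_panel <- function() {
  as_sample_panel(data.frame(
    sample_id = c("gA", "lB", "rob", "per"),
    taxon = c("guttatus", "luteus", "robertsii", "peregrinus"),
    ploidy = c(2L, 4L, 3L, 6L),
    role = c("parentA", "parentB", "hybrid3x", "hybrid6x"),
    population = "P", stringsAsFactors = FALSE))
}

test_that("unique hybrid alleles obey the strict frequency thresholds", {
  panel <- cmp_panel()
  # columns: gA, lB, rob, per; values are reference-allele frequencies so
  # the alternate-allele frequency is 1 - f
  f <- rbind(c(1.00, 1.00, 0.80, 1.00),   # rob alt freq 0.20, parents 0 -> hit
             c(1.00, 1.00, 0.88, 1.00),   # rob alt freq 0.12 <= 0.167 -> no
             c(1.00, 0.85, 0.80, 1.00),   # a parent carries it at 0.15 -> no
             c(1.00, 1.00, 1.00, 0.70))   # per alt freq 0.30 -> hit
  adm <- adm_from_freq(f, depth = 100L, samples = panel$sample_id)
  res <- unique_hybrid_alleles(adm, panel)
  expect_equal(res$n_tested, 4L)
  expect_equal(res$events$site, c(1L, 4L))
  expect_equal(res$events$sample, c("rob", "per"))
  expect_equal(res$events$freq, c(0.20, 0.30), tolerance = 1e-12)
})

test_that("gained alleles require triploid fixation and a 1/6 hexaploid dose", {
  panel <- cmp_panel()
  f <- rbind(c(1, 1, 0.95, 0.82),   # rob fixed ref, per alt 0.18 -> gain
             c(1, 1, 0.95, 0.90),   # per alt 0.10 < 0.167 -> no
             c(1, 1, 0.80, 0.60),   # rob not fixed -> not even tested
             c(1, 1, 0.05, 0.30))   # rob fixed for the alternate -> gain of ref? no: per ref 0.3 >= 0.167 -> hit
  adm <- adm_from_freq(f, depth = 100L, samples = panel$sample_id)
  res <- gained_alleles(adm, panel, "rob", "per")
  expect_equal(sort(res$events$site), c(1L, 4L))
  expect_equal(res$n_tested, 3L)  # sites 1, 2 (ref-fixed) and 4 (alt-fixed)
  expect_equal(res$summary$n_loci, 2L)
  # inclusive gain bound: exactly 0.167 qualifies
  f2 <- rbind(c(1, 1, 0.95, 1 - 0.167))
  adm2 <- adm_from_freq(f2, depth = 1000L, samples = panel$sample_id)
  expect_equal(nrow(gained_alleles(adm2, panel, "rob", "per")$events), 1L)
  expect_error(gained_alleles(adm, panel, character(0), "per"), "scope")
})

test_that("lost alleles require triploid heterozygosity and hexaploid homozygosity", {
  panel <- cmp_panel()
  f <- rbind(c(1, 1, 0.33, 0.95),   # rob het, per hom ref -> loss
             c(1, 1, 0.33, 0.85),   # per 0.85 not beyond 0.9 -> no
             c(1, 1, 0.33, 0.05),   # per hom alt -> loss
             c(1, 1, 0.95, 0.95))   # rob not het -> untested
  adm <- adm_from_freq(f, depth = 100L, samples = panel$sample_id)
  res <- lost_alleles(adm, panel, "rob", "per")
  expect_equal(res$events$site, c(1L, 3L))
  expect_equal(res$n_tested, 3L)
  expect_equal(res$events$lost_allele, c("C", "A"))
})

test_that("event counts are monotone in their thresholds", {
  sim <- small_sim(157, n_probes = 150, sites_per_probe = 5, d_fixed = 0.2,
                   depth_mean = 80)
  snp <- filter_sites(sim$adm, polymorphic_only = TRUE)$matrix
  panel <- sim$panel
  rob <- panel_samples(panel, "hybrid3x")
  per <- panel_samples(panel, "hybrid6x")
  qs <- c(0.05, 0.1, 0.2, 0.3)
  uq <- vapply(qs, function(q)
    nrow(unique_hybrid_alleles(snp, panel, q_min = q)$events), numeric(1))
  expect_true(all(diff(uq) <= 0))
  ga <- vapply(qs, function(q)
    nrow(gained_alleles(snp, panel, rob, per, gain_min = q)$events),
    numeric(1))
  expect_true(all(diff(ga) <= 0))
})

test_that("global events reappear in the corresponding local pair", {
  sim <- small_sim(163, n_probes = 200, sites_per_probe = 5, d_fixed = 0.2,
                   depth_mean = 100)
  snp <- filter_sites(sim$adm, polymorphic_only = TRUE)$matrix
  panel <- sim$panel
  rob <- panel_samples(panel, "hybrid3x")
  per <- panel_samples(panel, "hybrid6x")
  glob <- gained_alleles(snp, panel, rob, per)$events
  if (nrow(glob)) {
    for (k in seq_len(nrow(glob))) {
      s6 <- glob$sample[k]
      s3 <- panel$local_pair[panel$sample_id == s6]
      pair_ev <- gained_alleles(snp, panel, s3, s6, scope = "pair")$events
      expect_true(glob$site[k] %in% pair_ev$site)
    }
  } else {
    succeed("no global gains in this draw; nothing to cross-check")
  }
})

test_that("window means track constant differences and identical samples", {
  panel <- cmp_panel()
  n <- 12L
  f <- cbind(rep(1, n), rep(1, n), rep(0.5, n), rep(0.5 + 1 / 6, n))
  adm <- adm_from_freq(f, depth = 600L, samples = panel$sample_id)
  sc <- window_scan(adm, "rob", "per", window = 10)
  expect_equal(nrow(sc), 3L)
  expect_equal(sc$mean_diff, rep(1 / 6, 3), tolerance = 1e-3)

  same <- window_scan(adm, "rob", "rob", window = 10)
  expect_true(all(same$mean_diff == 0))

  # fewer informative sites than the window: no rows, linkage group logged
  few <- adm_subset(adm, 1:5)
  sc2 <- window_scan(few, "rob", "per", window = 10)
  expect_equal(nrow(sc2), 0L)
  expect_equal(attr(sc2, "skipped"), "LG01")
})

test_that("window means are reversal-invariant up to re-indexing", {
  sim <- small_sim(167, n_probes = 30, sites_per_probe = 6, d_fixed = 0.3,
                   depth_mean = 100, n_linkage_groups = 1)
  snp <- filter_sites(sim$adm, polymorphic_only = TRUE)$matrix
  sc <- window_scan(snp, "rob-1", "per-1", window = 5)
  flipped <- snp
  flipped$sites$pos <- max(flipped$sites$pos) + 1L - flipped$sites$pos
  flipped <- adm_subset(flipped, order(flipped$sites$pos))
  sc_r <- window_scan(flipped, "rob-1", "per-1", window = 5)
  expect_equal(sort(round(sc_r$mean_diff, 10)),
               sort(round(sc$mean_diff, 10)))
})

test_that("run detection finds maximal qualifying runs without gap merging", {
  scan <- data.frame(chrom = "LG14", win = 1:20,
                     start = seq(100, by = 100, length.out = 20),
                     end = seq(1000, by = 100, length.out = 20),
                     n_sites = 10,
                     mean_diff = c(rep(0, 3), rep(0.18, 8), 0.02,
                                   rep(-0.15, 6), rep(0, 2)),
                     mean_abs_diff = NA, stringsAsFactors = FALSE)
  runs <- detect_runs(scan, min_abs = 0.1, min_windows = 5)
  expect_equal(nrow(runs), 2L)  # the sub-threshold window splits the runs
  expect_equal(runs$n_windows, c(8L, 6L))
  expect_equal(runs$mean_diff, c(0.18, -0.15), tolerance = 1e-12)
  # brute-force oracle over all windows
  qual <- abs(scan$mean_diff) >= 0.1
  r <- rle(qual)
  expect_equal(sum(r$values & r$lengths >= 5), nrow(runs))
  # an all-zero scan yields no regions
  scan$mean_diff <- 0
  expect_equal(nrow(detect_runs(scan)), 0L)
})

test_that("an injected terminal conversion produces the 1/6 plateau", {
  mk <- function(events = list()) {
    sim_config(n_probes = 100, sites_per_probe = 10, n_linkage_groups = 2,
               depth_mean = 150, error = 0, seed = 173,
               n_parentA = 1, n_parentB = 1, n_hybrid3x = 1, n_hybrid6x = 1,
               events = events)
  }
  t0 <- form_hybrids(simulate_parents(mk()))
  span <- terminal_informative_span(t0, "rob-1", "LG01", 30)
  ev <- event_spec("single_copy_conversion", "per-1", chrom = "LG01",
                   start = span$start, end = span$end, allele = "ref")
  sim <- simulate_panel(mk(list(ev)))
  snp <- filter_sites(sim$adm, polymorphic_only = TRUE)$matrix
  sc <- window_scan(snp, "rob-1", "per-1", window = 10)
  inside <- sc$chrom == "LG01" & sc$start >= span$start & sc$end <= span$end
  expect_gte(sum(inside), 10L)
  plateau <- mean(sc$mean_diff[inside])
  f <- ref_freq(snp)
  site_d <- (f[, "per-1"] - f[, "rob-1"])[
    snp$sites$chrom == "LG01" & snp$sites$pos >= span$start &
      f[, "rob-1"] >= 0.1 & f[, "rob-1"] <= 0.9]
  se <- sd(site_d) / sqrt(length(site_d))
  expect_lt(abs(plateau - 1 / 6), 2 * se + 1e-6)
  # and the region detector flags a run overlapping the event span
  # (boundary windows straddling the span edge may extend the run left)
  runs <- detect_runs(sc)
  expect_true(any(runs$chrom == "LG01" & runs$end >= span$start &
                    runs$start <= span$end))
})
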