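# Fixture builders shared across the suite. Everything is constructed in
# code; no binary or stored data.

# Build an allele_depth_matrix directly from ref/alt count matrices.
make_adm <- function(ref_counts, alt_counts, samples = NULL,
                     chrom = NULL, pos = NULL, ref = "A", alt = "C",
                     missing = NULL) {
  n <- nrow(ref_counts)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(ref_counts)))
  if (is.null(chrom)) chrom <- rep("LG01", n)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  depth <- array(0L, dim = c(n, length(samples), 2L))
  depth[, , 1L] <- as.integer(ref_counts)
  depth[, , 2L] <- as.integer(alt_counts)
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      stringsAsFactors = FALSE)
  allele_depth_matrix(sites, samples, depth, missing = missing)
}

# A matrix whose cells have exact reference-allele frequencies f at a
# fixed total depth.
adm_from_freq <- function(f, depth = 100L, ...) {
  f <- as.matrix(f)
  ref_counts <- round(f * depth)
  make_adm(ref_counts, depth - ref_counts, ...)
}

# A 16-sample panel mirroring the study design (4 samples per taxon).
study_panel <- function() {
  build_panel(sim_config(seed = 1))
}

# Small full simulation; defaults keep tests fast.
small_sim <- function(seed, n_probes = 100, sites_per_probe = 10, ...) {
  simulate_panel(sim_config(n_probes = n_probes,
                            sites_per_probe = sites_per_probe,
                            seed = seed, ...))
}

# Independent brute-force re-implementation of the site filters, used as
# the oracle for filter_sites.
brute_force_filter <- function(x, min_depth = 50, polymorphic_only = FALSE,
                               lo = 0.1, hi = 0.9) {
  keep <- logical(n_sites(x))
  for (i in seq_len(n_sites(x))) {
    tots <- sapply(seq_along(x$samples), function(s) sum(x$depth[i, s, ]))
    if (any(tots < min_depth) || any(x$missing[i, ])) next
    n_obs <- sum(sapply(seq_len(dim(x$depth)[3]),
                        function(k) any(x$depth[i, , k] > 0)))
    if (n_obs > 2L) next
    if (polymorphic_only) {
      fr <- x$depth[i, , 1L] / tots
      st <- ifelse(fr > hi, "hom_ref", ifelse(fr < lo, "hom_alt", "het"))
      if (!(any(st == "het") || (any(st == "hom_ref") && any(st == "hom_alt")))) next
    }
    keep[i] <- TRUE
  }
  keep
}
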