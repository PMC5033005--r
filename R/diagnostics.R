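#' Discover sites reciprocally fixed between the parental taxa
#'
#' A site is diagnostic when every diploid-parent sample carries one of
#' the two alleles at read frequency above \code{fix_threshold} and every
#' tetraploid-parent sample carries the other allele above the same
#' threshold. Reads at such sites in hybrids can then be assigned to a
#' parental subgenome. The frequency threshold (rather than requiring
#' literally zero alternative reads) keeps discovery robust to sequencing
#' error.
#'
#' @param x allele_depth_matrix, already filtered so that retained sites
#'   have at most two observed alleles; sites with more are skipped.
#' @param panel sample_panel with both parent roles present.
#' @param fix_threshold minimum within-sample read frequency for an allele
#'   to count as fixed (default 0.9, the complement of the heterozygote
#'   rule).
#' @return data.frame of class \code{diagnostic_sites}: site (row index
#'   into \code{x}), chrom, pos, probe_id, parentA_allele, parentB_allele,
#'   \code{a_is_ref} (whether the diploid-taxon allele matches the
#'   reference genome — the capture-bias classes), plus attribute
#'   \code{"summary"} with per-probe and per-linkage-group counts.
#' @export
find_diagnostic_sites <- function(x, panel, fix_threshold = 0.9) {
  pa <- panel_samples(panel, "parentA")
  pb <- panel_samples(panel, "parentB")
  if (length(pa) == 0L || length(pb) == 0L) {
    stop("panel must contain samples with roles parentA and parentB")
  }
  empty <- data.frame(site = integer(0), chrom = character(0),
                      pos = integer(0), probe_id = character(0),
                      parentA_allele = character(0),
                      parentB_allele = character(0),
                      a_is_ref = logical(0), stringsAsFactors = FALSE)
  if (n_sites(x) == 0L) return(structure(empty, class = c("diagnostic_sites", "data.frame")))
  f <- ref_freq(x)
  biallelic <- observed_allele_count(x) == 2L
  fixed_side <- function(samps) {
    fs <- f[, samps, drop = FALSE]
    all_ref <- rowSums(fs > fix_threshold, na.rm = TRUE) == length(samps) &
      rowSums(is.na(fs)) == 0L
    all_alt <- rowSums(fs < 1 - fix_threshold, na.rm = TRUE) == length(samps) &
      rowSums(is.na(fs)) == 0L
    ifelse(all_ref, 1L, ifelse(all_alt, 2L, NA_integer_))
  }
  fa <- fixed_side(pa)
  fb <- fixed_side(pb)
  idx <- which(biallelic & !is.na(fa) & !is.na(fb) & fa != fb)
  alleles <- x$alleles
  out <- data.frame(
    site = idx, chrom = x$sites$chrom[idx], pos = x$sites$pos[idx],
    probe_id = x$sites$probe_id[idx],
    parentA_allele = vapply(seq_along(idx),
                            function(i) alleles[[idx[i]]][fa[idx[i]]], character(1)),
    parentB_allele = vapply(seq_along(idx),
                            function(i) alleles[[idx[i]]][fb[idx[i]]], character(1)),
    a_is_ref = fa[idx] == 1L, stringsAsFactors = FALSE)
  summ <- list(
    n_sites = nrow(out),
    by_probe = as.data.frame(table(probe_id = out$probe_id),
                             stringsAsFactors = FALSE),
    by_chrom = as.data.frame(table(chrom = out$chrom),
                             stringsAsFactors = FALSE))
  structure(out, summary = summ, class = c("diagnostic_sites", "data.frame"))
}

#' Per-(hybrid, site) subgenome allele dosage
#'
#' For each hybrid sample and diagnostic site, the fraction of reads
#' carrying the diploid-taxon ("parent A") allele out of reads carrying
#' either diagnostic allele. Reads supporting any other allele are
#' excluded from the denominator (dosage is a two-allele ratio). The
#' expectation for an unbiased GLL triploid or GGLLLL hexaploid is 1/3.
#'
#' @param x allele_depth_matrix
#' @param diag diagnostic site table from
#'   \code{\link{find_diagnostic_sites}}
#' @param panel sample_panel
#' @param roles hybrid roles to evaluate (default both hybrid3x and
#'   hybrid6x).
#' @return data.frame of \code{dosage_records}: sample, taxon, role,
#'   site, chrom, pos, probe_id, a_is_ref, f_A, depth (reads over the two
#'   diagnostic alleles). Cells with zero informative depth are dropped;
#'   hybrids with zero depth at every diagnostic site are reported in the
#'   \code{"flagged"} attribute.
#' @export
dosage <- function(x, diag, panel, roles = c("hybrid3x", "hybrid6x")) {
  if (nrow(diag) == 0L) stop("diagnostic site table is empty")
  hyb <- panel_samples(panel, roles)
  if (length(hyb) == 0L) stop("panel has no samples in roles ",
                              paste(roles, collapse = ", "))
  idx <- diag$site
  # per-site index of the parentA allele within the site's allele list
  a_idx <- ifelse(diag$a_is_ref, 1L, 2L)
  b_idx <- 3L - a_idx
  sm <- match(hyb, x$samples)
  ad_a <- matrix(0L, length(idx), length(hyb))
  ad_b <- matrix(0L, length(idx), length(hyb))
  for (k in 1:2) {
    ra <- which(a_idx == k)
    rb <- which(b_idx == k)
    if (length(ra)) ad_a[ra, ] <- x$depth[idx[ra], sm, k]
    if (length(rb)) ad_b[rb, ] <- x$depth[idx[rb], sm, k]
  }
  dep <- ad_a + ad_b
  f_A <- ifelse(dep > 0L, ad_a / dep, NA_real_)
  pi <- match(hyb, panel$sample_id)
  rec <- data.frame(
    sample = rep(hyb, each = length(idx)),
    taxon = rep(panel$taxon[pi], each = length(idx)),
    role = rep(panel$role[pi], each = length(idx)),
    site = rep(idx, length(hyb)),
    chrom = rep(diag$chrom, length(hyb)),
    pos = rep(diag$pos, length(hyb)),
    probe_id = rep(diag$probe_id, length(hyb)),
    a_is_ref = rep(diag$a_is_ref, length(hyb)),
    f_A = as.vector(f_A), depth = as.vector(dep),
    stringsAsFactors = FALSE)
  flagged <- hyb[colSums(dep) == 0L]
  rec <- rec[!is.na(rec$f_A), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, flagged = flagged, class = c("dosage_records", "data.frame"))
}

#' Summaries of subgenome dosage
#'
#' Three views of the dosage records, mirroring how capture studies report
#' allelic dosage: (i) per-site values averaged per sample and pooled per
#' taxon — both as a pool of all (site, individual) values and as per-site
#' cross-individual means averaged over sites, since either pooling may be
#' wanted; (ii) per-probe means, then mean and SD across probes; (iii)
#' pooled histogram counts in bins of width 0.1 (left-closed; the final
#' bin closed on both sides).
#'
#' @param records dosage_records
#' @return list with \code{by_sample}, \code{by_taxon},
#'   \code{by_taxon_per_site}, \code{by_probe}, \code{probe_summary},
#'   \code{histogram}.
#' @export
dosage_summary <- function(records) {
  msd <- function(v) c(n = length(v), mean = mean(v), sd = stats::sd(v))
  agg <- function(formula, data) {
    a <- stats::aggregate(formula, data, msd)
    cbind(a[-length(a)], as.data.frame(a[[length(a)]]))
  }
  by_sample <- agg(f_A ~ sample + taxon, records)
  by_taxon <- agg(f_A ~ taxon, records)
  # per-site mean across individuals, then across sites
  site_means <- stats::aggregate(f_A ~ taxon + site, records, mean)
  by_taxon_per_site <- agg(f_A ~ taxon, site_means)
  probe_means <- stats::aggregate(f_A ~ taxon + probe_id, records, mean)
  probe_summary <- agg(f_A ~ taxon, probe_means)
  breaks <- seq(0, 1, by = 0.1)
  hist_tab <- do.call(rbind, lapply(split(records$f_A, records$taxon),
    function(v) {
      counts <- tabulate(pmin(findInterval(v, breaks), 10L), nbins = 10L)
      data.frame(bin_lo = breaks[-11L], bin_hi = breaks[-1L], count = counts)
    }))
  hist_tab$taxon <- sub("\\.\\d+$", "", rownames(hist_tab))
  rownames(hist_tab) <- NULL
  list(by_sample = by_sample, by_taxon = by_taxon,
       by_taxon_per_site = by_taxon_per_site,
       by_probe = probe_means, probe_summary = probe_summary,
       histogram = hist_tab[, c("taxon", "bin_lo", "bin_hi", "count")])
}

#' Decompose dosage by reference-allele match (capture bias)
#'
#' Splits the dosage records into the two diagnostic-site classes — sites
#' where the diploid-taxon allele matches the reference genome the capture
#' probes were designed from, and sites where the tetraploid-taxon allele
#' matches — and summarizes each separately. Under reference-biased
#' capture the class whose parent-A allele matches the reference shows an
#' inflated parent-A read fraction.
#'
#' @param records dosage_records
#' @return data.frame: taxon, class (\code{A_matches_ref} /
#'   \code{B_matches_ref}), n_sites, n_probes, n_values, mean, sd. Classes
#'   with zero sites appear with zero counts and \code{NA} moments.
#' @export
bias_decomposition <- function(records) {
  records$class <- ifelse(records$a_is_ref, "A_matches_ref", "B_matches_ref")
  taxa <- unique(records$taxon)
  grid <- expand.grid(taxon = taxa,
                      class = c("A_matches_ref", "B_matches_ref"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- records[records$taxon == grid$taxon[i] & records$class == grid$class[i], ]
    data.frame(taxon = grid$taxon[i], class = grid$class[i],
               n_sites = length(unique(v$site)),
               n_probes = length(unique(v$probe_id[!is.na(v$probe_id)])),
               n_values = nrow(v),
               mean = if (nrow(v)) mean(v$f_A) else NA_real_,
               sd = if (nrow(v) > 1L) stats::sd(v$f_A) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call missing parental alleles at diagnostic sites
#'
#' A hybrid cell homozygous at a diagnostic site has lost (or never
#' inherited) one parental allele: parent-A allele missing when the
#' parent-A read fraction falls below \code{hom_lo}, parent-B allele
#' missing above \code{hom_hi}. Besides the per-cell events, tallies are
#' produced per sample (with probe and linkage-group counts) and per
#' taxon, counting sites homozygous in at least one individual.
#'
#' @param x allele_depth_matrix
#' @param diag diagnostic site table
#' @param panel sample_panel
#' @param hom_lo,hom_hi homozygosity thresholds (defaults 0.1 / 0.9).
#' @param roles hybrid roles to scan.
#' @return list with \code{events} (sample, taxon, site, chrom, pos,
#'   probe_id, missing, f_A, depth), \code{by_sample},
#'   \code{by_taxon} tallies.
#' @export
missing_parent_allele <- function(x, diag, panel, hom_lo = 0.1, hom_hi = 0.9,
                                  roles = c("hybrid3x", "hybrid6x")) {
  rec <- dosage(x, diag, panel, roles)
  ev <- rec[rec$f_A < hom_lo | rec$f_A > hom_hi, , drop = FALSE]
  ev$missing <- ifelse(ev$f_A < hom_lo, "parentA_allele", "parentB_allele")
  ev <- ev[, c("sample", "taxon", "site", "chrom", "pos", "probe_id",
               "missing", "f_A", "depth")]
  rownames(ev) <- NULL
  empty_tally <- function(cols) {
    vals <- lapply(cols, function(cc) {
      if (startsWith(cc, "n_")) integer(0) else character(0)
    })
    as.data.frame(stats::setNames(vals, cols), stringsAsFactors = FALSE)
  }
  if (nrow(ev) == 0L) {
    return(list(events = ev,
                by_sample = empty_tally(c("sample", "taxon", "n_sites",
                                          "n_missing_A", "n_missing_B",
                                          "n_probes", "n_chroms")),
                by_taxon = empty_tally(c("taxon", "n_sites_any_individual",
                                         "n_missing_A", "n_missing_B",
                                         "n_probes", "n_chroms"))))
  }
  by_sample <- do.call(rbind, lapply(split(ev, ev$sample), function(d) {
    data.frame(sample = d$sample[1L], taxon = d$taxon[1L],
               n_sites = nrow(d),
               n_missing_A = sum(d$missing == "parentA_allele"),
               n_missing_B = sum(d$missing == "parentB_allele"),
               n_probes = length(unique(d$probe_id[!is.na(d$probe_id)])),
               n_chroms = length(unique(d$chrom)),
               stringsAsFactors = FALSE)
  }))
  by_taxon <- do.call(rbind, lapply(split(ev, ev$taxon), function(d) {
    data.frame(taxon = d$taxon[1L],
               n_sites_any_individual = length(unique(d$site)),
               n_missing_A = length(unique(d$site[d$missing == "parentA_allele"])),
               n_missing_B = length(unique(d$site[d$missing == "parentB_allele"])),
               n_probes = length(unique(d$probe_id[!is.na(d$probe_id)])),
               n_chroms = length(unique(d$chrom)),
               stringsAsFactors = FALSE)
  }))
  rownames(by_sample) <- rownames(by_taxon) <- NULL
  list(events = ev, by_sample = by_sample, by_taxon = by_taxon)
}
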