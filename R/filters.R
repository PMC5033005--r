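#' Call a read-frequency genotype state
#'
#' Heterozygotes are cells whose reference-allele read fraction lies in
#' \code{[lo, hi]} (bounds inclusive, so a hexaploid single copy at
#' expected frequency 1/6 and a boundary ratio like 5/50 are not split by
#' floating-point noise); above \code{hi} is homozygous-reference, below
#' \code{lo} homozygous-alternate. Cells with no reads are missing.
#'
#' @param f_ref numeric vector/matrix of reference-allele read fractions
#'   (\code{NA} = no reads).
#' @param lo,hi heterozygote band (defaults 0.1 and 0.9).
#' @return character vector/matrix over \code{"hom_ref"}, \code{"het"},
#'   \code{"hom_alt"}, \code{"missing"}.
#' @export
call_state <- function(f_ref, lo = 0.1, hi = 0.9) {
  stopifnot(lo < hi, lo >= 0, hi <= 1)
  out <- ifelse(is.na(f_ref), "missing",
         ifelse(f_ref > hi, "hom_ref",
         ifelse(f_ref < lo, "hom_alt", "het")))
  if (!is.null(dim(f_ref))) dim(out) <- dim(f_ref)
  out
}

#' Apply the site-level filters
#'
#' Filters are applied in a fixed order so the per-rule attrition counts in
#' the report are reproducible:
#' \enumerate{
#'   \item \strong{depth}: total read depth at least \code{min_depth} in
#'     every sample (or in at least one sample when
#'     \code{require_all_samples = FALSE});
#'   \item \strong{all_samples}: no sample has a missing allele-depth cell
#'     (missing cells carry zero depth, so this rule only bites when
#'     \code{min_depth = 0});
#'   \item \strong{biallelic}: at most two alleles observed across the
#'     panel, i.e. sites with two or more alternate alleles are discarded
#'     (monomorphic sites survive this rule; they are removed by the
#'     polymorphic rule when that is enabled);
#'   \item \strong{polymorphic}: at least one sample heterozygous, or two
#'     samples homozygous for different alleles.
#' }
#'
#' @param x allele_depth_matrix
#' @param min_depth minimum total depth per cell (default 50).
#' @param require_all_samples apply the depth rule across every sample.
#' @param biallelic_only discard sites with more than two observed alleles.
#' @param polymorphic_only additionally require polymorphism within the
#'   panel (used for the SNP analyses; leave \code{FALSE} for
#'   heterozygosity statistics, which are per-base over all genotyped
#'   sites).
#' @param lo,hi heterozygote band used by the polymorphic rule.
#' @return list with \code{matrix} (the filtered allele_depth_matrix) and
#'   \code{report} (data.frame: rule, removed, retained after each rule).
#' @export
filter_sites <- function(x, min_depth = 50, require_all_samples = TRUE,
                         biallelic_only = TRUE, polymorphic_only = FALSE,
                         lo = 0.1, hi = 0.9) {
  n0 <- n_sites(x)
  report <- data.frame(rule = character(0), removed = integer(0),
                       retained = integer(0), stringsAsFactors = FALSE)
  note <- function(rule, keep) {
    report <<- rbind(report, data.frame(rule = rule,
                                        removed = sum(!keep),
                                        retained = sum(keep),
                                        stringsAsFactors = FALSE))
  }
  if (n0 == 0L) {
    return(list(matrix = x, report = report))
  }

  tot <- total_depth(x)
  keep <- if (require_all_samples) {
    apply(tot >= min_depth, 1L, all)
  } else {
    apply(tot >= min_depth, 1L, any)
  }
  note("depth", keep)
  x <- adm_subset(x, keep)

  if (require_all_samples && n_sites(x) > 0L) {
    keep <- rowSums(x$missing) == 0L
    note("all_samples", keep)
    x <- adm_subset(x, keep)
  }

  if (biallelic_only && n_sites(x) > 0L) {
    keep <- observed_allele_count(x) <= 2L
    note("biallelic", keep)
    x <- adm_subset(x, keep)
  }

  if (polymorphic_only && n_sites(x) > 0L) {
    st <- call_state(ref_freq(x), lo, hi)
    any_het <- rowSums(st == "het") > 0L
    hr <- rowSums(st == "hom_ref") > 0L
    ha <- rowSums(st == "hom_alt") > 0L
    keep <- any_het | (hr & ha)
    note("polymorphic", keep)
    x <- adm_subset(x, keep)
  }
  stopifnot(n0 == n_sites(x) + sum(report$removed))
  list(matrix = x, report = report)
}

#' Fraction of heterozygous sites per sample
#'
#' The per-individual genome-wide heterozygosity statistic: number of
#' sites called heterozygous by the read-frequency rule divided by the
#' number of sites genotyped (non-missing, nonzero depth) in that sample.
#' Invariant to site and sample order.
#'
#' @param x allele_depth_matrix (typically depth-filtered, without the
#'   polymorphic rule).
#' @param lo,hi heterozygote band.
#' @return named numeric vector over samples; \code{NaN} when a sample has
#'   no genotyped sites.
#' @export
het_fraction <- function(x, lo = 0.1, hi = 0.9) {
  st <- call_state(ref_freq(x), lo, hi)
  het <- colSums(st == "het")
  genotyped <- colSums(st != "missing")
  out <- het / genotyped
  names(out) <- x$samples
  out
}

#' Per-taxon summary of heterozygous fractions
#'
#' @param x allele_depth_matrix
#' @param panel sample_panel
#' @param lo,hi heterozygote band
#' @return list with \code{by_sample} (sample, taxon, role, het_fraction)
#'   and \code{by_taxon} (taxon, n, mean, sd).
#' @export
het_summary <- function(x, panel, lo = 0.1, hi = 0.9) {
  h <- het_fraction(x, lo, hi)
  i <- match(names(h), panel$sample_id)
  by_sample <- data.frame(sample_id = names(h), taxon = panel$taxon[i],
                          role = panel$role[i], het_fraction = unname(h),
                          stringsAsFactors = FALSE)
  agg <- stats::aggregate(het_fraction ~ taxon, by_sample,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v)))
  by_taxon <- data.frame(taxon = agg$taxon,
                         n = agg$het_fraction[, "n"],
                         mean = agg$het_fraction[, "mean"],
                         sd = agg$het_fraction[, "sd"],
                         stringsAsFactors = FALSE)
  list(by_sample = by_sample, by_taxon = by_taxon)
}
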