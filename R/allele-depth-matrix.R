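#' Allele-depth matrix
#'
#' The central container of the package: per-(site, sample) read counts for
#' each allele observed at a site, as carried by the AD field of a
#' multi-sample VCF. Sites are kept sorted by (linkage group, position) so
#' that downstream window scans and reports are deterministic for a fixed
#' input.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (comma-separated alternate alleles, \code{""} or
#'   \code{"."} for monomorphic reference sites) and optionally
#'   \code{probe_id}.
#' @param samples character vector of sample ids (column order of
#'   \code{depth}).
#' @param depth integer array of dimension (n_sites, n_samples, K) holding
#'   read counts; slice \code{[, , k]} is the count of the k-th allele of
#'   each site (reference first), zero-padded for sites with fewer than K
#'   alleles.
#' @param missing logical matrix (n_sites x n_samples); \code{TRUE} marks
#'   cells whose AD was absent in the input. Missing cells carry zero depth.
#'
#' @return An object of class \code{allele_depth_matrix}: a list with
#'   elements \code{sites}, \code{samples}, \code{depth}, \code{alleles}
#'   (list of per-site allele vectors, reference first) and \code{missing}.
#' @export
allele_depth_matrix <- function(sites, samples, depth, missing = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (length(dim(depth)) == 2L) depth <- array(depth, dim = c(dim(depth), 1L))
  stopifnot(length(dim(depth)) == 3L,
            dim(depth)[1] == nrow(sites),
            dim(depth)[2] == length(samples))
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (any(sites$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (is.null(sites$probe_id)) sites$probe_id <- NA_character_
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(sites), length(samples))
  }
  stopifnot(all(dim(missing) == c(nrow(sites), length(samples))))
  if (any(depth < 0)) stop("negative allele depths")

  alleles <- site_alleles(sites)
  k_site <- lengths(alleles)
  if (max(c(k_site, 1L)) > dim(depth)[3])
    stop("depth array has fewer allele slots than site allele lists")
  # zero-pad beyond each site's allele count
  for (k in seq_len(dim(depth)[3])) {
    pad <- k_site < k
    if (any(pad)) depth[pad, , k] <- 0L
  }

  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  depth <- depth[ord, , , drop = FALSE]
  missing <- missing[ord, , drop = FALSE]
  alleles <- alleles[ord]

  dimnames(depth) <- list(NULL, samples, NULL)
  dimnames(missing) <- list(NULL, samples)
  structure(list(sites = sites, samples = samples, depth = depth,
                 alleles = alleles, missing = missing),
            class = "allele_depth_matrix")
}

site_alleles <- function(sites) {
  alt <- as.character(sites$alt)
  alt[is.na(alt) | alt == "." | alt == ""] <- NA_character_
  mapply(function(r, a) {
    if (is.na(a)) r else c(r, strsplit(a, ",", fixed = TRUE)[[1]])
  }, as.character(sites$ref), alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @export
print.allele_depth_matrix <- function(x, ...) {
  cat(sprintf("allele_depth_matrix: %d sites x %d samples (%d linkage groups)\n",
              n_sites(x), length(x$samples),
              length(unique(x$sites$chrom))))
  cat(sprintf("  mean cell depth %.1f; %d missing cells\n",
              mean(total_depth(x)), sum(x$missing)))
  invisible(x)
}

#' Number of sites in an allele-depth matrix
#' @param x allele_depth_matrix
#' @export
n_sites <- function(x) nrow(x$sites)

#' Total read depth per (site, sample)
#'
#' @param x allele_depth_matrix
#' @return integer matrix (sites x samples); sums the per-allele counts.
#' @export
total_depth <- function(x) rowSums(x$depth, dims = 2L)

#' Reference-allele read fraction per (site, sample)
#'
#' The quantity every genotype rule in the package operates on: count of reads
#' carrying the reference allele divided by the total depth of the cell.
#' Cells with zero depth (or flagged missing) are \code{NA}.
#'
#' @param x allele_depth_matrix
#' @return numeric matrix (sites x samples) in [0, 1] or \code{NA}.
#' @export
ref_freq <- function(x) {
  tot <- total_depth(x)
  f <- x$depth[, , 1L, drop = TRUE] / tot
  if (is.null(dim(f))) f <- matrix(f, n_sites(x), length(x$samples),
                                   dimnames = list(NULL, x$samples))
  f[tot == 0L | x$missing] <- NA_real_
  f
}

#' Number of alleles observed at each site across the panel
#'
#' An allele counts as observed when at least one read supports it in at
#' least one sample.
#'
#' @param x allele_depth_matrix
#' @return integer vector over sites.
#' @export
observed_allele_count <- function(x) {
  k <- dim(x$depth)[3]
  obs <- matrix(0L, n_sites(x), k)
  for (j in seq_len(k)) obs[, j] <- as.integer(rowSums(x$depth[, , j, drop = FALSE]) > 0)
  rowSums(obs)
}

#' Subset an allele-depth matrix by site index
#' @param x allele_depth_matrix
#' @param idx integer or logical site index
#' @export
adm_subset <- function(x, idx) {
  allele_depth_matrix(x$sites[idx, , drop = FALSE], x$samples,
                      x$depth[idx, , , drop = FALSE],
                      x$missing[idx, , drop = FALSE])
}

#' Per-allele read frequency at a set of sites
#'
#' @param x allele_depth_matrix
#' @param allele_idx integer vector (one per requested site) indexing into
#'   each site's allele list (1 = reference).
#' @param site_idx sites to evaluate (default all).
#' @return numeric matrix (length(site_idx) x samples).
#' @export
allele_freq <- function(x, allele_idx, site_idx = seq_len(n_sites(x))) {
  stopifnot(length(allele_idx) == length(site_idx))
  tot <- total_depth(x)[site_idx, , drop = FALSE]
  cnt <- matrix(0L, length(site_idx), length(x$samples))
  for (k in sort(unique(allele_idx))) {
    rows <- which(allele_idx == k)
    cnt[rows, ] <- x$depth[site_idx[rows], , k, drop = TRUE]
  }
  f <- cnt / tot
  f[tot == 0L | x$missing[site_idx, , drop = FALSE]] <- NA_real_
  dimnames(f) <- list(NULL, x$samples)
  f
}
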