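#' Read per-sample allele depths from a multi-sample VCF
#'
#' Parses a VCF v4.x file and builds an \code{\link{allele_depth_matrix}}
#' from the per-sample \code{AD} FORMAT field. Genotype (GT) calls are
#' ignored entirely: every downstream rule in this package is a
#' read-frequency rule. Records with missing AD in a sample are retained
#' with the cell flagged missing (depth 0), so that the all-samples depth
#' filter can account for them explicitly. Multiallelic records are kept
#' as-is for downstream discarding by the biallelic filter.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return an \code{\link{allele_depth_matrix}}.
#' @export
read_allele_depths <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    stop("VCF '", path, "' contains no variant records")
  }
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF '", path, "' has no sample columns")
  has_ad <- grepl("(^|:)AD(:|$)", gt[, "FORMAT"])
  if (!all(has_ad)) {
    stop("VCF '", path, "' lacks the AD FORMAT field at record(s) ",
         paste(utils::head(which(!has_ad), 5L), collapse = ", "),
         "; allele depths are required input")
  }
  samples <- colnames(gt)[-1L]
  ad <- vcfR::extract.gt(vcf, element = "AD")

  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  alleles <- site_alleles(sites)
  kmax <- max(lengths(alleles))
  n <- nrow(sites)
  depth <- array(0L, dim = c(n, length(samples), kmax))
  missing <- matrix(FALSE, n, length(samples))
  for (s in seq_along(samples)) {
    cell <- ad[, s]
    bad <- is.na(cell) | cell == "." | cell == ""
    missing[bad, s] <- TRUE
    counts <- strsplit(ifelse(bad, "0", cell), ",", fixed = TRUE)
    nk <- lengths(counts)
    flat <- suppressWarnings(as.integer(unlist(counts)))
    if (anyNA(flat)) {
      stop("non-integer AD value in VCF '", path, "', sample ", samples[s])
    }
    idx <- cbind(rep.int(seq_len(n), nk), s, sequence(nk))
    keep <- idx[, 3] <= kmax
    depth[idx[keep, , drop = FALSE]] <- flat[keep]
  }
  allele_depth_matrix(sites, samples, depth, missing)
}

#' Write an allele-depth matrix as a minimal VCF v4.2
#'
#' Emits one record per site with FORMAT \code{AD} only (the only field the
#' pipeline consumes). Round-trips exactly through
#' \code{\link{read_allele_depths}}.
#'
#' @param x allele_depth_matrix
#' @param path output file path
#' @param source_tag free-text value for the \code{##source} header line
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(x, path, source_tag = "allodose") {
  alt <- vapply(x$alleles, function(a) {
    if (length(a) == 1L) "." else paste(a[-1L], collapse = ",")
  }, character(1))
  k_site <- lengths(x$alleles)
  n <- n_sites(x)
  cells <- matrix("", n, length(x$samples))
  for (s in seq_along(x$samples)) {
    for_site <- lapply(seq_len(n), function(i) x$depth[i, s, seq_len(k_site[i])])
    cells[, s] <- vapply(for_site, paste, character(1), collapse = ",")
    cells[x$missing[, s], s] <- "."
  }
  header <- c("##fileformat=VCFv4.2",
              paste0("##source=", source_tag),
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$samples), collapse = "\t"))
  body <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, alt, ".",
                "PASS", ".", "AD",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and validate a sample panel
#'
#' The panel maps each sequenced individual to its taxon, ploidy, role in
#' the cross design (diploid parent, tetraploid parent, triploid hybrid,
#' genome-doubled hexaploid), population, and an optional geographically
#' paired sample used for local comparisons.
#'
#' @param path TSV with header columns \code{sample_id}, \code{taxon},
#'   \code{ploidy}, \code{role}, \code{population}, and optionally
#'   \code{local_pair}.
#' @return a validated data.frame of class \code{sample_panel}.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("panel '", path, "' is empty")
  df$ploidy <- suppressWarnings(as.integer(df$ploidy))
  as_sample_panel(df)
}

#' Construct a sample panel from a data.frame
#'
#' @param df data.frame with the columns documented in
#'   \code{\link{read_panel}}.
#' @export
as_sample_panel <- function(df) {
  req <- c("sample_id", "taxon", "ploidy", "role", "population")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("panel lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$local_pair)) df$local_pair <- NA_character_
  df$local_pair[df$local_pair %in% c("", ".", "NA")] <- NA_character_
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  roles <- c(parentA = 2L, parentB = 4L, hybrid3x = 3L, hybrid6x = 6L)
  bad_role <- !df$role %in% names(roles)
  if (any(bad_role)) {
    stop("unknown role(s) in panel row(s) ", paste(which(bad_role), collapse = ", "),
         ": ", paste(unique(df$role[bad_role]), collapse = ", "))
  }
  if (anyNA(df$ploidy) || any(df$ploidy != roles[df$role])) {
    off <- which(is.na(df$ploidy) | df$ploidy != roles[df$role])
    stop("ploidy/role mismatch in panel row(s): ", paste(off, collapse = ", "),
         " (expected parentA=2, parentB=4, hybrid3x=3, hybrid6x=6)")
  }
  for (r in c("parentA", "parentB")) {
    if (!any(df$role == r)) stop("panel has no sample with role ", r)
  }
  unknown_pair <- !is.na(df$local_pair) & !df$local_pair %in% df$sample_id
  if (any(unknown_pair)) {
    stop("local_pair refers to unknown sample(s): ",
         paste(df$local_pair[unknown_pair], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_panel", "data.frame")
  df
}

#' Samples having a given role
#' @param panel sample_panel
#' @param role one or more of parentA, parentB, hybrid3x, hybrid6x
#' @export
panel_samples <- function(panel, role) panel$sample_id[panel$role %in% role]

#' Write a sample panel as TSV
#' @param panel sample_panel
#' @param path output path
#' @export
write_panel <- function(panel, path) {
  write_table(as.data.frame(panel), path)
}

#' Write a result table as TSV
#'
#' Plain tab-separated output with a header row and no quoting; the stable
#' on-disk form of every report in the pipeline.
#'
#' @param records data.frame
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by \code{\link{write_table}}
#' @param path input path
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a probe interval map (BED4)
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention (a line \code{LG14 0 450 probe_0001} covers
#' positions 1..450 on LG14). Intervals must be sorted by (chrom, start);
#' overlapping intervals are allowed but sites falling in an overlap are
#' assigned to the first interval, with a warning.
#'
#' @param path BED4 file (chrom, start, end, name), no header.
#' @return data.frame with columns chrom, start, end (1-based inclusive),
#'   probe_id.
#' @export
read_probes <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start0", "end", "probe_id"))
  if (nrow(df) == 0L) stop("BED '", path, "' is empty")
  ord <- order(df$chrom, df$start0)
  if (!identical(ord, seq_len(nrow(df)))) {
    stop("BED '", path, "' is not sorted by (chrom, start)")
  }
  if (any(df$end <= df$start0)) stop("BED '", path, "' has empty/negative intervals")
  data.frame(chrom = df$chrom, start = df$start0 + 1L, end = df$end,
             probe_id = df$probe_id, stringsAsFactors = FALSE)
}

#' Assign sites to probes
#'
#' Fills the \code{probe_id} column of the site table from a probe interval
#' map. Sites outside every interval keep \code{NA}. Where intervals
#' overlap, the first (leftmost) matching interval wins and a warning is
#' issued.
#'
#' @param x allele_depth_matrix
#' @param probes probe map from \code{\link{read_probes}}
#' @return \code{x} with \code{sites$probe_id} filled.
#' @export
assign_probes <- function(x, probes) {
  overlap <- FALSE
  pid <- rep(NA_character_, n_sites(x))
  for (chr in unique(x$sites$chrom)) {
    p <- probes[probes$chrom == chr, , drop = FALSE]
    if (nrow(p) == 0L) next
    if (nrow(p) > 1L && any(p$start[-1L] <= p$end[-nrow(p)])) overlap <- TRUE
    rows <- which(x$sites$chrom == chr)
    pos <- x$sites$pos[rows]
    for (i in seq_len(nrow(p))) {  # file order => first interval wins
      hit <- is.na(pid[rows]) & pos >= p$start[i] & pos <= p$end[i]
      pid[rows[hit]] <- p$probe_id[i]
    }
  }
  if (overlap) warning("overlapping probe intervals; sites assigned to the first match")
  x$sites$probe_id <- pid
  x
}

#' Write a tree in Newick format
#'
#' @param tree an object of class \code{phylo} (as returned by
#'   \code{\link{nj_tree}} or \code{\link{bootstrap_support}}); internal
#'   node labels, when present, are written as support values.
#' @param path output file
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write the JSON run-metadata sidecar
#'
#' Records the seed, thresholds and package version next to a result
#' directory so that a run can be reproduced from its outputs alone.
#'
#' @param meta named list of settings
#' @param path output .json path
#' @export
write_run_metadata <- function(meta, path) {
  meta$package_version <- as.character(utils::packageVersion("allodose"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
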