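#' Alleles unique to the hybrid taxa
#'
#' Scans biallelic sites for alleles carried by any triploid or hexaploid
#' sample at read frequency strictly above \code{q_min} (the frequency of
#' one of six copies in a hexaploid, 1/6) while remaining below
#' \code{parent_max} in every sample of both parental taxa — i.e. alleles
#' not attributable to the sampled parents.
#'
#' @param x allele_depth_matrix (filtered, biallelic).
#' @param panel sample_panel.
#' @param q_min minimum hybrid frequency (strict; default 0.167).
#' @param parent_max maximum parental frequency (strict; default 0.1).
#' @return list with \code{events} (site, chrom, pos, allele, sample,
#'   freq) — one row per qualifying (site, allele, hybrid sample) — and
#'   \code{n_tested}, the denominator of tested loci.
#' @export
unique_hybrid_alleles <- function(x, panel, q_min = 0.167, parent_max = 0.1) {
  hyb <- panel_samples(panel, c("hybrid3x", "hybrid6x"))
  par <- panel_samples(panel, c("parentA", "parentB"))
  tested <- which(observed_allele_count(x) <= 2L)
  f_ref <- ref_freq(x)
  events <- list()
  for (allele_idx in 1:2) {
    f <- if (allele_idx == 1L) f_ref else 1 - f_ref
    ok_parent <- rowSums(f[, par, drop = FALSE] < parent_max, na.rm = TRUE) == length(par) &
      rowSums(is.na(f[, par, drop = FALSE])) == 0L
    hy <- f[, hyb, drop = FALSE] > q_min
    hy[is.na(hy)] <- FALSE
    cand <- intersect(tested, which(ok_parent & rowSums(hy) > 0L))
    for (i in cand) {
      ss <- hyb[hy[i, ]]
      al <- x$alleles[[i]]
      if (allele_idx > length(al)) next
      events[[length(events) + 1L]] <- data.frame(
        site = i, chrom = x$sites$chrom[i], pos = x$sites$pos[i],
        allele = al[allele_idx], sample = ss,
        freq = f[i, ss], stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(site = integer(0), chrom = character(0), pos = integer(0),
               allele = character(0), sample = character(0),
               freq = numeric(0), stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  list(events = ev, n_tested = length(tested))
}

resolve_scope <- function(panel, rob_samples, per_samples) {
  if (length(rob_samples) == 0L || length(per_samples) == 0L) {
    stop("comparison scope is empty: need at least one triploid and one hexaploid")
  }
  ok <- c(rob_samples, per_samples) %in% panel$sample_id
  if (!all(ok)) stop("unknown sample(s) in scope: ",
                     paste(c(rob_samples, per_samples)[!ok], collapse = ", "))
  invisible(TRUE)
}

#' Alleles gained in the hexaploid relative to the triploid
#'
#' Sites fixed in every scoped triploid (either allele at frequency above
#' \code{fixed_min}) where some scoped hexaploid shows the other allele at
#' frequency at least \code{gain_min} (one of six hexaploid copies). The
#' scope is either all triploids vs all hexaploids (global) or a local
#' pair.
#'
#' @param x allele_depth_matrix (filtered, biallelic).
#' @param panel sample_panel.
#' @param rob_samples,per_samples scoped triploid and hexaploid sample ids.
#' @param fixed_min triploid fixation threshold (strict >; default 0.9).
#' @param gain_min minimum hexaploid frequency of the new allele
#'   (inclusive; default 0.167).
#' @param scope label recorded on the events ("global" or a pair label).
#' @return list with \code{events} (one row per site x qualifying
#'   hexaploid), \code{n_tested} (sites fixed in the scoped triploids:
#'   the denominator of potentially informative loci), and
#'   \code{summary} (n_loci, mean and SD of the new-allele frequency).
#' @export
gained_alleles <- function(x, panel, rob_samples, per_samples,
                           fixed_min = 0.9, gain_min = 0.167,
                           scope = "global") {
  resolve_scope(panel, rob_samples, per_samples)
  f_ref <- ref_freq(x)
  biallelic <- observed_allele_count(x) <= 2L
  rows <- list()
  n_tested <- 0L
  for (allele_idx in 1:2) {  # allele the triploid is fixed FOR
    f_fix <- if (allele_idx == 1L) f_ref else 1 - f_ref
    f_new <- 1 - f_fix
    rob_fixed <- rowSums(f_fix[, rob_samples, drop = FALSE] > fixed_min,
                         na.rm = TRUE) == length(rob_samples) &
      rowSums(is.na(f_fix[, rob_samples, drop = FALSE])) == 0L
    tested <- which(biallelic & rob_fixed)
    n_tested <- n_tested + length(tested)
    gain <- f_new[, per_samples, drop = FALSE] >= gain_min
    gain[is.na(gain)] <- FALSE
    for (i in intersect(tested, which(rowSums(gain) > 0L))) {
      ss <- per_samples[gain[i, ]]
      al <- x$alleles[[i]]
      new_idx <- 3L - allele_idx
      rows[[length(rows) + 1L]] <- data.frame(
        site = i, chrom = x$sites$chrom[i], pos = x$sites$pos[i],
        probe_id = x$sites$probe_id[i],
        allele = if (new_idx <= length(al)) al[new_idx] else NA_character_,
        sample = ss, freq = f_new[i, ss], scope = scope,
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), chrom = character(0), pos = integer(0),
               probe_id = character(0), allele = character(0),
               sample = character(0), freq = numeric(0),
               scope = character(0), stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  list(events = ev, n_tested = n_tested,
       summary = data.frame(scope = scope,
                            n_loci = length(unique(ev$site)),
                            n_tested = n_tested,
                            mean_freq = if (nrow(ev)) mean(ev$freq) else NA_real_,
                            sd_freq = if (nrow(ev) > 1L) stats::sd(ev$freq) else NA_real_,
                            stringsAsFactors = FALSE))
}

#' Alleles lost in the hexaploid relative to the triploid
#'
#' Sites heterozygous in every scoped triploid (reference-allele frequency
#' strictly between \code{het_lo} and \code{het_hi}) that appear
#' homozygous in at least one scoped hexaploid (frequency below
#' \code{hom_lo} or above \code{hom_hi}, a deliberately more conservative
#' band).
#'
#' @inheritParams gained_alleles
#' @param het_lo,het_hi triploid heterozygote band (strict; defaults
#'   0.167 / 0.833, the one-in-six copy bounds).
#' @param hom_lo,hom_hi hexaploid homozygosity thresholds (strict;
#'   defaults 0.1 / 0.9).
#' @return list with \code{events}, \code{n_tested} (sites heterozygous
#'   in all scoped triploids) and \code{summary}.
#' @export
lost_alleles <- function(x, panel, rob_samples, per_samples,
                         het_lo = 0.167, het_hi = 0.833,
                         hom_lo = 0.1, hom_hi = 0.9, scope = "global") {
  resolve_scope(panel, rob_samples, per_samples)
  f_ref <- ref_freq(x)
  biallelic <- observed_allele_count(x) <= 2L
  fr <- f_ref[, rob_samples, drop = FALSE]
  rob_het <- rowSums(fr > het_lo & fr < het_hi, na.rm = TRUE) == length(rob_samples) &
    rowSums(is.na(fr)) == 0L
  tested <- which(biallelic & rob_het)
  fp <- f_ref[, per_samples, drop = FALSE]
  hom <- fp < hom_lo | fp > hom_hi
  hom[is.na(hom)] <- FALSE
  rows <- list()
  for (i in intersect(tested, which(rowSums(hom) > 0L))) {
    ss <- per_samples[hom[i, ]]
    rows[[length(rows) + 1L]] <- data.frame(
      site = i, chrom = x$sites$chrom[i], pos = x$sites$pos[i],
      probe_id = x$sites$probe_id[i], sample = ss,
      freq = fp[i, ss],
      lost_allele = ifelse(fp[i, ss] > hom_hi,
                           vapply(x$alleles[i], function(a)
                             if (length(a) > 1L) a[2L] else NA_character_,
                             character(1)),
                           x$sites$ref[i]),
      scope = scope, stringsAsFactors = FALSE)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), chrom = character(0), pos = integer(0),
               probe_id = character(0), sample = character(0),
               freq = numeric(0), lost_allele = character(0),
               scope = character(0), stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  list(events = ev, n_tested = length(tested),
       summary = data.frame(scope = scope,
                            n_loci = length(unique(ev$site)),
                            n_tested = length(tested),
                            stringsAsFactors = FALSE))
}

#' Moving-average allele-frequency difference along linkage groups
#'
#' For one triploid/hexaploid pair, takes the informative sites — sites
#' heterozygous in the triploid, where loss or conversion in the hexaploid
#' is observable — sorted by position within each linkage group, and
#' slides a window of \code{window} consecutive informative sites (step 1)
#' over the signed per-site difference in reference-allele frequency
#' (hexaploid minus triploid). The loss or conversion of a single copy in
#' a hexaploid shifts the window mean by about 1/6.
#'
#' @param x allele_depth_matrix (filtered).
#' @param rob,per the triploid and hexaploid sample ids of the pair.
#' @param window number of informative SNPs per window (default 10).
#' @param lo,hi heterozygote band defining informative sites.
#' @return data.frame of \code{window_scan} records: chrom, win (index
#'   within linkage group), start, end (genomic span of the window's
#'   sites), n_sites, mean_diff (signed), mean_abs_diff. Linkage groups
#'   with fewer informative sites than \code{window} contribute no rows
#'   and are listed in the \code{"skipped"} attribute.
#' @export
window_scan <- function(x, rob, per, window = 10, lo = 0.1, hi = 0.9) {
  stopifnot(window >= 1, rob %in% x$samples, per %in% x$samples)
  f <- ref_freq(x)
  informative <- !is.na(f[, rob]) & !is.na(f[, per]) &
    f[, rob] >= lo & f[, rob] <= hi
  out <- list()
  skipped <- character(0)
  for (chr in unique(x$sites$chrom)) {
    idx <- which(informative & x$sites$chrom == chr)
    idx <- idx[order(x$sites$pos[idx])]
    if (length(idx) < window) {
      skipped <- c(skipped, chr)
      next
    }
    d <- f[idx, per] - f[idx, rob]
    nw <- length(idx) - window + 1L
    cs <- cumsum(c(0, d))
    wmean <- (cs[(window + 1L):(length(d) + 1L)] - cs[1:nw]) / window
    csa <- cumsum(c(0, abs(d)))
    wabs <- (csa[(window + 1L):(length(d) + 1L)] - csa[1:nw]) / window
    out[[chr]] <- data.frame(
      chrom = chr, win = seq_len(nw),
      start = x$sites$pos[idx[1:nw]],
      end = x$sites$pos[idx[window:length(idx)]],
      n_sites = window, mean_diff = wmean, mean_abs_diff = wabs,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), win = integer(0), start = integer(0),
               end = integer(0), n_sites = integer(0), mean_diff = numeric(0),
               mean_abs_diff = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, skipped = skipped, class = c("window_scan", "data.frame"))
}

#' Detect candidate loss/conversion regions in a window scan
#'
#' Maximal runs of consecutive windows whose absolute mean difference is
#' at least \code{min_abs}, of length at least \code{min_windows}. Runs
#' separated by even a single sub-threshold window are reported
#' separately (no gap merging).
#'
#' @param scan window_scan records.
#' @param min_abs minimum |mean difference| per window (default 0.1).
#' @param min_windows minimum run length in windows (default 5).
#' @return data.frame: chrom, start, end, n_windows, mean_diff of the run.
#' @export
detect_runs <- function(scan, min_abs = 0.1, min_windows = 5) {
  out <- list()
  for (chr in unique(scan$chrom)) {
    d <- scan[scan$chrom == chr, , drop = FALSE]
    d <- d[order(d$win), , drop = FALSE]
    r <- rle(abs(d$mean_diff) >= min_abs)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_windows)) {
      seg <- d[starts[k]:ends[k], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(seg$start), end = max(seg$end),
        n_windows = nrow(seg), mean_diff = mean(seg$mean_diff),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0), mean_diff = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
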