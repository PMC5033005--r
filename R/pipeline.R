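#' Pipeline run configuration
#'
#' Collects the input paths, every numeric rule threshold, the seed, and
#' stage toggles for a full analysis run. All thresholds default to the
#' values the analysis rules are defined with; every one of them is
#' recorded in the run manifest.
#'
#' @param vcf path to the multi-sample VCF with AD fields.
#' @param panel path to the sample panel TSV.
#' @param probes optional path to a probe BED4 file.
#' @param outdir output directory.
#' @param min_depth minimum per-sample site depth.
#' @param lo,hi heterozygote band for genotype states.
#' @param fix_threshold parental fixation threshold for diagnostic sites.
#' @param q_min,parent_max unique-allele rule thresholds.
#' @param gain_min hexaploid new-allele frequency threshold.
#' @param het_lo,het_hi triploid heterozygote band for the loss rule.
#' @param hom_lo,hom_hi homozygosity thresholds (loss rule and missing
#'   parental alleles).
#' @param window window size (informative SNPs) for the scan.
#' @param run_min_abs,run_min_windows run-detection thresholds.
#' @param n_reps bootstrap replicates.
#' @param seed seed for the bootstrap stage (mandatory when
#'   \code{do_relate}).
#' @param do_het,do_diagnostics,do_compare,do_scan,do_relate stage toggles.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(vcf, panel, probes = NULL, outdir,
                       min_depth = 50, lo = 0.1, hi = 0.9,
                       fix_threshold = 0.9, q_min = 0.167, parent_max = 0.1,
                       gain_min = 0.167, het_lo = 0.167, het_hi = 0.833,
                       hom_lo = 0.1, hom_hi = 0.9,
                       window = 10, run_min_abs = 0.1, run_min_windows = 5,
                       n_reps = 1000, seed = NULL,
                       do_het = TRUE, do_diagnostics = TRUE,
                       do_compare = TRUE, do_scan = TRUE, do_relate = TRUE) {
  th <- c(lo = lo, hi = hi, fix_threshold = fix_threshold, q_min = q_min,
          parent_max = parent_max, gain_min = gain_min, het_lo = het_lo,
          het_hi = het_hi, hom_lo = hom_lo, hom_hi = hom_hi)
  if (any(th < 0 | th > 1)) stop("run_config: thresholds must lie in [0, 1]")
  if (lo >= hi) stop("run_config: lo must be below hi")
  if (het_lo >= het_hi) stop("run_config: het_lo must be below het_hi")
  if (hom_lo >= hom_hi) stop("run_config: hom_lo must be below hom_hi")
  if (min_depth < 0 || window < 1 || n_reps < 1) {
    stop("run_config: min_depth, window and n_reps must be positive")
  }
  if (do_relate && is.null(seed)) {
    stop("run_config: seed is required when the relationships stage ",
         "(bootstrap) is enabled")
  }
  structure(list(vcf = vcf, panel = panel, probes = probes, outdir = outdir,
                 min_depth = min_depth, lo = lo, hi = hi,
                 fix_threshold = fix_threshold, q_min = q_min,
                 parent_max = parent_max, gain_min = gain_min,
                 het_lo = het_lo, het_hi = het_hi,
                 hom_lo = hom_lo, hom_hi = hom_hi, window = window,
                 run_min_abs = run_min_abs, run_min_windows = run_min_windows,
                 n_reps = n_reps, seed = seed,
                 do_het = do_het, do_diagnostics = do_diagnostics,
                 do_compare = do_compare, do_scan = do_scan,
                 do_relate = do_relate),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: site filtering, per-sample heterozygosity,
#' diagnostic-site discovery with dosage and bias decomposition and
#' missing-allele calls, triploid/hexaploid gain/loss comparisons (global
#' and per local pair), window scans for each local pair, and the
#' relationships stage (Nei distance, NJ tree with bootstrap, PCA). Each
#' stage writes TSV outputs into \code{cfg$outdir}; a JSON manifest
#' records the inputs (with checksums), every threshold, the seed and the
#' package version. Reruns with an identical configuration are
#' bit-identical.
#'
#' @param cfg run_config
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)

  adm <- stage("read", {
    a <- read_allele_depths(cfg$vcf)
    if (!is.null(cfg$probes)) a <- assign_probes(a, read_probes(cfg$probes))
    a
  })
  panel <- stage("read", read_panel(cfg$panel))
  if (!all(panel$sample_id %in% adm$samples)) {
    stop("pipeline stage 'read' failed: panel samples absent from VCF: ",
         paste(setdiff(panel$sample_id, adm$samples), collapse = ", "))
  }

  flt <- stage("filter", filter_sites(adm, min_depth = cfg$min_depth,
                                      biallelic_only = TRUE,
                                      polymorphic_only = FALSE,
                                      lo = cfg$lo, hi = cfg$hi))
  write_table(flt$report, out("filter_report.tsv"))
  genotyped <- flt$matrix
  snp <- stage("filter", filter_sites(genotyped, min_depth = cfg$min_depth,
                                      polymorphic_only = TRUE,
                                      lo = cfg$lo, hi = cfg$hi))$matrix

  if (cfg$do_het) {
    hs <- stage("het", het_summary(genotyped, panel, cfg$lo, cfg$hi))
    write_table(hs$by_sample, out("het_by_sample.tsv"))
    write_table(hs$by_taxon, out("het_by_taxon.tsv"))
  }

  diag <- NULL
  if (cfg$do_diagnostics) {
    diag <- stage("diagnostics",
                  find_diagnostic_sites(snp, panel, cfg$fix_threshold))
    write_table(as.data.frame(diag), out("diagnostic_sites.tsv"))
    if (nrow(diag) > 0L) {
      rec <- stage("diagnostics", dosage(snp, diag, panel))
      write_table(as.data.frame(rec), out("dosage_per_site.tsv"))
      ds <- dosage_summary(rec)
      write_table(ds$by_sample, out("dosage_by_sample.tsv"))
      write_table(ds$by_taxon, out("dosage_by_taxon.tsv"))
      write_table(ds$by_taxon_per_site, out("dosage_by_taxon_per_site.tsv"))
      write_table(ds$by_probe, out("dosage_per_probe.tsv"))
      write_table(ds$probe_summary, out("dosage_probe_summary.tsv"))
      write_table(ds$histogram, out("dosage_histogram.tsv"))
      write_table(bias_decomposition(rec), out("bias_classes.tsv"))
      mp <- stage("diagnostics",
                  missing_parent_allele(snp, diag, panel,
                                        cfg$hom_lo, cfg$hom_hi))
      write_table(mp$events, out("missing_allele_events.tsv"))
      write_table(mp$by_sample, out("missing_allele_by_sample.tsv"))
      write_table(mp$by_taxon, out("missing_allele_by_taxon.tsv"))
    }
  }

  rob <- panel_samples(panel, "hybrid3x")
  per <- panel_samples(panel, "hybrid6x")
  pairs <- panel[panel$role == "hybrid6x" & !is.na(panel$local_pair),
                 c("sample_id", "local_pair")]
  if (cfg$do_compare) {
    uq <- stage("compare", unique_hybrid_alleles(snp, panel,
                                                 cfg$q_min, cfg$parent_max))
    write_table(uq$events, out("unique_hybrid_alleles.tsv"))
    if (length(rob) && length(per)) {
      ga <- stage("compare",
                  gained_alleles(snp, panel, rob, per,
                                 fixed_min = cfg$hi, gain_min = cfg$gain_min,
                                 scope = "global"))
      la <- stage("compare",
                  lost_alleles(snp, panel, rob, per,
                               het_lo = cfg$het_lo, het_hi = cfg$het_hi,
                               hom_lo = cfg$hom_lo, hom_hi = cfg$hom_hi,
                               scope = "global"))
      gev <- ga$events; gsum <- ga$summary
      lev <- la$events; lsum <- la$summary
      for (k in seq_len(nrow(pairs))) {
        sc <- paste0(pairs$local_pair[k], "-", pairs$sample_id[k])
        gp <- gained_alleles(snp, panel, pairs$local_pair[k],
                             pairs$sample_id[k], fixed_min = cfg$hi,
                             gain_min = cfg$gain_min, scope = sc)
        lp <- lost_alleles(snp, panel, pairs$local_pair[k],
                           pairs$sample_id[k], het_lo = cfg$het_lo,
                           het_hi = cfg$het_hi, hom_lo = cfg$hom_lo,
                           hom_hi = cfg$hom_hi, scope = sc)
        gev <- rbind(gev, gp$events); gsum <- rbind(gsum, gp$summary)
        lev <- rbind(lev, lp$events); lsum <- rbind(lsum, lp$summary)
      }
      write_table(gev, out("gained_alleles.tsv"))
      write_table(gsum, out("gained_alleles_summary.tsv"))
      write_table(lev, out("lost_alleles.tsv"))
      write_table(lsum, out("lost_alleles_summary.tsv"))
    }
  }

  if (cfg$do_scan && nrow(pairs)) {
    scans <- list(); regions <- list()
    for (k in seq_len(nrow(pairs))) {
      sc <- window_scan(snp, pairs$local_pair[k], pairs$sample_id[k],
                        window = cfg$window, lo = cfg$lo, hi = cfg$hi)
      if (nrow(sc)) {
        sc$pair <- paste0(pairs$local_pair[k], "-", pairs$sample_id[k])
        scans[[k]] <- sc
        rg <- detect_runs(sc, cfg$run_min_abs, cfg$run_min_windows)
        if (nrow(rg)) {
          rg$pair <- sc$pair[1L]
          regions[[k]] <- rg
        }
      }
    }
    write_table(if (length(scans)) do.call(rbind, scans) else
                  data.frame(), out("scan.tsv"))
    write_table(if (length(regions)) do.call(rbind, regions) else
                  data.frame(chrom = character(0)), out("regions.tsv"))
  }

  if (cfg$do_relate) {
    pm <- stage("relate", presence_matrix(snp, cfg$lo, cfg$hi))
    D <- stage("relate", nei_distance(pm))
    write_table(data.frame(sample_id = rownames(D), D,
                           check.names = FALSE), out("distances.tsv"))
    bs <- stage("relate", bootstrap_support(pm, cfg$n_reps, cfg$seed))
    write_newick(bs$tree, out("tree.nwk"))
    write_table(bs$support, out("tree_support.tsv"))
    pc <- stage("relate", pca_presence(pm))
    write_table(data.frame(sample_id = rownames(pc$scores), pc$scores,
                           check.names = FALSE), out("pca_scores.tsv"))
    write_table(data.frame(component = seq_along(pc$explained),
                           explained = pc$explained), out("pca_explained.tsv"))
  }

  meta <- cfg
  class(meta) <- NULL
  meta$inputs <- list(
    vcf_md5 = unname(tools::md5sum(cfg$vcf)),
    panel_md5 = unname(tools::md5sum(cfg$panel)),
    probes_md5 = if (is.null(cfg$probes)) NULL else
      unname(tools::md5sum(cfg$probes)))
  write_run_metadata(meta, out("manifest.json"))
  invisible(cfg$outdir)
}

#' One-command synthetic demonstration run
#'
#' Generates a 16-sample panel mirroring the study design — four samples
#' each of the diploid parent, tetraploid parent, triploid hybrid and
#' genome-doubled hexaploid, with the hexaploids paired to local
#' triploids and one terminal loss/conversion region injected on LG14 of
#' the Orkney-style hexaploid — writes the VCF, panel, probe BED and
#' truth tables, and runs the full pipeline on them.
#'
#' @param seed integer seed driving both the simulation and the bootstrap.
#' @param dir output directory.
#' @param n_probes,sites_per_probe problem size (defaults give ~4,800
#'   sites, enough for a visible terminal event region).
#' @param n_reps bootstrap replicates (default 100 for a quick demo).
#' @param event_sites number of terminal triploid-heterozygous sites
#'   converted in the hexaploid.
#' @return list with \code{dir}, \code{truth}, and the paths of the
#'   generated inputs.
#' @export
run_demo <- function(seed, dir, n_probes = 1198, sites_per_probe = 4,
                     n_reps = 100, event_sites = 15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairing <- c(2L, 2L, 1L, 4L)  # hexaploids double their local triploids
  cfg0 <- sim_config(n_probes = n_probes, sites_per_probe = sites_per_probe,
                     seed = seed, pairing = pairing)
  truth0 <- form_hybrids(simulate_parents(cfg0))
  span <- terminal_informative_span(truth0, "rob-1", "LG14", event_sites)
  ev <- event_spec("single_copy_conversion", "per-3", chrom = "LG14",
                   start = span$start, end = span$end, allele = "ref")
  cfg <- sim_config(n_probes = n_probes, sites_per_probe = sites_per_probe,
                    seed = seed, pairing = pairing, events = list(ev))
  sim <- simulate_panel(cfg)

  vcf <- file.path(dir, "synthetic_panel.vcf")
  panel_tsv <- file.path(dir, "panel.tsv")
  bed <- file.path(dir, "probes.bed")
  write_vcf(sim$adm, vcf)
  write_panel(sim$panel, panel_tsv)
  lay <- site_layout(cfg)
  probe_rows <- !duplicated(lay$probe_id)
  bed_df <- data.frame(chrom = lay$chrom[probe_rows],
                       start0 = lay$pos[probe_rows] - 1L,
                       end = lay$pos[probe_rows] - 1L + cfg$probe_span,
                       probe_id = lay$probe_id[probe_rows])
  bed_df <- bed_df[order(bed_df$chrom, bed_df$start0), ]
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  emit_truth_tables(sim$truth, file.path(dir, "truth"))

  rcfg <- run_config(vcf = vcf, panel = panel_tsv, probes = bed,
                     outdir = file.path(dir, "results"),
                     n_reps = n_reps, seed = seed)
  run_pipeline(rcfg)
  list(dir = dir, truth = sim$truth, vcf = vcf, panel = panel_tsv,
       probes = bed, results = file.path(dir, "results"))
}
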