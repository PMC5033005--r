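#' Simulation configuration for a synthetic allopolyploid capture panel
#'
#' Defines the study design the generator emulates: a diploid parental
#' taxon ("G"), a tetraploid parental taxon ("L") carrying fixed 2:2
#' heterozygosity on homeologous subgenomes, GLL triploid hybrids formed
#' from reduced gametes, and GGLLLL hexaploids formed by whole-genome
#' doubling of a triploid with optional injected allele-change events.
#' Read counts are then sampled per cell with Poisson total depth,
#' reference-biased allele draws, and a per-read error flip.
#'
#' Site classes are drawn independently per site:
#' \itemize{
#'   \item reciprocally fixed between the taxa with probability
#'     \code{d_fixed} (the diagnostic sites);
#'   \item polymorphic in the diploid taxon with probability
#'     \code{2 * het_parentA}: each diploid individual is heterozygous
#'     there with probability 1/2 (low-frequency variants segregate mostly
#'     as heterozygotes), giving a per-individual heterozygous fraction of
#'     \code{het_parentA};
#'   \item fixed-heterozygous (2:2 across homeologs) in every tetraploid
#'     individual with probability \code{het_parentB};
#'   \item otherwise monomorphic for the reference allele.
#' }
#' Under this design the truth heterozygosity of a triploid is
#' \code{d_fixed + het_parentB + het_parentA / 2} in expectation; the
#' defaults (0.0095, 0.047, 0.019) reproduce the per-taxon heterozygous
#' fractions observed in the study system (0.019 diploid, 0.047 tetraploid,
#' 0.066 triploid).
#'
#' @param n_probes number of probes tiled across linkage groups.
#' @param sites_per_probe variant sites per probe.
#' @param n_linkage_groups linkage groups (default 14).
#' @param d_fixed fraction of sites reciprocally fixed between the parents.
#' @param het_parentA per-individual heterozygous site fraction of the
#'   diploid parent.
#' @param het_parentB fixed-heterozygosity fraction of the tetraploid
#'   parent.
#' @param depth_mean Poisson mean read depth per cell: a single number, or
#'   a vector named by role (\code{parentA}, \code{parentB},
#'   \code{hybrid3x}, \code{hybrid6x}). Defaults follow the study's
#'   per-taxon mean depths.
#' @param bias capture-bias odds multiplier favouring reads whose allele
#'   matches the reference genome (1 = unbiased).
#' @param error per-read probability of being recorded as another of the
#'   site's alleles.
#' @param seed integer seed; mandatory, every stage derives its stream
#'   from it.
#' @param events list of \code{\link{event_spec}} records applied to
#'   hexaploids after doubling.
#' @param n_parentA,n_parentB,n_hybrid3x,n_hybrid6x samples per role.
#' @param pairing integer vector, one entry per hexaploid, giving the index
#'   of the triploid it doubles (default: the same index, recycled).
#' @param probe_span probe footprint in bp.
#' @param probe_spacing distance between probe starts within a linkage
#'   group, in bp.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_probes = 120, sites_per_probe = 10,
                       n_linkage_groups = 14,
                       d_fixed = 0.0095, het_parentA = 0.019,
                       het_parentB = 0.047,
                       depth_mean = c(parentA = 83, parentB = 88,
                                      hybrid3x = 105, hybrid6x = 100),
                       bias = 1, error = 0.001, seed,
                       events = list(),
                       n_parentA = 4, n_parentB = 4,
                       n_hybrid3x = 4, n_hybrid6x = 4,
                       pairing = NULL,
                       probe_span = 450, probe_spacing = 10000) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed) || seed > .Machine$integer.max - 3L) {
    stop("sim_config: seed must be an integer below 2^31 - 3")
  }
  fracs <- c(d_fixed = d_fixed, het_parentA = het_parentA,
             het_parentB = het_parentB)
  if (any(fracs < 0 | fracs > 1)) stop("sim_config: fractions must lie in [0, 1]")
  if (d_fixed + 2 * het_parentA + het_parentB > 1) {
    stop("sim_config: d_fixed + 2*het_parentA + het_parentB exceeds 1; ",
         "site classes must partition the genome")
  }
  if (any(depth_mean <= 0)) stop("sim_config: depth_mean must be positive")
  if (bias <= 0) stop("sim_config: bias must be positive")
  if (error < 0 || error >= 0.5) stop("sim_config: error must lie in [0, 0.5)")
  stopifnot(n_probes >= 1, sites_per_probe >= 1, n_linkage_groups >= 1,
            n_parentA >= 1, n_parentB >= 1, n_hybrid3x >= 0, n_hybrid6x >= 0)
  if (n_hybrid6x > 0 && n_hybrid3x == 0) {
    stop("sim_config: hexaploids require at least one triploid to double")
  }
  if (is.null(pairing)) {
    pairing <- if (n_hybrid6x > 0) ((seq_len(n_hybrid6x) - 1L) %% n_hybrid3x) + 1L
               else integer(0)
  }
  stopifnot(length(pairing) == n_hybrid6x,
            all(pairing >= 1 & pairing <= max(n_hybrid3x, 1L)))
  if (!all(vapply(events, inherits, logical(1), "event_spec"))) {
    stop("sim_config: events must be a list of event_spec records")
  }
  structure(list(n_probes = n_probes, sites_per_probe = sites_per_probe,
                 n_linkage_groups = n_linkage_groups, d_fixed = d_fixed,
                 het_parentA = het_parentA, het_parentB = het_parentB,
                 depth_mean = depth_mean, bias = bias, error = error,
                 seed = seed, events = events,
                 n_parentA = n_parentA, n_parentB = n_parentB,
                 n_hybrid3x = n_hybrid3x, n_hybrid6x = n_hybrid6x,
                 pairing = pairing, probe_span = probe_span,
                 probe_spacing = probe_spacing),
            class = "sim_config")
}

#' Specify an allele-change event injected into a hybrid
#'
#' Events model the post-polyploidization changes the pipeline is designed
#' to detect: loss or conversion of a single chromosome copy, loss of all
#' copies of one parental allele (indistinguishable from conversion at
#' read level, so implemented as conversion of every copy), and gain of an
#' allele absent from the parents.
#'
#' @param kind one of \code{single_copy_loss}, \code{single_copy_conversion},
#'   \code{full_allele_loss}, \code{novel_allele_gain}.
#' @param sample target sample id (must be a hybrid).
#' @param chrom linkage group of the affected span.
#' @param start,end 1-based inclusive positional span; every eligible site
#'   inside it is affected.
#' @param pos optional explicit positions instead of a span.
#' @param allele for conversions/gains, the allele copies are converted
#'   \emph{to} (\code{"ref"}, \code{"alt"} or \code{"novel"}); for losses,
#'   the allele that is lost.
#' @return an \code{event_spec}.
#' @export
event_spec <- function(kind, sample, chrom = NULL, start = NULL, end = NULL,
                       pos = NULL, allele = "ref") {
  kinds <- c("single_copy_loss", "single_copy_conversion",
             "full_allele_loss", "novel_allele_gain")
  if (!kind %in% kinds) stop("unknown event kind: ", kind)
  if (is.null(pos) && (is.null(chrom) || is.null(start) || is.null(end))) {
    stop("event_spec: give either pos or chrom+start+end")
  }
  if (!allele %in% c("ref", "alt", "novel")) {
    stop("event_spec: allele must be 'ref', 'alt' or 'novel'")
  }
  if (allele == "novel" && kind != "novel_allele_gain") {
    stop("event_spec: allele 'novel' only applies to novel_allele_gain")
  }
  structure(list(kind = kind, sample = sample, chrom = chrom,
                 start = start, end = end, pos = pos, allele = allele),
            class = "event_spec")
}

#' Build the sample panel implied by a simulation configuration
#'
#' Sample ids follow the field's shorthand: \code{gut-i} (diploid parent),
#' \code{lut-i} (tetraploid parent), \code{rob-i} (triploid), \code{per-i}
#' (hexaploid). Each hexaploid's \code{local_pair} is the triploid it was
#' doubled from.
#'
#' @param config sim_config
#' @return a \code{sample_panel}
#' @export
build_panel <- function(config) {
  mk <- function(prefix, n) if (n > 0) paste0(prefix, "-", seq_len(n)) else character(0)
  gut <- mk("gut", config$n_parentA); lut <- mk("lut", config$n_parentB)
  rob <- mk("rob", config$n_hybrid3x); per <- mk("per", config$n_hybrid6x)
  df <- data.frame(
    sample_id = c(gut, lut, rob, per),
    taxon = rep(c("guttatus", "luteus", "robertsii", "peregrinus"),
                c(length(gut), length(lut), length(rob), length(per))),
    ploidy = rep(c(2L, 4L, 3L, 6L),
                 c(length(gut), length(lut), length(rob), length(per))),
    role = rep(c("parentA", "parentB", "hybrid3x", "hybrid6x"),
               c(length(gut), length(lut), length(rob), length(per))),
    population = c(paste0("POP", seq_along(gut), recycle0 = TRUE),
                   paste0("POP", seq_along(lut), recycle0 = TRUE),
                   paste0("POP", seq_along(rob), recycle0 = TRUE),
                   paste0("POP", config$pairing, recycle0 = TRUE)),
    local_pair = c(rep(NA_character_, length(gut) + length(lut) + length(rob)),
                   rob[config$pairing]),
    stringsAsFactors = FALSE)
  as_sample_panel(df)
}

site_layout <- function(config) {
  n_lg <- config$n_linkage_groups
  lg_of_probe <- ((seq_len(config$n_probes) - 1L) %% n_lg) + 1L
  within_lg <- stats::ave(seq_len(config$n_probes), lg_of_probe,
                          FUN = seq_along)
  starts <- (within_lg - 1L) * config$probe_spacing + 1L
  offs <- round(seq(0, config$probe_span - 1L,
                    length.out = config$sites_per_probe))
  lay <- data.frame(
    chrom = rep(sprintf("LG%02d", lg_of_probe), each = config$sites_per_probe),
    pos = as.integer(rep(starts, each = config$sites_per_probe) + offs),
    probe_id = rep(sprintf("probe_%04d", seq_len(config$n_probes)),
                   each = config$sites_per_probe),
    stringsAsFactors = FALSE)
  # keep truth rows in (chrom, pos) order so they align with the
  # allele_depth_matrix site order
  lay[order(lay$chrom, lay$pos), , drop = FALSE]
}

#' Simulate the parental taxa of the panel
#'
#' Draws the site classes and parental genotypes (allele copy counts) under
#' \code{config}, seeding the RNG with \code{config$seed}. Diploid samples
#' are heterozygous at rate \code{het_parentA}; tetraploids carry fixed 2:2
#' heterozygosity at rate \code{het_parentB}; a fraction \code{d_fixed} of
#' sites is reciprocally fixed between the taxa, with the diploid-taxon
#' allele matching the reference genome at a random half of them.
#'
#' @param config sim_config
#' @return a \code{truth_set}: sites, panel, allele copy counts per
#'   (site, sample, allele) with allele 1 the reference, site categories,
#'   and an (initially empty) event log. Hybrid columns are unfilled until
#'   \code{\link{form_hybrids}}.
#' @export
simulate_parents <- function(config) {
  set.seed(config$seed)
  panel <- build_panel(config)
  lay <- site_layout(config)
  n <- nrow(lay)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  cat_p <- c(fixed = config$d_fixed, polyA = 2 * config$het_parentA,
             polyB = config$het_parentB)
  category <- sample(c(names(cat_p), "mono"), n, replace = TRUE,
                     prob = c(cat_p, 1 - sum(cat_p)))
  a_is_ref <- rep(NA, n)
  a_is_ref[category == "fixed"] <- sample(c(TRUE, FALSE),
                                          sum(category == "fixed"),
                                          replace = TRUE)
  alt[category == "mono"] <- NA_character_

  sites <- data.frame(chrom = lay$chrom, pos = lay$pos, ref = ref,
                      alt = ifelse(is.na(alt), ".", alt),
                      probe_id = lay$probe_id,
                      category = category, a_is_ref = a_is_ref,
                      stringsAsFactors = FALSE)

  samples <- panel$sample_id
  copies <- array(NA_integer_, dim = c(n, length(samples), 2L),
                  dimnames = list(NULL, samples, NULL))

  is_fixed <- category == "fixed"
  is_pA <- category == "polyA"
  is_pB <- category == "polyB"
  for (s in panel_samples(panel, "parentA")) {
    cp <- cbind(rep(2L, n), 0L)
    cp[is_fixed & !a_is_ref, ] <- rep(c(0L, 2L), each = sum(is_fixed & !a_is_ref))
    het <- is_pA & sample(c(TRUE, FALSE), n, replace = TRUE)
    cp[het, ] <- rep(c(1L, 1L), each = sum(het))
    copies[, s, ] <- cp
  }
  for (s in panel_samples(panel, "parentB")) {
    cp <- cbind(rep(4L, n), 0L)
    cp[is_fixed & a_is_ref, ] <- rep(c(0L, 4L), each = sum(is_fixed & a_is_ref))
    cp[is_pB, ] <- rep(c(2L, 2L), each = sum(is_pB))
    copies[, s, ] <- cp
  }

  structure(list(sites = sites, panel = panel, samples = samples,
                 copies = copies, config = config,
                 events = empty_event_log()),
            class = "truth_set")
}

empty_event_log <- function() {
  data.frame(kind = character(0), sample = character(0),
             chrom = character(0), pos = integer(0),
             allele = character(0), copies_changed = integer(0),
             stringsAsFactors = FALSE)
}

#' Form triploid and doubled hexaploid hybrids
#'
#' Each triploid receives one reduced gamete from a diploid parent (one
#' allele per site, drawn uniformly at heterozygous sites) and one reduced
#' gamete from a tetraploid parent (disomic inheritance: half of each
#' homeolog pair, so fixed 2:2 heterozygosity transmits as 1:1). Each
#' hexaploid is an exact whole-genome doubling of its paired triploid,
#' after which the configured events are applied in order and logged with
#' realized coordinates.
#'
#' @param truth truth_set from \code{\link{simulate_parents}}
#' @return the completed truth_set.
#' @export
form_hybrids <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 1L)
  panel <- truth$panel
  n <- nrow(truth$sites)
  gut <- panel_samples(panel, "parentA")
  lut <- panel_samples(panel, "parentB")
  rob <- panel_samples(panel, "hybrid3x")
  per <- panel_samples(panel, "hybrid6x")

  for (i in seq_along(rob)) {
    pa <- truth$copies[, gut[((i - 1L) %% length(gut)) + 1L], ]
    pb <- truth$copies[, lut[((i - 1L) %% length(lut)) + 1L], ]
    # diploid gamete: one allele; uniform at heterozygous sites
    g_ref <- ifelse(pa[, 1L] == 2L, 1L,
             ifelse(pa[, 1L] == 0L, 0L,
                    stats::rbinom(n, 1L, 0.5)))
    ga <- cbind(g_ref, 1L - g_ref)
    gb <- pb %/% 2L  # disomic gamete: tetraploid counts are even by design
    truth$copies[, rob[i], ] <- ga + gb
  }
  for (j in seq_along(per)) {
    src <- rob[config$pairing[j]]
    truth$copies[, per[j], ] <- 2L * truth$copies[, src, ]
  }
  for (ev in config$events) truth <- apply_event(truth, ev)
  truth
}

event_sites <- function(truth, ev) {
  if (!is.null(ev$pos)) {
    which(truth$sites$pos %in% ev$pos &
            (is.null(ev$chrom) | truth$sites$chrom == ev$chrom))
  } else {
    which(truth$sites$chrom == ev$chrom &
            truth$sites$pos >= ev$start & truth$sites$pos <= ev$end)
  }
}

apply_event <- function(truth, ev) {
  s <- ev$sample
  role <- truth$panel$role[match(s, truth$panel$sample_id)]
  if (is.na(role) || !role %in% c("hybrid3x", "hybrid6x")) {
    stop("event targets non-hybrid sample: ", s)
  }
  idx <- event_sites(truth, ev)
  log <- truth$events
  for (i in idx) {
    cp <- truth$copies[i, s, ]
    changed <- 0L
    allele_lab <- ev$allele
    if (ev$kind == "single_copy_conversion") {
      to <- if (ev$allele == "ref") 1L else 2L
      from <- 3L - to
      if (!is.na(cp[from]) && cp[from] >= 1L &&
          (to == 1L || truth$sites$alt[i] != ".")) {
        cp[from] <- cp[from] - 1L; cp[to] <- cp[to] + 1L; changed <- 1L
      }
    } else if (ev$kind == "full_allele_loss") {
      lost <- if (ev$allele == "ref") 1L else 2L
      kept <- 3L - lost
      if (cp[lost] >= 1L && cp[kept] >= 1L) {  # loss-as-conversion keeps ploidy
        changed <- cp[lost]
        cp[kept] <- cp[kept] + cp[lost]; cp[lost] <- 0L
      }
    } else if (ev$kind == "single_copy_loss") {
      lost <- if (ev$allele == "ref") 1L else 2L
      if (cp[lost] >= 1L) { cp[lost] <- cp[lost] - 1L; changed <- 1L }
    } else if (ev$kind == "novel_allele_gain") {
      if (truth$sites$alt[i] == ".") {
        # materialize an alternate allele unseen in the parents
        bases <- setdiff(c("A", "C", "G", "T"), truth$sites$ref[i])
        truth$sites$alt[i] <- bases[1L]
      } else if (ev$allele == "novel") {
        stop("novel_allele_gain at an already biallelic site is not ",
             "supported: the panel would no longer be biallelic")
      }
      if (cp[1L] >= 1L) { cp[1L] <- cp[1L] - 1L; cp[2L] <- cp[2L] + 1L; changed <- 1L }
      allele_lab <- truth$sites$alt[i]
    }
    if (changed > 0L) {
      truth$copies[i, s, ] <- cp
      log <- rbind(log, data.frame(kind = ev$kind, sample = s,
                                   chrom = truth$sites$chrom[i],
                                   pos = truth$sites$pos[i],
                                   allele = allele_lab,
                                   copies_changed = changed,
                                   stringsAsFactors = FALSE))
    }
  }
  truth$events <- log
  truth
}

lambda_for <- function(config, role) {
  lam <- config$depth_mean
  if (length(lam) == 1L && is.null(names(lam))) return(as.numeric(lam))
  if (!is.null(names(lam)) && role %in% names(lam)) return(as.numeric(lam[role]))
  if (length(lam) == 1L) return(as.numeric(lam))
  stop("depth_mean has no entry for role ", role)
}

#' Expected allele read fractions under the capture model
#'
#' The closed-form sampling probabilities the read simulator draws from:
#' for each (site, allele) the probability is proportional to the allele's
#' copy number times \code{bias} when the allele matches the reference.
#' With \code{bias = 1} this is simply copy count / ploidy.
#'
#' @param truth truth_set (hybrids formed)
#' @param sample sample id
#' @param bias odds multiplier (default from the truth's config)
#' @return numeric matrix (sites x 2) of expected read fractions.
#' @export
expected_allele_fraction <- function(truth, sample, bias = truth$config$bias) {
  cp <- truth$copies[, sample, , drop = TRUE]
  w <- cp * cbind(rep(bias, nrow(cp)), 1)
  w / rowSums(w)
}

#' Simulate capture read counts from a completed truth set
#'
#' Per (site, sample) cell: total depth is Poisson with the role's mean
#' depth; reads are drawn between the site's alleles with probability
#' proportional to copy count, multiplied by \code{bias} for the
#' reference-matching allele; each read is then recorded as the site's
#' other allele with probability \code{error}. Deterministic given the
#' configuration seed.
#'
#' @param truth truth_set with hybrids formed
#' @return an \code{\link{allele_depth_matrix}} over the full panel.
#' @export
simulate_reads <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 2L)
  if (anyNA(truth$copies)) {
    stop("simulate_reads: hybrids not formed yet; call form_hybrids() first")
  }
  n <- nrow(truth$sites)
  panel <- truth$panel
  depth <- array(0L, dim = c(n, nrow(panel), 2L))
  biallelic <- truth$sites$alt != "."
  eps <- config$error
  for (s in seq_len(nrow(panel))) {
    lam <- lambda_for(config, panel$role[s])
    dep <- stats::rpois(n, lam)
    cp <- truth$copies[, s, ]
    w1 <- cp[, 1L] * config$bias
    w2 <- cp[, 2L]
    tot_w <- w1 + w2
    p1 <- ifelse(tot_w > 0, w1 / tot_w, 0)
    dep[tot_w == 0] <- 0L  # a fully deleted site yields no reads
    x1 <- stats::rbinom(n, dep, p1)
    x2 <- dep - x1
    if (eps > 0) {
      flip_out <- stats::rbinom(n, x1, eps)
      flip_in <- stats::rbinom(n, x2, eps)
      # flips only defined where a second allele exists at the site
      flip_out[!biallelic] <- 0L
      flip_in[!biallelic] <- 0L
      x1 <- x1 - flip_out + flip_in
      x2 <- x2 + flip_out - flip_in
    }
    depth[, s, 1L] <- x1
    depth[, s, 2L] <- x2
  }
  allele_depth_matrix(truth$sites[, c("chrom", "pos", "ref", "alt", "probe_id")],
                      panel$sample_id, depth)
}

#' Run the whole generator: parents, hybrids, reads
#'
#' @param config sim_config
#' @return list with \code{truth} (truth_set), \code{adm}
#'   (allele_depth_matrix) and \code{panel}.
#' @export
simulate_panel <- function(config) {
  truth <- form_hybrids(simulate_parents(config))
  adm <- simulate_reads(truth)
  list(truth = truth, adm = adm, panel = truth$panel)
}

#' True heterozygous-site fraction per sample
#'
#' Computed from allele copy counts: a site is heterozygous when the sample
#' carries at least one copy of each of two alleles. For ploidies up to six
#' the minor-allele copy fraction is at least 1/6, inside the read-frequency
#' heterozygote band, so this is the estimand of
#' \code{\link{het_fraction}}.
#'
#' @param truth truth_set
#' @return named numeric vector over formed samples.
#' @export
truth_het_fraction <- function(truth) {
  out <- vapply(truth$samples, function(s) {
    cp <- truth$copies[, s, ]
    if (anyNA(cp)) return(NA_real_)
    mean(cp[, 1L] > 0L & cp[, 2L] > 0L)
  }, numeric(1))
  out
}

#' Ground-truth diagnostic sites by brute-force scan
#'
#' A site is truly diagnostic when every diploid-parent sample carries only
#' one allele, every tetraploid-parent sample carries only the other, at
#' full copy number.
#'
#' @param truth truth_set
#' @return data.frame: site index, chrom, pos, parentA_allele,
#'   parentB_allele, a_is_ref.
#' @export
truth_diagnostic_sites <- function(truth) {
  pa <- panel_samples(truth$panel, "parentA")
  pb <- panel_samples(truth$panel, "parentB")
  fixed_for <- function(samps) {
    m <- sapply(samps, function(s) {
      cp <- truth$copies[, s, ]
      ifelse(cp[, 2L] == 0L, 1L, ifelse(cp[, 1L] == 0L, 2L, NA_integer_))
    })
    if (is.null(dim(m))) m <- matrix(m, ncol = length(samps))
    same <- rowSums(m == m[, 1L]) == ncol(m)
    ifelse(!is.na(same) & same & !is.na(m[, 1L]), m[, 1L], NA_integer_)
  }
  fa <- fixed_for(pa)
  fb <- fixed_for(pb)
  idx <- which(!is.na(fa) & !is.na(fb) & fa != fb)
  alleles <- site_alleles(truth$sites)
  data.frame(site = idx,
             chrom = truth$sites$chrom[idx], pos = truth$sites$pos[idx],
             probe_id = truth$sites$probe_id[idx],
             parentA_allele = mapply(function(i, k) alleles[[i]][k], idx, fa[idx]),
             parentB_allele = mapply(function(i, k) alleles[[i]][k], idx, fb[idx]),
             a_is_ref = fa[idx] == 1L,
             stringsAsFactors = FALSE)
}

#' Positional span covering the last n truth-heterozygous sites of a
#' linkage group
#'
#' Helper for placing terminal loss/conversion events on sites where the
#' change is observable (the paired triploid is heterozygous there).
#'
#' @param truth truth_set
#' @param sample the triploid whose heterozygous sites define informativeness
#' @param chrom linkage group
#' @param n_sites number of terminal informative sites to cover
#' @return list(chrom, start, end, sites): a 1-based inclusive span.
#' @export
terminal_informative_span <- function(truth, sample, chrom, n_sites) {
  on_lg <- which(truth$sites$chrom == chrom)
  cp <- truth$copies[on_lg, sample, , drop = FALSE]
  inf <- on_lg[cp[, 1L, 1L] > 0L & cp[, 1L, 2L] > 0L]
  if (length(inf) < n_sites) {
    stop("linkage group ", chrom, " has only ", length(inf),
         " informative sites for ", sample, "; need ", n_sites)
  }
  chosen <- utils::tail(inf[order(truth$sites$pos[inf])], n_sites)
  list(chrom = chrom, start = min(truth$sites$pos[chosen]),
       end = max(truth$sites$pos[on_lg]), sites = chosen)
}

#' Write the simulator's ground-truth tables
#'
#' Emits the per-sample true heterozygosity, the brute-force diagnostic
#' site list and the realized event log as TSVs for the test harness and
#' for auditing a demo run.
#'
#' @param truth truth_set
#' @param dir output directory (created if needed)
#' @return the directory, invisibly.
#' @export
emit_truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  het <- truth_het_fraction(truth)
  write_table(data.frame(sample_id = names(het), truth_het = unname(het)),
              file.path(dir, "truth_het.tsv"))
  write_table(truth_diagnostic_sites(truth),
              file.path(dir, "truth_diagnostic_sites.tsv"))
  write_table(truth$events, file.path(dir, "truth_events.tsv"))
  invisible(dir)
}
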