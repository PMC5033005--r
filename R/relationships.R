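#' Allele presence/absence matrix
#'
#' Encodes each (sample, site) genotype state as alternate-allele
#' prevalence: homozygous-reference 0, heterozygous 0.5,
#' homozygous-alternate 1, missing \code{NA}. Sites that are not
#' polymorphic within the panel (no heterozygote and no pair of samples
#' homozygous for different alleles) are dropped.
#'
#' @param x allele_depth_matrix (filtered, biallelic).
#' @param lo,hi heterozygote band.
#' @return numeric matrix, samples in rows, loci in columns; column names
#'   \code{chrom:pos}.
#' @export
presence_matrix <- function(x, lo = 0.1, hi = 0.9) {
  st <- call_state(ref_freq(x), lo, hi)
  code <- matrix(NA_real_, n_sites(x), length(x$samples))
  code[st == "hom_ref"] <- 0
  code[st == "het"] <- 0.5
  code[st == "hom_alt"] <- 1
  any_het <- rowSums(st == "het") > 0L
  poly <- any_het | (rowSums(st == "hom_ref") > 0L & rowSums(st == "hom_alt") > 0L)
  code <- code[poly, , drop = FALSE]
  pm <- t(code)
  dimnames(pm) <- list(x$samples,
                       paste0(x$sites$chrom[poly], ":", x$sites$pos[poly]))
  pm
}

#' Nei's (1972) standard genetic distance from a presence matrix
#'
#' Each individual's per-locus allele frequencies are taken as
#' \eqn{(1 - s, s)} with \eqn{s} the alternate-allele prevalence code.
#' With \eqn{J_{xy} = \sum_l \sum_a p_{xla} p_{yla}} (and \eqn{J_x},
#' \eqn{J_y} the corresponding self-products) summed over loci typed in
#' both individuals, the distance is
#' \eqn{D = -\ln(J_{xy} / \sqrt{J_x J_y})}. Missing cells are excluded
#' pairwise (sums run over the shared loci only). Symmetric with zero
#' diagonal by construction; permutation-equivariant in samples and
#' invariant to locus order.
#'
#' @param pm presence matrix (samples x loci).
#' @return symmetric numeric matrix with sample labels.
#' @export
nei_distance <- function(pm) {
  n <- nrow(pm)
  if (n < 2L) stop("need at least two samples")
  if (ncol(pm) < 1L) stop("need at least one locus")
  D <- matrix(0, n, n, dimnames = list(rownames(pm), rownames(pm)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      xi <- pm[i, ]; yj <- pm[j, ]
      ok <- !is.na(xi) & !is.na(yj)
      if (!any(ok)) {
        stop("samples ", rownames(pm)[i], " and ", rownames(pm)[j],
             " share no typed loci; distance undefined")
      }
      xo <- xi[ok]; yo <- yj[ok]
      jxy <- sum(xo * yo + (1 - xo) * (1 - yo))
      jx <- sum(xo^2 + (1 - xo)^2)
      jy <- sum(yo^2 + (1 - yo)^2)
      D[i, j] <- D[j, i] <- -log(jxy / sqrt(jx * jy))
    }
  }
  D
}

# Saitou-Nei neighbor joining on a distance matrix; returns the join
# structure used for both Newick serialization and bipartition bookkeeping.
# Tie-breaking: among minimal-Q pairs, the lexicographically smallest
# (min-leaf-label, max-leaf-label) pair wins, so results are deterministic.
nj_core <- function(D) {
  labels <- rownames(D)
  n <- nrow(D)
  stopifnot(n >= 3L, identical(rownames(D), colnames(D)))
  if (any(abs(D - t(D)) > 1e-12)) stop("distance matrix is not symmetric")
  nwk <- labels                 # current newick fragment per active node
  leafset <- as.list(labels)    # leaves under each active node
  key <- labels                 # min leaf label, for tie-breaking
  act <- D
  clusters <- list()
  while (nrow(act) > 3L) {
    r <- nrow(act)
    rs <- rowSums(act)
    Q <- (r - 2) * act - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- cbind(pmin(key[cand[, 1]], key[cand[, 2]]),
                       pmax(key[cand[, 1]], key[cand[, 2]]))
    best <- order(pair_keys[, 1], pair_keys[, 2])[1L]
    i <- cand[best, 1]; j <- cand[best, 2]
    dij <- act[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    dnew <- (act[i, ] + act[j, ] - dij) / 2
    dnew <- dnew[-c(i, j)]
    merged_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], li, nwk[j], lj)
    merged_leaves <- sort(c(leafset[[i]], leafset[[j]]))
    clusters[[length(clusters) + 1L]] <- merged_leaves
    keep <- setdiff(seq_len(r), c(i, j))
    act <- act[keep, keep, drop = FALSE]
    act <- rbind(cbind(act, dnew), c(dnew, 0))
    nwk <- c(nwk[keep], merged_nwk)
    leafset <- c(leafset[keep], list(merged_leaves))
    key <- c(key[keep], min(merged_leaves))
  }
  # closed-form three-point resolution
  d12 <- act[1, 2]; d13 <- act[1, 3]; d23 <- act[2, 3]
  l1 <- max(0, (d12 + d13 - d23) / 2)
  l2 <- max(0, (d12 + d23 - d13) / 2)
  l3 <- max(0, (d13 + d23 - d12) / 2)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nwk[1], l1, nwk[2], l2, nwk[3], l3)
  list(newick = newick, clusters = clusters, labels = labels)
}

cluster_key <- function(leaves, all_labels) {
  # canonical bipartition key: the side not containing the smallest label
  side <- if (min(all_labels) %in% leaves) setdiff(all_labels, leaves) else leaves
  paste(sort(side), collapse = "|")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration implemented from first principles: repeatedly
#' join the pair minimizing the Q-criterion, assign branch lengths by the
#' standard divergence formulas, reduce the matrix, and resolve the final
#' three nodes in closed form. Exact on additive distances. Negative
#' branch lengths are clamped to zero with the excess moved to the sibling
#' branch; ties in Q are broken lexicographically by leaf label for
#' determinism.
#'
#' @param D symmetric distance matrix with row/column names, n >= 3.
#' @return an unrooted tree of class \code{phylo}, with attribute
#'   \code{"clusters"}: the internal-edge bipartitions as canonical keys.
#' @export
nj_tree <- function(D) {
  core <- nj_core(D)
  tree <- ape::read.tree(text = core$newick)
  attr(tree, "clusters") <- vapply(core$clusters, cluster_key,
                                   character(1), all_labels = core$labels)
  tree
}

#' Locus-bootstrap support for a neighbor-joining tree
#'
#' Resamples loci (presence-matrix columns) with replacement
#' \code{n_reps} times, recomputes Nei distance and the NJ tree for each
#' replicate, and reports for each internal edge of the original tree the
#' fraction of replicates containing the same leaf bipartition. Supports
#' are attached to the returned tree as internal node labels.
#'
#' @param pm presence matrix (samples x loci).
#' @param n_reps bootstrap replicates (>= 1; 1000 in a full analysis).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with \code{tree} (phylo, node labels = support fractions),
#'   \code{support} (data.frame of bipartition keys and supports).
#' @export
bootstrap_support <- function(pm, n_reps = 1000, seed) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (missing(seed)) stop("bootstrap_support: seed is mandatory")
  set.seed(as.integer(seed))
  D <- nei_distance(pm)
  core <- nj_core(D)
  keys <- vapply(core$clusters, cluster_key, character(1),
                 all_labels = core$labels)
  counts <- stats::setNames(numeric(length(keys)), keys)
  L <- ncol(pm)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    Db <- nei_distance(pm[, cols, drop = FALSE])
    kb <- vapply(nj_core(Db)$clusters, cluster_key, character(1),
                 all_labels = core$labels)
    hit <- keys %in% kb
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / n_reps
  tree <- ape::read.tree(text = core$newick)
  tree <- label_nodes_with_support(tree, support)
  list(tree = tree,
       support = data.frame(bipartition = keys, support = unname(support),
                            stringsAsFactors = FALSE))
}

label_nodes_with_support <- function(tree, support) {
  labs <- rep("", tree$Nnode)
  all_labels <- tree$tip.label
  for (node in seq_len(tree$Nnode) + length(all_labels)) {
    kids <- leaves_under(tree, node)
    key <- cluster_key(kids, all_labels)
    idx <- match(key, names(support))
    if (!is.na(idx)) labs[node - length(all_labels)] <- format(support[idx], digits = 3)
  }
  tree$node.label <- labs
  tree
}

leaves_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  sort(unlist(lapply(kids, leaves_under, tree = tree)))
}

#' Principal component analysis of the presence matrix
#'
#' Column-centered PCA (no variance scaling — the data are allele
#' prevalence codes on a common scale), computed from first principles by
#' singular value decomposition of the centered matrix. Missing cells are
#' replaced by the locus mean (equivalently, zero after centering).
#'
#' @param pm presence matrix (samples x loci).
#' @param n_axes number of components to return (default: all with
#'   nonzero variance).
#' @return list with \code{scores} (samples x components),
#'   \code{explained} (fraction of variance per returned component),
#'   \code{sdev} (component standard deviations).
#' @export
pca_presence <- function(pm, n_axes = NULL) {
  mu <- colMeans(pm, na.rm = TRUE)
  X <- sweep(pm, 2L, mu)
  X[is.na(X)] <- 0
  sv <- svd(X)
  lambda <- sv$d^2
  nz <- which(lambda > max(lambda) * 1e-12)
  if (max(lambda) == 0) {
    return(list(scores = matrix(numeric(0), nrow(pm), 0,
                                dimnames = list(rownames(pm), NULL)),
                explained = numeric(0), sdev = numeric(0)))
  }
  if (is.null(n_axes)) n_axes <- length(nz)
  nz <- nz[seq_len(min(n_axes, length(nz)))]
  scores <- sv$u[, nz, drop = FALSE] %*% diag(sv$d[nz], length(nz))
  dimnames(scores) <- list(rownames(pm), paste0("PC", seq_along(nz)))
  list(scores = scores,
       explained = lambda[nz] / sum(lambda),
       sdev = sv$d[nz] / sqrt(max(1, nrow(pm) - 1)))
}
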