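test_that("presence codes follow the state encoding and drop monomorphic loci", {
  f <- rbind(c(0.5, 0.95, 0.02),
             c(0.97, 0.98, 0.99),   # monomorphic hom_ref everywhere -> drop
             c(0.5, 0.5, 0.5))
  adm <- adm_from_freq(f, depth = 100L)
  pm <- presence_matrix(adm)
  expect_equal(dim(pm), c(3L, 2L))
  expect_equal(unname(pm[, 1]), c(0.5, 0, 1))
  expect_equal(unname(pm[, 2]), c(0.5, 0.5, 0.5))
})

test_that("Nei distance matches the closed-form hand example", {
  # two loci; x states (1, 0), y states (0.5, 0)
  pm <- rbind(x = c(1, 0), y = c(0.5, 0))
  D <- nei_distance(pm)
  jxy <- (0 * 0.5 + 1 * 0.5) + (1 * 1 + 0 * 0)    # = 1.5
  jx <- (0 + 1) + (1 + 0)                          # = 2
  jy <- (0.25 + 0.25) + (1 + 0)                    # = 1.5
  expect_equal(D["x", "y"], -log(jxy / sqrt(jx * jy)), tolerance = 1e-12)
  expect_equal(D["x", "y"], -log(1.5 / sqrt(2 * 1.5)), tolerance = 1e-12)
})

test_that("Nei distance is zero on identical samples, symmetric, order-invariant", {
  set.seed(179)
  pm <- matrix(sample(c(0, 0.5, 1), 60, replace = TRUE), nrow = 6)
  rownames(pm) <- paste0("s", 1:6)
  pm[2, ] <- pm[1, ]
  D <- nei_distance(pm)
  expect_equal(D[1, 2], 0)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  # locus order invariance and sample permutation equivariance
  D2 <- nei_distance(pm[, sample.int(ncol(pm))])
  expect_equal(D2, D)
  perm <- sample.int(nrow(pm))
  D3 <- nei_distance(pm[perm, ])
  expect_equal(D3, D[perm, perm])
  # missing cells are excluded pairwise
  pm_na <- pm; pm_na[1, 1:3] <- NA
  expect_equal(nei_distance(pm_na)[1, 3],
               nei_distance(pm[, 4:10, drop = FALSE])[1, 3])
  pm_bad <- pm; pm_bad[1, ] <- NA
  expect_error(nei_distance(pm_bad), "share no typed loci")
})

test_that("three-taxon neighbor joining uses the closed-form branch lengths", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[rownames(D), colnames(D)], D, tolerance = 1e-9)
  la <- (5 + 9 - 10) / 2
  expect_equal(tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")],
               la, tolerance = 1e-9)
  expect_error(nj_tree(D[1:2, 1:2]), "n >= 3|>= 3")
})

test_that("neighbor joining is exact on additive matrices", {
  # tree ((A:2,B:3):1,(C:4,D:5):2) -> additive pairwise path lengths
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 2 + 1 + 2 + 4
  D["A", "D"] <- D["D", "A"] <- 2 + 1 + 2 + 5
  D["B", "C"] <- D["C", "B"] <- 3 + 1 + 2 + 4
  D["B", "D"] <- D["D", "B"] <- 3 + 1 + 2 + 5
  D["C", "D"] <- D["D", "C"] <- 9
  tr <- nj_tree(D)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[rownames(D), colnames(D)], D, tolerance = 1e-9)
  expect_true("A|B" %in% attr(tr, "clusters") ||
                "C|D" %in% attr(tr, "clusters"))

  # random additive matrices from random trees, path-length oracle
  set.seed(181)
  for (rep in 1:5) {
    rt <- ape::rtree(8, br = function(n) runif(n, 0.1, 2))
    rt$tip.label <- paste0("t", 1:8)
    Dr <- ape::cophenetic.phylo(rt)
    Dr <- Dr[sort(rownames(Dr)), sort(rownames(Dr))]
    tr2 <- nj_tree(Dr)
    pl2 <- ape::cophenetic.phylo(tr2)
    expect_equal(pl2[rownames(Dr), colnames(Dr)], Dr, tolerance = 1e-8)
  }
})

test_that("our neighbor joining agrees with an independent implementation", {
  set.seed(191)
  pm <- matrix(sample(c(0, 0.5, 1), 300, replace = TRUE,
                      prob = c(0.5, 0.2, 0.3)), nrow = 10)
  rownames(pm) <- paste0("s", sprintf("%02d", 1:10))
  D <- nei_distance(pm)
  ours <- nj_tree(D)
  theirs <- ape::nj(stats::as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap supports are deterministic and saturate on perfect splits", {
  pm <- rbind(a1 = rep(0, 20), a2 = rep(0, 20), a3 = rep(0, 20),
              b1 = rep(0.5, 20), b2 = rep(0.5, 20), b3 = rep(0.5, 20))
  bs <- bootstrap_support(pm, n_reps = 50, seed = 99)
  split_keys <- bs$support$bipartition
  ab <- split_keys[split_keys %in% c("b1|b2|b3", "a1|a2|a3")]
  expect_gte(length(ab), 1L)
  expect_true(all(bs$support$support[bs$support$bipartition %in% ab] == 1))
  bs2 <- bootstrap_support(pm, n_reps = 50, seed = 99)
  expect_identical(bs$support, bs2$support)
  expect_error(bootstrap_support(pm, n_reps = 0, seed = 1), "n_reps")
  # supports land on the tree as internal node labels
  expect_true(any(nchar(bs$tree$node.label) > 0))
})

test_that("PCA scores are orthogonal, variance-ordered and complete", {
  set.seed(193)
  pm <- matrix(sample(c(0, 0.5, 1), 30 * 8, replace = TRUE), nrow = 8)
  rownames(pm) <- paste0("s", 1:8)
  pc <- pca_presence(pm)
  G <- crossprod(pc$scores)
  expect_equal(G[upper.tri(G)], rep(0, sum(upper.tri(G))), tolerance = 1e-8)
  expect_true(all(diff(diag(G)) <= 1e-8))
  expect_equal(sum(pc$explained), 1, tolerance = 1e-9)
  # against the standard implementation (oracle): same scores up to sign
  pr <- stats::prcomp(ifelse(is.na(pm), colMeans(pm, na.rm = TRUE), pm),
                      center = TRUE, scale. = FALSE)
  k <- ncol(pc$scores)
  for (j in seq_len(min(3, k))) {
    expect_equal(abs(pc$scores[, j]), abs(pr$x[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # duplicated samples score identically
  pm2 <- rbind(pm, dup = pm[1, ])
  pc2 <- pca_presence(pm2)
  expect_equal(unname(pc2$scores["dup", ]), unname(pc2$scores["s1", ]),
               tolerance = 1e-8)
  # constant matrix has no components
  pc0 <- pca_presence(matrix(0.5, 4, 6, dimnames = list(paste0("c", 1:4), NULL)))
  expect_equal(length(pc0$explained), 0L)
})

test_that("the synthetic study panel reproduces the published structure", {
  sim <- small_sim(197, n_probes = 300, sites_per_probe = 5,
                   depth_mean = 100)
  snp <- filter_sites(sim$adm, polymorphic_only = TRUE)$matrix
  pm <- presence_matrix(snp)
  D <- nei_distance(pm)
  tr <- nj_tree(D)
  clust <- attr(tr, "clusters")
  # bipartition keys are canonicalized to the side away from the smallest
  # label, so the diploid-parent clade is keyed by its complement
  key_for <- function(leaves, all) {
    side <- if (min(all) %in% leaves) setdiff(all, leaves) else leaves
    paste(sort(side), collapse = "|")
  }
  all_s <- rownames(pm)
  gut <- key_for(paste0("gut-", 1:4), all_s)
  lut <- key_for(paste0("lut-", 1:4), all_s)
  expect_true(gut %in% clust)
  expect_true(lut %in% clust)
  bs <- bootstrap_support(pm, n_reps = 100, seed = 7)
  expect_gte(bs$support$support[bs$support$bipartition == gut], 0.95)
  expect_gte(bs$support$support[bs$support$bipartition == lut], 0.95)
  # PC1 places hybrids between the parental clusters
  pc <- pca_presence(pm)
  s1 <- pc$scores[, 1]
  gutm <- mean(s1[paste0("gut-", 1:4)]); lutm <- mean(s1[paste0("lut-", 1:4)])
  hybm <- mean(s1[c(paste0("rob-", 1:4), paste0("per-", 1:4))])
  expect_true((hybm > min(gutm, lutm)) && (hybm < max(gutm, lutm)))
})
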