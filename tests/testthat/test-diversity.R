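test_that("expected rarefied richness matches the hypergeometric formula", {
  # full-depth rarefaction returns the observed richness
  x <- c(4, 0, 1, 7)
  expect_equal(rarefied_richness(x, sum(x)), 3)
  # hand case: counts (5,5), depth 2 -> 2*(1 - C(5,2)/C(10,2)) = 14/9
  expect_equal(rarefied_richness(c(5, 5), 2), 14 / 9, tolerance = 1e-12)
  # a single taxon always yields richness 1
  expect_equal(rarefied_richness(c(9, 0), 1), 1)
  expect_error(rarefied_richness(c(2, 2), 10), "exceeds")
})

test_that("analytic rarefaction agrees with Monte-Carlo subsampling", {
  set.seed(42)
  for (i in 1:5) {
    x <- rpois(15, lambda = sample(3:25, 1)) + sample(0:1, 15, replace = TRUE)
    depth <- max(2, floor(sum(x) / 2))
    mc <- rarefied_richness(x, depth, method = "montecarlo",
                            n_draws = 1500, seed = i)
    expect_lt(abs(rarefied_richness(x, depth) - mc),
              3 * attr(mc, "se") + 1e-3)
  }
})

test_that("Shannon entropy in nats matches hand values", {
  expect_equal(shannon_entropy(rep(5, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(10, 0, 0)), 0)
  h <- -(0.25 * log(0.25) * 2 + 0.5 * log(0.5))
  expect_equal(shannon_entropy(c(1, 1, 2)), h, tolerance = 1e-12)
  expect_error(shannon_entropy(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis distances match the 2*min formula", {
  m <- cbind(a = c(6, 0, 2), b = c(2, 4, 2))
  expect_equal(as.numeric(bray_curtis(m)), 0.5, tolerance = 1e-12)
  same <- cbind(a = c(3, 1), b = c(3, 1))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disj <- cbind(a = c(5, 0), b = c(0, 5))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  expect_error(bray_curtis(cbind(a = c(1, 1), b = c(0, 0))), "zero-sum")
})

test_that("unweighted UniFrac reduces to Jaccard on a star tree", {
  set.seed(7)
  m <- matrix(rpois(60, 2), nrow = 6,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  m[1, ] <- m[1, ] + 1   # keep every sample non-empty
  tree <- star_tree(rownames(m))
  uu <- as.matrix(unweighted_unifrac(m, tree))
  jac <- as.matrix(vegan::vegdist(t(m > 0), method = "jaccard",
                                  binary = TRUE))
  expect_lt(max(abs(uu - jac[rownames(uu), colnames(uu)])), 1e-12)
})

test_that("unweighted UniFrac separates disjoint clades completely", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  m <- matrix(c(3, 2, 0, 0,
                0, 0, 4, 1), ncol = 2,
              dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  expect_equal(as.numeric(unweighted_unifrac(m, tree)), 1)
  ident <- matrix(c(1, 1, 0, 2, 2, 0, 2, 0), ncol = 2,
                  dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  ident[, 2] <- ident[, 1] * 2   # same presence sets
  expect_equal(as.numeric(unweighted_unifrac(ident, tree)), 0)
  rownames(m)[1] <- "missing_tip"
  expect_error(unweighted_unifrac(m, tree), "absent from tree")
})

test_that("weighted UniFrac equals half-L1 on a star tree and 1 for disjoint leaves", {
  set.seed(8)
  m <- matrix(rpois(40, 4) + 1, nrow = 5,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:8)))
  tree <- star_tree(rownames(m))
  wu <- as.matrix(weighted_unifrac(m, tree))
  rel <- relative_abundance(m)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(wu[i, j], sum(abs(rel[, i] - rel[, j])) / 2,
                 tolerance = 1e-12)
  two <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("t1", "t2"), c("a", "b")))
  tree2 <- ape::read.tree(text = "(t1:1,t2:1);")
  expect_equal(as.numeric(weighted_unifrac(two, tree2)), 1)
  prop <- matrix(c(2, 4, 1, 2), 2,
                 dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_equal(as.numeric(weighted_unifrac(prop, tree2)), 0)
})

test_that("weighted UniFrac agrees with phyloseq on a random instance", {
  set.seed(21)
  n <- 12
  tree <- ape::rcoal(n, tip.label = paste0("t", 1:n))
  m <- matrix(rpois(n * 6, 5) + 1, nrow = n,
              dimnames = list(tree$tip.label, paste0("s", 1:6)))
  ours <- as.matrix(weighted_unifrac(m, tree))
  ps <- phyloseq::phyloseq(phyloseq::otu_table(m, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tree))
  theirs <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                        normalized = TRUE))
  expect_lt(max(abs(ours - theirs[rownames(ours), colnames(ours)])), 1e-10)
  ours_u <- as.matrix(unweighted_unifrac(m > 0, tree))
  theirs_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_lt(max(abs(ours_u - theirs_u[rownames(ours_u), colnames(ours_u)])),
            1e-10)
})

test_that("distance outputs satisfy the distance-matrix invariants", {
  set.seed(33)
  for (i in 1:5) {
    m <- matrix(rpois(8 * 6, 3), nrow = 8,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:6)))
    m[1, ] <- m[1, ] + 1
    tree <- ape::rcoal(8, tip.label = rownames(m))
    for (d in list(bray_curtis(m), jaccard_distance(m),
                   unweighted_unifrac(m, tree), weighted_unifrac(m, tree))) {
      dm <- as.matrix(d)
      expect_true(all(abs(dm - t(dm)) < 1e-12))
      expect_true(all(diag(dm) == 0))
      expect_true(all(dm >= 0 & dm <= 1 + 1e-12))
    }
  }
})

test_that("PCoA reconstructs planar configurations", {
  set.seed(11)
  for (i in 1:3) {
    pts <- matrix(rnorm(8), 4, 2)
    d <- dist(pts)
    fit <- pcoa(d, n_axes = 2)
    expect_lt(max(abs(dist(fit$coordinates) - d)), 1e-8)
    expect_true(all(diff(fit$eigenvalues) <= 1e-9))  # descending order
  }
  # collinear points: axis 1 carries all the spacing
  pts <- cbind(c(0, 1, 3), 0)
  fit <- pcoa(dist(pts), n_axes = 2)
  expect_equal(abs(diff(fit$coordinates[, 1])), c(1, 2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(fit$coordinates[, 2])), 1e-8)
  # degenerate all-zero distances
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(pcoa(as.dist(z), 2)$coordinates == 0))
  expect_error(pcoa(dist(pts), n_axes = 9), "exceeds")
})

test_that("PERMANOVA recovers trivial structure", {
  # zero within-group, positive between-group distance: R2 = 1
  dm <- matrix(1, 6, 6) - diag(1, 6)
  dm[1:3, 1:3] <- 0; dm[4:6, 4:6] <- 0
  rownames(dm) <- colnames(dm) <- paste0("s", 1:6)
  g <- setNames(rep(c("a", "b"), each = 3), rownames(dm))
  pr <- permanova(dm, g, permutations = 199, seed = 1)
  expect_equal(pr$r_squared, 1, tolerance = 1e-12)
  # all pairwise distances equal: F identical under any relabelling, p = 1
  eq <- matrix(1, 6, 6) - diag(1, 6)
  rownames(eq) <- colnames(eq) <- paste0("s", 1:6)
  pr2 <- permanova(eq, g, permutations = 199, seed = 1)
  expect_equal(pr2$p_value, 1)
  expect_error(permanova(dm, setNames(c("a", rep("b", 5)), rownames(dm)),
                         permutations = 99), "at least 2")
})

test_that("exhaustive PERMANOVA p equals a brute-force enumeration oracle", {
  set.seed(14)
  pts <- matrix(rnorm(12), 6, 2)
  pts[4:6, ] <- pts[4:6, ] + 1.5
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:6)
  g <- setNames(rep(c("a", "b"), each = 3), rownames(dm))
  pr <- permanova(dm, g, permutations = "exhaustive")

  # independent oracle: pseudo-F from scratch for every permutation
  d2 <- dm^2
  fstat_oracle <- function(lab) {
    n <- 6; a <- 2
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (gg in unique(lab)) {
      i <- which(lab == gg)
      ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  perms <- gtools_style_perms <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
  }
  pm <- perms(6)
  f_obs <- fstat_oracle(g)
  f_all <- apply(pm, 1, function(ix) fstat_oracle(g[ix]))
  expect_equal(pr$p_value, mean(f_all >= f_obs), tolerance = 1e-12)
  expect_equal(pr$pseudo_f, f_obs, tolerance = 1e-12)
})

test_that("PERMANOVA matches vegan::adonis2 on observed statistics", {
  set.seed(90)
  m <- matrix(rpois(10 * 12, 6), nrow = 10,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:12)))
  d <- bray_curtis(m)
  g <- setNames(rep(c("x", "y", "z"), each = 4), colnames(m))
  ours <- permanova(d, g, permutations = 199, seed = 3)
  df <- data.frame(g = g)
  ref <- vegan::adonis2(d ~ g, data = df, permutations = 99)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$r_squared, ref$R2[1], tolerance = 1e-10)

  # numeric covariate: distance-matrix regression form
  z <- setNames(rnorm(12), colnames(m))
  ours_n <- permanova(d, z, permutations = 199, seed = 3)
  ref_n <- vegan::adonis2(d ~ z, data = data.frame(z = z), permutations = 99)
  expect_equal(ours_n$pseudo_f, ref_n$F[1], tolerance = 1e-10)
  expect_equal(ours_n$r_squared, ref_n$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA results do not depend on sample ordering", {
  set.seed(15)
  m <- matrix(rpois(8 * 10, 5), nrow = 8,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  d <- bray_curtis(m)
  g <- setNames(rep(c("a", "b"), 5), colnames(m))
  p1 <- permanova(d, g, permutations = 199, seed = 7)
  ord <- sample(10)
  d2 <- as.dist(as.matrix(d)[ord, ord])
  p2 <- permanova(d2, g[ord], permutations = 199, seed = 7)
  expect_equal(p1$p_value, p2$p_value)
  expect_equal(p1$pseudo_f, p2$pseudo_f, tolerance = 1e-12)
})
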