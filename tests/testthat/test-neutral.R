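test_that("predicted occupancy honours its boundary cases", {
  expect_equal(predicted_occupancy(0, 1e4, 0.1), 0)
  expect_equal(predicted_occupancy(1, 1e4, 0.1), 1)
  expect_equal(predicted_occupancy(c(0, 1), 1e4, 0.5,
                                   detection = "sampling"), c(0, 1))
  expect_error(predicted_occupancy(0.5, 1e4, 2), "m")
})

test_that("the threshold form matches numerical quadrature of the Beta tail", {
  cases <- expand.grid(p = c(1e-4, 1e-3, 0.01, 0.1),
                       m = c(0.05, 0.1, 0.5))
  for (i in seq_len(nrow(cases))) {
    p <- cases$p[i]; m <- cases$m[i]; N <- 1e4; d <- 1
    got <- predicted_occupancy(p, N, m, d)
    want <- integrate(function(a) dbeta(a, N * m * p, N * m * (1 - p)),
                      lower = d / N, upper = 1, rel.tol = 1e-12)$value
    expect_lt(abs(got - want), 1e-8)
  }
})

test_that("the sampling form matches integration of the Beta-binomial tail", {
  for (p in c(1e-4, 1e-3, 0.01)) {
    N <- 1e4; m <- 0.1; D <- 8000
    got <- predicted_occupancy(p, N, m, detection = "sampling", depth = D)
    a <- N * m * p; b <- N * m * (1 - p)
    # E[(1-x)^D] under Beta(a,b), with the substitution u = x^a that
    # removes the endpoint singularity of the Beta density
    integrand <- function(u) (1 - u^(1 / a))^(b + D - 1)
    want <- 1 - integrate(integrand, 0, 1, rel.tol = 1e-11)$value /
      (a * beta(a, b))
    expect_lt(abs(got - want), 1e-8)
  }
  # heterogeneous depths: the mean of the per-depth curves
  depths <- c(5000, 20000)
  got2 <- predicted_occupancy(1e-3, 1e4, 0.1, detection = "sampling",
                              depth = depths)
  want2 <- mean(vapply(depths, function(D)
    predicted_occupancy(1e-3, 1e4, 0.1, detection = "sampling", depth = D),
    numeric(1)))
  expect_equal(got2, want2, tolerance = 1e-12)
})

test_that("predicted occupancy is monotone in p and in m", {
  ps <- 10^seq(-5, -0.5, length.out = 40)
  for (det in c("threshold", "sampling")) {
    occ <- predicted_occupancy(ps, 1e4, 0.1, detection = det)
    expect_true(all(diff(occ) >= -1e-12))
    for (p in c(1e-4, 1e-3, 1e-2)) {
      ms <- seq(0.01, 1, length.out = 30)
      occ_m <- vapply(ms, function(m)
        predicted_occupancy(p, 1e4, m, detection = det), numeric(1))
      expect_true(all(diff(occ_m) >= -1e-12))
    }
  }
})

test_that("a noise-free curve is refit to its own migration rate", {
  N <- 1e4; m_true <- 0.2
  p <- 10^seq(-5, -1, length.out = 60)
  occ <- predicted_occupancy(p, N, m_true, detection = "threshold")
  fit <- fit_neutral_profiles(p, occ, N = N, n_samples = 36,
                              detection = "threshold")
  expect_lt(abs(fit$m - m_true), 1e-4)
  expect_gt(fit$r_squared, 0.9999)
  # same property for the sampling detection model
  occ2 <- predicted_occupancy(p, N, m_true, detection = "sampling", depth = N)
  fit2 <- fit_neutral_profiles(p, occ2, N = N, n_samples = 36,
                               detection = "sampling")
  expect_lt(abs(fit2$m - m_true), 1e-4)
})

test_that("the optimizer beats a dense grid search", {
  sim <- simulate_neutral_dataset(small_cfg(seed = 31, source_alpha = 8,
                                            n_signal_taxa = 0,
                                            n_planted_core = 0,
                                            n_planted_above = 0,
                                            n_planted_below = 0))
  fit <- fit_neutral(sim$dataset, phase = NULL)
  counts <- sim$dataset$counts
  depth <- colSums(counts)
  p <- rowMeans(sweep(counts, 2, depth, "/"))
  occ <- rowMeans(counts >= 1)
  keep <- p > 0
  sse <- function(m) sum((occ[keep] - predicted_occupancy(
    p[keep], fit$N, m, detection = "sampling", depth = depth))^2)
  grid_min <- min(vapply(exp(seq(log(1e-6), 0, length.out = 1000)), sse,
                         numeric(1)))
  expect_lte(fit$sse, grid_min + 1e-12)
})

test_that("classification is neutral on the curve and flags planted taxa", {
  # observed exactly at the prediction: never outside the band
  N <- 1e4
  p <- 10^seq(-4, -1, length.out = 30)
  occ <- predicted_occupancy(p, N, 0.1, detection = "threshold")
  fit <- fit_neutral_profiles(p, occ, N = N, n_samples = 36,
                              detection = "threshold")
  expect_true(all(fit$taxa$class == "neutral"))

  sim <- simulate_dataset(small_cfg(seed = 32, source_alpha = 8))
  for (g in c("Low", "Meso")) {
    f <- fit_neutral(sim$dataset, group = g)
    cl <- setNames(as.character(f$taxa$class), f$taxa$taxon)
    expect_true(all(cl[sim$truth$planted_above_ids] == "above"),
                label = paste("above in", g))
    expect_true(all(cl[sim$truth$planted_below_ids] == "below"),
                label = paste("below in", g))
  }
})

test_that("the fit is invariant to taxon ordering", {
  sim <- simulate_neutral_dataset(small_cfg(seed = 33, source_alpha = 8))
  counts <- sim$dataset$counts
  f1 <- fit_neutral(counts)
  set.seed(1)
  perm <- sample(nrow(counts))
  f2 <- fit_neutral(counts[perm, ])
  expect_equal(f1$m, f2$m, tolerance = 1e-10)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
})

test_that("degenerate occupancy data is flagged unreliable", {
  p <- 10^seq(-3, -1, length.out = 25)
  expect_warning(fit <- fit_neutral_profiles(p, rep(1, 25), N = 1e4,
                                             n_samples = 10),
                 "unreliable")
  expect_true(fit$unreliable)
})

test_that("class tallies aggregate to the requested rank", {
  sim <- simulate_dataset(small_cfg(seed = 34))
  f <- fit_neutral(sim$dataset, group = "Low")
  tally <- neutral_class_tally(f, sim$dataset$taxonomy, rank = "phylum")
  expect_equal(sum(tally), sum(!is.na(f$taxa$class)))
  expect_true(all(rownames(tally) %in% sim$dataset$taxonomy$phylum))
})
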