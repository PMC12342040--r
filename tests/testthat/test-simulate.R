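test_that("source community is a long-tailed probability vector", {
  expect_error(simulate_source_community(1), ">= 2")
  p <- simulate_source_community(300)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_identical(p, simulate_source_community(300))
  expect_true(p[1] / p[300] > 100)       # long tail: > 2 decades
  expect_true(all(diff(p) < 0))          # monotone rank-abundance
})

test_that("the simulated design matches the study layout", {
  sim <- simulate_neutral_dataset(simulation_config(n_taxa = 60, seed = 1))
  md <- sim$dataset$metadata
  expect_equal(sum(md$phase == "DNA-enrichment"), 36L)  # 3 x 4 x 3
  expect_equal(sum(md$phase != "DNA-enrichment"), 27L)  # 3 x 3 x 3 cDNA
  expect_equal(ncol(sim$dataset$counts), 63L)
  expect_setequal(unique(md$group), c("Low", "Meso", "Thermo"))
  expect_setequal(unique(md$temperature_nominal), c(15, 35, 48))
  expect_setequal(sim$dataset$tree$tip.label, rownames(sim$dataset$counts))
})

test_that("identical configurations give byte-identical fixtures", {
  cfg <- small_cfg(seed = 9)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  s1 <- simulate_dataset(cfg); write_fixture(s1$dataset, s1$truth, d1)
  s2 <- simulate_dataset(cfg); write_fixture(s2$dataset, s2$truth, d2)
  for (f in c("abundance.tsv", "taxonomy.tsv", "metadata.tsv", "tree.nwk",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  s3 <- simulate_dataset(small_cfg(seed = 10))
  expect_false(identical(s1$dataset$counts, s3$dataset$counts))
})

test_that("per-taxon mean abundance tracks the source community", {
  cfg <- simulation_config(n_taxa = 300, seed = 4, group_effect = 0,
                           n_planted_core = 0, n_planted_above = 0,
                           n_planted_below = 0, n_signal_taxa = 0)
  sim <- simulate_neutral_dataset(cfg)   # 63 samples
  obs <- rowMeans(relative_abundance(sim$dataset$counts))
  keep <- sim$truth$source_p > 10 / cfg$local_community_size
  rho <- cor(obs[keep], sim$truth$source_p[keep], method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("larger migration gives higher occupancy at fixed source", {
  occ_at <- function(m) {
    sim <- simulate_neutral_dataset(small_cfg(seed = 6, m_true = m,
                                              n_planted_core = 0,
                                              n_planted_above = 0,
                                              n_planted_below = 0,
                                              n_signal_taxa = 0))
    mean(sim$dataset$counts >= 1)
  }
  expect_gt(occ_at(0.5), occ_at(0.05))
})

test_that("planted taxa have the occupancy patterns they encode", {
  sim <- simulate_dataset(small_cfg(seed = 2))
  counts <- sim$dataset$counts
  tr <- sim$truth
  # above: present in every sample
  expect_true(all(counts[tr$planted_above_ids, ] >= 1))
  # below: confined to one replicate line
  occ_below <- rowMeans(counts[tr$planted_below_ids, , drop = FALSE] >= 1)
  share <- mean(sim$dataset$metadata$replicate == 1)
  expect_true(all(occ_below <= share + 1e-12))
  # disjoint planted sets
  expect_length(intersect(tr$planted_core_ids, tr$planted_above_ids), 0)
  expect_length(intersect(tr$planted_core_ids, tr$planted_below_ids), 0)
  expect_length(intersect(tr$planted_above_ids, tr$planted_below_ids), 0)
  # core: detected in every sample at clearly higher abundance than "above"
  expect_true(all(counts[tr$planted_core_ids, ] >= 1))
  expect_gt(min(rowMeans(relative_abundance(counts)[tr$planted_core_ids, ])),
            max(rowMeans(relative_abundance(counts)[tr$planted_above_ids, ])))
})

test_that("planting more taxa than exist is rejected", {
  cfg <- small_cfg(seed = 1)
  expect_error(simulation_config(n_taxa = 10, n_planted_core = 8,
                                 n_planted_above = 2, n_planted_below = 3),
               "exceed")
  expect_error(simulation_config(n_signal_taxa = 5), "even")
})

test_that("the planted covariate is an exactly zero-sum log-contrast", {
  sim <- simulate_dataset(small_cfg(seed = 3))
  beta <- sim$truth$signal_beta
  expect_equal(sum(beta), 0, tolerance = 1e-12)
  expect_equal(sum(beta != 0), 6L)

  # noise-free, signal-free limit: y is the constant intercept
  cfg0 <- small_cfg(seed = 3, noise_sd = 0, beta_magnitude = 0)
  sim0 <- simulate_dataset(cfg0)
  expect_equal(unname(sim0$dataset$metadata$temperature),
               rep(cfg0$beta0, ncol(sim0$dataset$counts)), tolerance = 1e-9)
})

test_that("ordinary least squares on the true contrasts recovers beta", {
  cfg <- simulation_config(seed = 8, cdna_timepoints = 0)  # 36 samples
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  beta <- sim$truth$signal_beta
  sig <- names(beta)[beta != 0]
  logx <- log(sweep(ds$counts + 1, 2, colSums(ds$counts + 1), "/"))
  fit <- lm(ds$metadata$temperature ~ t(logx[sig, ]))
  est <- coef(summary(fit))[-1, ]
  expect_true(all(abs(est[, "Estimate"] - beta[sig]) <=
                    2 * est[, "Std. Error"]))
})

test_that("fixtures round-trip and the truth file matches the config", {
  cfg <- small_cfg(seed = 12)
  sim <- simulate_dataset(cfg)
  dir <- file.path(tempdir(), "fx_rt")
  paths <- write_fixture(sim$dataset, sim$truth, dir)
  ds <- read_dataset(paths["abundance"], paths["taxonomy"],
                     paths["metadata"], paths["tree"])
  expect_identical(ds$counts, sim$dataset$counts)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$m_true, cfg$m_true)
  expect_equal(truth$seed, cfg$seed)
  tree <- ape::read.tree(paths["tree"])
  expect_setequal(tree$tip.label, rownames(sim$dataset$counts))
})
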