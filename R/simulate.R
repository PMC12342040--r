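#' Configuration for the synthetic community generator
#'
#' Captures the enrichment-study design the generator emulates: three
#' temperature groups (Low/Meso/Thermo at 15/35/48 degrees C) sampled at
#' four timepoints in triplicate (DNA phase), plus a three-timepoint
#' cDNA-like phase, with uneven sequencing depth, a long-tailed source
#' community, neutrally assembled taxa, planted core / selected /
#' dispersal-limited taxa and a planted temperature-like compositional
#' signal.
#'
#' @param n_taxa number of ASVs in the source community.
#' @param n_groups number of temperature groups.
#' @param timepoints_per_group DNA-phase timepoints per group.
#' @param replicates_per_timepoint replicate reactors per group.
#' @param cdna_timepoints cDNA-phase timepoints per group (0 disables the
#'   cDNA design).
#' @param depth_range min/max reads per sample; depths are drawn uniformly.
#' @param local_community_size Sloan local community size N (individuals).
#' @param m_true true migration parameter in (0, 1].
#' @param source_alpha long-tail shape: source abundances follow
#'   `p_i` proportional to `exp(-source_alpha * (i-1)/(n_taxa-1))`, i.e. a
#'   log-series-like rank-abundance spanning `source_alpha / ln(10)`
#'   decades.
#' @param n_planted_core,n_planted_above,n_planted_below numbers of planted
#'   persistent-core, environmentally selected (always present, rare) and
#'   dispersal-limited (abundant in one replicate line only) taxa.
#' @param n_signal_taxa number of taxa carrying the compositional covariate
#'   signal (must be even so the alternating coefficients sum to zero).
#' @param group_effect strength of the temperature-group restructuring of
#'   the source community: source abundances of sub-dominant taxa (ranks
#'   below `n_shared_head`) are multiplied per group by
#'   `exp(group_effect * z)` with `z ~ Uniform(-2, 2)` and renormalised,
#'   so groups share their dominant taxa but diverge in the sub-dominant
#'   fraction with bounded fold-changes (0 disables, giving one common
#'   source community).
#' @param n_shared_head number of top-abundance taxa shared (unperturbed)
#'   across groups.
#' @param beta_magnitude absolute value of each nonzero log-contrast
#'   coefficient (covariate units per log-unit).
#' @param beta0 covariate intercept (centre of the temperature scale).
#' @param noise_sd Gaussian noise added to the simulated covariate.
#' @param seed integer seed; identical configurations yield byte-identical
#'   fixtures.
#' @return a list of class `nc_sim_config`.
#' @export
simulation_config <- function(n_taxa = 300,
                              n_groups = 3,
                              timepoints_per_group = 4,
                              replicates_per_timepoint = 3,
                              cdna_timepoints = 3,
                              depth_range = c(11000, 124000),
                              local_community_size = 10000,
                              m_true = 0.1,
                              source_alpha = 8,
                              n_planted_core = 10,
                              n_planted_above = 5,
                              n_planted_below = 5,
                              n_signal_taxa = 6,
                              group_effect = 0.8,
                              n_shared_head = 60,
                              beta_magnitude = 8,
                              beta0 = 35,
                              noise_sd = 0.5,
                              seed = 1) {
  stopifnot(n_taxa >= 2, m_true > 0, m_true <= 1,
            depth_range[1] <= depth_range[2], depth_range[1] > 0,
            n_planted_core >= 0, n_planted_above >= 0, n_planted_below >= 0)
  if (n_signal_taxa %% 2 != 0)
    stop("n_signal_taxa must be even (alternating +/- coefficients sum to zero)")
  if (n_planted_core + n_planted_above + n_planted_below > n_taxa)
    stop("requested planted taxa exceed n_taxa")
  structure(as.list(environment()), class = "nc_sim_config")
}

#' Source community relative abundances
#'
#' Long-tailed (log-series-like) rank-abundance vector: `p_i` proportional
#' to `exp(-alpha * (i-1)/(n-1))`, normalised to sum to 1. The decay is
#' deterministic so identical calls are identical regardless of RNG state;
#' `seed` is accepted for interface symmetry with the stochastic
#' generators.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param source_alpha tail shape (natural-log range of the abundances).
#' @param seed ignored (the vector is deterministic).
#' @return numeric probability vector of length `n_taxa`.
#' @export
simulate_source_community <- function(n_taxa, source_alpha = 8, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  p <- exp(-source_alpha * (seq_len(n_taxa) - 1) / (n_taxa - 1))
  p / sum(p)
}

sample_design <- function(cfg) {
  groups <- c("Low", "Meso", "Thermo")[seq_len(cfg$n_groups)]
  temps <- c(15, 35, 48)[seq_len(cfg$n_groups)]
  dna <- expand.grid(replicate = seq_len(cfg$replicates_per_timepoint),
                     timepoint = seq_len(cfg$timepoints_per_group),
                     group = groups, stringsAsFactors = FALSE)
  dna$phase <- "DNA-enrichment"
  dna$sample_id <- sprintf("%s_T%d_R%d", dna$group, dna$timepoint, dna$replicate)
  if (cfg$cdna_timepoints > 0) {
    cd <- expand.grid(replicate = seq_len(cfg$replicates_per_timepoint),
                      timepoint = seq_len(cfg$cdna_timepoints),
                      group = groups, stringsAsFactors = FALSE)
    cd$phase <- ifelse(cd$timepoint < cfg$cdna_timepoints,
                       "cDNA-enrichment", "cDNA-accumulation")
    cd$sample_id <- sprintf("%s_cT%d_R%d", cd$group, cd$timepoint, cd$replicate)
    dna <- rbind(dna, cd)
  }
  dna$temperature <- temps[match(dna$group, groups)]
  dna$reactor <- paste(dna$group, dna$replicate, sep = "_")
  dna
}

synthetic_taxonomy <- function(asv_ids) {
  n <- length(asv_ids)
  phyla <- c("Proteobacteria", "Bacteroidota", "Actinobacteriota",
             "Firmicutes", "Chloroflexi", "Planctomycetota")
  idx <- seq_len(n)
  data.frame(domain = "Bacteria",
             phylum = phyla[(idx %% length(phyla)) + 1L],
             class = sprintf("Class_%02d", (idx %% 12L) + 1L),
             order = sprintf("Order_%02d", (idx %% 25L) + 1L),
             family = sprintf("Family_%03d", (idx %% 60L) + 1L),
             genus = sprintf("Genus_%04d", idx),
             species = "unassigned",
             row.names = asv_ids, stringsAsFactors = FALSE)
}

#' Simulate a neutrally assembled dataset
#'
#' For every sample the local relative abundance of taxon `i` is drawn from
#' `Beta(N*m*p_i, N*m*(1-p_i))` (the Sloan stationary distribution),
#' renormalised across taxa, and counts are drawn multinomially at a depth
#' drawn uniformly from `depth_range`. Metadata encodes
#' group/timepoint/replicate/phase plus environmental covariates, taxonomy
#' assigns synthetic genus labels, and a random coalescent tree over the
#' taxa is attached so phylogenetic metrics are exercised.
#'
#' @param cfg an [simulation_config()] object.
#' @return `list(dataset = nc_dataset, truth = nc_truth)` where the truth
#'   records the source abundances and true migration rate.
#' @export
simulate_neutral_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "nc_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_taxa
  asv_ids <- sprintf("ASV_%04d", seq_len(n))
  p <- simulate_source_community(n, cfg$source_alpha)
  names(p) <- asv_ids

  design <- sample_design(cfg)
  S <- nrow(design)
  N <- cfg$local_community_size
  m <- cfg$m_true

  # group-specific source communities: dominant head shared, sub-dominant
  # fraction restructured by temperature group
  groups <- unique(design$group)
  p_by_group <- setNames(rep(list(p), length(groups)), groups)
  if (cfg$group_effect > 0) {
    tail_ix <- which(rank(-p, ties.method = "first") > cfg$n_shared_head)
    for (g in groups) {
      pg <- p
      pg[tail_ix] <- pg[tail_ix] *
        exp(cfg$group_effect * runif(length(tail_ix), -2, 2))
      p_by_group[[g]] <- pg / sum(pg)
    }
  }

  depths <- round(runif(S, cfg$depth_range[1], cfg$depth_range[2]))
  counts <- matrix(0L, n, S, dimnames = list(asv_ids, design$sample_id))
  for (s in seq_len(S)) {
    pg <- p_by_group[[design$group[s]]]
    a <- rbeta(n, N * m * pg, N * m * (1 - pg))
    a <- a / sum(a)
    counts[, s] <- rmultinom(1, depths[s], a)
  }

  meta <- design[, c("group", "reactor", "temperature", "timepoint",
                     "replicate", "phase")]
  rownames(meta) <- design$sample_id
  meta$temperature_nominal <- meta$temperature
  base_ph <- c(Low = 8.6, Meso = 8.9, Thermo = 9.1)
  meta$pH <- round(base_ph[meta$group] + rnorm(S, 0, 0.05), 2)
  meta$TS <- round(3 + 0.15 * meta$timepoint + rnorm(S, 0, 0.2), 2)
  meta$VS <- round(2 + 0.1 * meta$timepoint + rnorm(S, 0, 0.15), 2)
  meta$ammonium_in <- round(50 + rnorm(S, 0, 0.5), 2)
  amm_out <- c(Low = 30, Meso = 20, Thermo = 10)
  meta$ammonium_out <- round(amm_out[meta$group] + rnorm(S, 0, 2), 2)
  pha <- c(Low = 35, Meso = 55, Thermo = 40)
  meta$PHA <- ifelse(meta$phase == "DNA-enrichment", NA,
                     round(pha[meta$group] + rnorm(S, 0, 5), 1))

  tree <- ape::rcoal(n, tip.label = sample(asv_ids))  # random topology
  tree$edge.length <- tree$edge.length / mean(ape::node.depth.edgelength(tree)[seq_len(n)])

  ds <- nc_dataset(counts, synthetic_taxonomy(asv_ids), meta, tree)
  truth <- structure(list(source_p = p, source_p_by_group = p_by_group,
                          m_true = m,
                          local_community_size = N,
                          planted_core_ids = character(0),
                          planted_above_ids = character(0),
                          planted_below_ids = character(0),
                          signal_beta = setNames(numeric(n), asv_ids),
                          beta0 = cfg$beta0,
                          seed = cfg$seed),
                     class = "nc_truth")
  list(dataset = ds, truth = truth)
}

#' Plant non-neutral and core taxa into a simulated dataset
#'
#' Overwrites the counts of disjoint taxon sets so that downstream stages
#' have known positives: "core" taxa are present in every sample at
#' moderate-to-high abundance (3-7% of reads, the signature of
#' enrichment-selected persistent taxa); "above" taxa are present in every
#' sample but rare (environmental selection: occupancy 1 at tiny mean
#' abundance); "below" taxa are abundant (2-5%) but confined to a single
#' replicate line (dispersal limitation).
#'
#' @param ds dataset from [simulate_neutral_dataset()].
#' @param truth the matching `nc_truth`.
#' @param cfg the generating [simulation_config()].
#' @return `list(dataset, truth)` with updated counts and truth sets.
#' @export
plant_non_neutral_taxa <- function(ds, truth, cfg) {
  n <- nrow(ds$counts)
  need <- cfg$n_planted_core + cfg$n_planted_above + cfg$n_planted_below
  if (need > n) stop("requested planted taxa exceed n_taxa")
  if (need == 0) return(list(dataset = ds, truth = truth))
  # plant into mid/low-rank taxa so the abundant neutral head is untouched
  pool <- order(truth$source_p, decreasing = TRUE)
  pool <- pool[-seq_len(min(50, floor(n / 4)))]
  if (length(pool) < need) pool <- seq_len(n)
  picked <- sample(pool, need)
  ids <- rownames(ds$counts)
  core <- ids[picked[seq_len(cfg$n_planted_core)]]
  above <- ids[picked[cfg$n_planted_core + seq_len(cfg$n_planted_above)]]
  below <- ids[picked[cfg$n_planted_core + cfg$n_planted_above +
                        seq_len(cfg$n_planted_below)]]
  depths <- colSums(ds$counts)
  S <- ncol(ds$counts)
  for (id in core)
    ds$counts[id, ] <- pmax(1L, as.integer(round(depths * runif(S, 0.03, 0.07))))
  for (id in above)
    ds$counts[id, ] <- 1L + rpois(S, 2)
  for (id in below) {
    v <- integer(S)
    line <- ds$metadata$replicate == 1
    v[line] <- pmax(1L, as.integer(round(depths[line] * runif(sum(line), 0.02, 0.05))))
    ds$counts[id, ] <- v
  }
  truth$planted_core_ids <- core
  truth$planted_above_ids <- above
  truth$planted_below_ids <- below
  list(dataset = ds, truth = truth)
}

#' Plant a compositional covariate signal
#'
#' Rewrites the `temperature` metadata column as a log-contrast response:
#' `y = beta0 + sum_j beta_j log(x_j)` plus Gaussian noise, where `x` is
#' the sample composition after a +1 pseudocount and closure, and `beta`
#' is nonzero only on `n_signal_taxa` abundant taxa with alternating
#' `+/- beta_magnitude` (hence exactly zero-sum). The nominal design
#' temperature is kept in `temperature_nominal`.
#'
#' @inheritParams plant_non_neutral_taxa
#' @return `list(dataset, truth)`; `truth$signal_beta` records the true
#'   coefficients.
#' @export
simulate_covariate_response <- function(ds, truth, cfg) {
  k <- cfg$n_signal_taxa
  if (k %% 2 != 0) stop("n_signal_taxa must be even")
  if (k == 0) return(list(dataset = ds, truth = truth))
  planted <- c(truth$planted_core_ids, truth$planted_above_ids,
               truth$planted_below_ids)
  ids <- rownames(ds$counts)
  # abundant, non-planted taxa so the signal survives the top-N filter
  cand <- ids[order(truth$source_p, decreasing = TRUE)]
  # abundant taxa from the shared head, so every signal taxon stays inside
  # the top-N mean-abundance filter of the downstream regression
  cand <- setdiff(cand, planted)
  cand <- cand[seq(min(15, length(cand) - k), min(55, length(cand)))]
  sig <- sample(cand, k)
  beta <- setNames(numeric(length(ids)), ids)
  beta[sig] <- cfg$beta_magnitude * rep(c(1, -1), k / 2)
  logx <- log(sweep(ds$counts + 1, 2, colSums(ds$counts + 1), "/"))
  y <- cfg$beta0 + as.vector(crossprod(logx, beta)) +
    rnorm(ncol(ds$counts), 0, cfg$noise_sd)
  ds$metadata$temperature <- round(y, 3)
  truth$signal_beta <- beta
  list(dataset = ds, truth = truth)
}

#' Simulate a complete study-like dataset
#'
#' Runs [simulate_neutral_dataset()], [plant_non_neutral_taxa()] and
#' [simulate_covariate_response()] under the configuration's seed.
#'
#' @param cfg an [simulation_config()].
#' @return `list(dataset, truth)`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  r <- simulate_neutral_dataset(cfg)
  r <- plant_non_neutral_taxa(r$dataset, r$truth, cfg)
  simulate_covariate_response(r$dataset, r$truth, cfg)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Writes `abundance.tsv`, `taxonomy.tsv`, `metadata.tsv`, `tree.nwk` and
#' `truth.json` into `out_dir`, readable back via [read_dataset()].
#'
#' @param ds an `nc_dataset`.
#' @param truth the matching `nc_truth` (or NULL to skip `truth.json`).
#' @param out_dir output directory, created if needed.
#' @return named character vector of file paths.
#' @export
write_fixture <- function(ds, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(out_dir, "abundance.tsv"),
             taxonomy = file.path(out_dir, "taxonomy.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             truth = file.path(out_dir, "truth.json"))
  ab <- data.frame(feature_id = rownames(ds$counts), ds$counts,
                   check.names = FALSE)
  write.table(ab, paths["abundance"], sep = "\t", quote = FALSE, row.names = FALSE)
  tx <- data.frame(feature_id = rownames(ds$taxonomy), ds$taxonomy,
                   check.names = FALSE)
  write.table(tx, paths["taxonomy"], sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = rownames(ds$metadata), ds$metadata,
                   check.names = FALSE)
  write.table(md, paths["metadata"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$tree)) ape::write.tree(ds$tree, paths["tree"]) else
    paths <- paths[names(paths) != "tree"]
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), paths["truth"], auto_unbox = TRUE,
                         digits = NA)
  } else paths <- paths[names(paths) != "truth"]
  paths
}
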