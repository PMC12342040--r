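#' Analysis run configuration
#'
#' Bundles every knob of the full pipeline. CLI flags override config-file
#' values, which override these defaults.
#'
#' @param group_col metadata column holding the temperature-group label.
#' @param phase_dna phase label of the DNA-based enrichment samples.
#' @param phase_cdna phase labels of the cDNA-based samples.
#' @param rarefaction_depth reads for rarefied richness; NULL = minimum
#'   post-filter sample depth.
#' @param permutations PERMANOVA permutations (p resolution
#'   `1/(permutations+1)`).
#' @param seed master seed recorded in every output.
#' @param core_threshold relative-gain cutoff for the core rule.
#' @param ci_level neutral-model confidence band level.
#' @param coda_top,coda_folds,coda_repeats taxa kept / CV folds / repeated
#'   CV rounds for the log-contrast model.
#' @param covariates covariates to test in PERMANOVA; NULL picks the group
#'   column plus every numeric metadata column that is complete on the
#'   selected samples.
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return a list of class `nc_run_config`.
#' @export
run_config <- function(group_col = "group",
                       phase_dna = "DNA-enrichment",
                       phase_cdna = c("cDNA-enrichment", "cDNA-accumulation"),
                       rarefaction_depth = NULL,
                       permutations = 999,
                       seed = 1,
                       core_threshold = 0.02,
                       ci_level = 0.95,
                       coda_top = 100,
                       coda_folds = 12,
                       coda_repeats = 3,
                       covariates = NULL,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "nc_run_config")
}

pick_covariates <- function(meta, group_col, requested = NULL) {
  if (!is.null(requested)) {
    missing <- setdiff(requested, colnames(meta))
    if (length(missing)) stop("covariates absent from metadata: ",
                              paste(missing, collapse = ", "))
    return(requested)
  }
  num <- vapply(meta, function(v) is.numeric(v) && !anyNA(v) && var(v) > 0,
                logical(1))
  num[c("replicate", "timepoint")] <- FALSE
  c(intersect(group_col, colnames(meta)), colnames(meta)[num])
}

distance_metrics <- function(ds) {
  out <- list(bray = bray_curtis(ds$counts),
              jaccard = jaccard_distance(ds$counts))
  if (!is.null(ds$tree)) {
    out$unweighted_unifrac <- unweighted_unifrac(ds$counts, ds$tree)
    out$weighted_unifrac <- weighted_unifrac(ds$counts, ds$tree)
  }
  out
}

permanova_table <- function(dists, meta, covariates, permutations, seed) {
  rows <- list()
  i <- 0L
  for (mname in names(dists)) for (cv in covariates) {
    i <- i + 1L
    v <- meta[[cv]]
    names(v) <- rownames(meta)
    pr <- permanova(dists[[mname]], v, permutations = permutations,
                    seed = seed + i, name = cv)
    rows[[i]] <- data.frame(metric = mname, covariate = cv,
                            pseudo_f = pr$pseudo_f, r_squared = pr$r_squared,
                            p_value = pr$p_value,
                            n_permutations = pr$n_permutations,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

alpha_summary <- function(counts, groups, depth) {
  rich <- rarefied_richness(counts, depth)
  shan <- shannon_entropy(counts)
  agg <- function(v) {
    s <- split(v, groups)
    data.frame(group = names(s),
               mean = vapply(s, mean, numeric(1)),
               sd = vapply(s, sd, numeric(1)), row.names = NULL)
  }
  list(rarefied_richness = agg(rich), shannon = agg(shan),
       per_sample = data.frame(sample = colnames(counts), group = groups,
                               rarefied_richness = rich, shannon = shan,
                               row.names = NULL),
       depth = depth)
}

#' Run the full enrichment (DNA-phase) analysis
#'
#' Contaminant filtering, alpha diversity, four beta-diversity distance
#' matrices with PCoA, a PERMANOVA row per covariate per metric, the
#' occupancy-ranked core microbiome and the neutral-model fit per
#' temperature group, and the temperature log-contrast signature.
#'
#' @param ds an `nc_dataset`.
#' @param config an [run_config()].
#' @return object of class `nc_report`.
#' @export
run_enrichment_analysis <- function(ds, config = run_config()) {
  stopifnot(inherits(ds, "nc_dataset"), inherits(config, "nc_run_config"))
  ds <- filter_contaminants(ds)
  sel <- if ("phase" %in% colnames(ds$metadata))
    ds$metadata$phase == config$phase_dna else rep(TRUE, ncol(ds$counts))
  if (!any(sel)) stop("stage [subset]: no samples in phase ", config$phase_dna)
  dna <- subset_samples(ds, rownames(ds$metadata)[sel])

  groups <- dna$metadata[[config$group_col]]
  if (is.null(groups)) stop("stage [subset]: metadata lacks column ", config$group_col)
  depth <- config$rarefaction_depth
  if (is.null(depth)) depth <- min(colSums(dna$counts))

  alpha <- alpha_summary(dna$counts, groups, depth)
  dists <- distance_metrics(dna)
  ordinations <- lapply(dists, pcoa, n_axes = 2)
  covs <- pick_covariates(dna$metadata, config$group_col, config$covariates)
  ptab <- permanova_table(dists, dna$metadata, covs, config$permutations,
                          config$seed)

  cores <- lapply(sort(unique(groups)), function(g)
    core_microbiome(dna, group = g, phase = NULL,
                    threshold = config$core_threshold))
  names(cores) <- sort(unique(groups))
  neutral <- lapply(sort(unique(groups)), function(g)
    fit_neutral(dna, group = g, phase = NULL, ci_level = config$ci_level))
  names(neutral) <- sort(unique(groups))

  coda <- if ("temperature" %in% colnames(dna$metadata))
    temperature_signature(dna, "temperature", n_top = config$coda_top,
                          n_folds = config$coda_folds,
                          cv_repeats = config$coda_repeats,
                          seed = config$seed)
  else NULL

  report <- structure(list(alpha = alpha, distances = dists,
                           ordinations = ordinations, permanova = ptab,
                           core = cores, neutral = neutral, coda = coda,
                           config = config,
                           provenance = list(seed = config$seed,
                                             package = "neutralcore",
                                             version = as.character(packageVersion("neutralcore")))),
                      class = "nc_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Compare phases on the cDNA-like samples
#'
#' Diversity and PERMANOVA restricted to the cDNA phases, testing phase
#' membership plus the numeric covariates (e.g. recovered PHA).
#'
#' @inheritParams run_enrichment_analysis
#' @return object of class `nc_report` (diversity + PERMANOVA sections).
#' @export
run_phase_comparison <- function(ds, config = run_config()) {
  stopifnot(inherits(ds, "nc_dataset"))
  ds <- filter_contaminants(ds)
  if (!"phase" %in% colnames(ds$metadata)) stop("metadata lacks 'phase'")
  sel <- ds$metadata$phase %in% config$phase_cdna
  cd <- subset_samples(ds, rownames(ds$metadata)[sel])
  if (length(unique(cd$metadata$phase)) < 2)
    stop("phase comparison needs at least two phases")

  depth <- config$rarefaction_depth
  if (is.null(depth)) depth <- min(colSums(cd$counts))
  alpha <- alpha_summary(cd$counts, cd$metadata$phase, depth)
  dists <- distance_metrics(cd)
  covs <- unique(c("phase", pick_covariates(cd$metadata, config$group_col,
                                            config$covariates)))
  ptab <- permanova_table(dists, cd$metadata, covs, config$permutations,
                          config$seed)
  structure(list(alpha = alpha, distances = dists,
                 ordinations = lapply(dists, pcoa, n_axes = 2),
                 permanova = ptab, core = NULL, neutral = NULL, coda = NULL,
                 config = config,
                 provenance = list(seed = config$seed,
                                   package = "neutralcore",
                                   version = as.character(packageVersion("neutralcore")))),
            class = "nc_report")
}

#' @export
print.nc_report <- function(x, ...) {
  cat("Analysis report (seed", x$provenance$seed, ")\n")
  cat("-- PERMANOVA --\n")
  tab <- x$permanova
  tab$r_squared <- round(tab$r_squared, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$core)) {
    cat("-- core sizes --\n")
    for (g in names(x$core))
      cat(" ", g, ":", length(x$core[[g]]$core), "taxa\n")
  }
  if (!is.null(x$neutral)) {
    cat("-- neutral fits --\n")
    for (g in names(x$neutral))
      cat(sprintf("  %s: m = %.4g, R2 = %.3f\n", g, x$neutral[[g]]$m,
                  x$neutral[[g]]$r_squared))
  }
  if (!is.null(x$coda))
    cat("-- temperature signature:", length(x$coda$selected_positive),
        "positive,", length(x$coda$selected_negative), "negative taxa\n")
  invisible(x)
}

fmt_num <- function(x) {
  if (is.numeric(x)) signif(x, 10) else x   # stable 10-digit serialization
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    df[] <- lapply(df, fmt_num)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(report$permanova, "permanova.tsv")
  wt(report$alpha$per_sample, "alpha_diversity.tsv")
  for (mname in names(report$distances)) {
    m <- as.matrix(report$distances[[mname]])
    wt(data.frame(sample_id = rownames(m), m, check.names = FALSE),
       paste0("distance_", mname, ".tsv"))
  }
  if (!is.null(report$core))
    for (g in names(report$core)) {
      wt(report$core[[g]]$profiles, paste0("occupancy_", g, ".tsv"))
      wt(report$core[[g]]$curve, paste0("explanatory_curve_", g, ".tsv"))
    }
  if (!is.null(report$neutral))
    for (g in names(report$neutral))
      wt(report$neutral[[g]]$taxa, paste0("neutral_", g, ".tsv"))
  if (!is.null(report$coda))
    wt(data.frame(taxon = names(report$coda$beta),
                  beta = report$coda$beta,
                  set = ifelse(report$coda$beta > 0, "positive",
                               ifelse(report$coda$beta < 0, "negative", "-"))),
       "coda_coefficients.tsv")
  summary_json <- list(
    seed = report$provenance$seed,
    version = report$provenance$version,
    core_sizes = if (!is.null(report$core))
      lapply(report$core, function(cc) length(cc$core)),
    neutral_m = if (!is.null(report$neutral))
      lapply(report$neutral, function(f) fmt_num(f$m)),
    coda_lambda = if (!is.null(report$coda)) fmt_num(report$coda$lambda))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
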