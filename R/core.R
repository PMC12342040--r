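#' Time-specific occupancy profiles
#'
#' For every taxon, computed on one temperature group's samples: the mean
#' relative abundance `p`, the occupancy within each timepoint (fraction of
#' that timepoint's replicate samples where the taxon is detected at
#' `detection` reads or more), the overall occupancy, and the replication
#' consistency `r` (fraction of timepoints where the taxon is detected in
#' every replicate). Taxa are ranked by
#' `ranking_index = (mean_t o_t + r) / 2`, with ties broken by descending
#' mean relative abundance and then taxon id.
#'
#' @param ds an `nc_dataset`.
#' @param group group label to select (NULL = all samples).
#' @param phase phase label to select (NULL = all phases).
#' @param detection minimum count regarded as presence (default 1 read).
#' @return data.frame ordered by rank with columns `taxon`,
#'   `mean_rel_abund`, `occupancy`, `replication_consistency`,
#'   `ranking_index`, `rank`; the per-timepoint occupancy matrix is
#'   attached as attribute `"occupancy_by_time"`.
#' @export
occupancy_profiles <- function(ds, group = NULL, phase = "DNA-enrichment",
                               detection = 1) {
  stopifnot(inherits(ds, "nc_dataset"))
  sel <- rep(TRUE, ncol(ds$counts))
  if (!is.null(group)) sel <- sel & ds$metadata$group == group
  if (!is.null(phase) && "phase" %in% colnames(ds$metadata))
    sel <- sel & ds$metadata$phase == phase
  if (sum(sel) < 2) stop("selected group has fewer than 2 samples")
  counts <- ds$counts[, sel, drop = FALSE]
  tp <- ds$metadata$timepoint[sel]
  pres <- counts >= detection
  p <- rowMeans(relative_abundance(counts))
  tps <- sort(unique(tp))
  o_t <- vapply(tps, function(t) rowMeans(pres[, tp == t, drop = FALSE]),
                numeric(nrow(counts)))
  colnames(o_t) <- paste0("t", tps)
  r <- rowMeans(o_t == 1)
  idx <- (rowMeans(o_t) + r) / 2
  out <- data.frame(taxon = rownames(counts), mean_rel_abund = p,
                    occupancy = rowMeans(pres),
                    replication_consistency = r, ranking_index = idx,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-out$ranking_index, -out$mean_rel_abund, out$taxon)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "occupancy_by_time") <- o_t[ord, , drop = FALSE]
  out
}

# Mean pairwise Bray-Curtis *similarity* (1 - dissimilarity on raw counts).
mean_bc_similarity <- function(table) {
  S <- ncol(table)
  tot <- colSums(table)
  sims <- numeric(0)
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    den <- tot[i] + tot[j]
    sims <- c(sims, if (den > 0) 2 * sum(pmin(table[, i], table[, j])) / den else 1)
  }
  mean(sims)
}

#' Bray-Curtis explanatory-value curve
#'
#' Computes, for every prefix size `k` of an occupancy ranking, the mean
#' pairwise Bray-Curtis similarity carried by the top-`k` taxa relative to
#' the full table: `E_k = BC(top-k) / BC(all)`, with per-step contribution
#' `C_k = 1 - E_k`. The subset similarity uses the raw counts of the
#' top-`k` taxa in the numerator over the full-sample read totals
#' (`2 sum_(i<=k) min(x_i, y_i) / (sum_all x + sum_all y)`), so it grows
#' monotonically from 0 to the full-table similarity as the prefix is
#' extended: at `k = K` (all taxa) `E = 1` and `C = 0` by construction.
#'
#' @param table taxa x samples count matrix.
#' @param ranking character vector of taxon ids, best first (a permutation
#'   of the rownames, or a prefix-able subset).
#' @return data.frame with columns `k`, `taxon`, `explanatory_value` (E_k)
#'   and `contribution` (C_k); mean full-table similarity is attached as
#'   attribute `"bc_all"`.
#' @export
explanatory_curve <- function(table, ranking) {
  if (!length(ranking)) stop("empty ranking")
  table <- as.matrix(table)
  if (!all(ranking %in% rownames(table))) stop("ranking contains unknown taxa")
  S <- ncol(table)
  bc_all <- mean_bc_similarity(table)
  pairs <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  tot <- colSums(table)
  den <- tot[pairs[, 1]] + tot[pairs[, 2]]  # full-sample totals per pair
  min_sum <- numeric(nrow(pairs))           # prefix sums of pairwise mins
  E <- numeric(length(ranking))
  for (k in seq_along(ranking)) {
    x <- table[ranking[k], ]
    min_sum <- min_sum + pmin(x[pairs[, 1]], x[pairs[, 2]])
    E[k] <- mean(2 * min_sum / den) / bc_all
  }
  structure(data.frame(k = seq_along(ranking), taxon = ranking,
                       explanatory_value = E, contribution = 1 - E,
                       stringsAsFactors = FALSE),
            bc_all = bc_all)
}

#' Select the core set from an explanatory-value curve
#'
#' Implements the "last 2%" rule: the core is the ranking prefix up to the
#' largest `k` whose relative gain `(E_k - E_(k-1)) / E_(k-1)` exceeds
#' `threshold`; the top-ranked taxon is always included.
#'
#' @param curve data.frame from [explanatory_curve()] (or a numeric E_k
#'   vector).
#' @param threshold relative-gain cutoff (default 0.02).
#' @return list with `core` (taxon ids, when available), `stop_index`, and
#'   the per-step relative `gains`.
#' @export
select_core <- function(curve, threshold = 0.02) {
  E <- if (is.data.frame(curve)) curve$explanatory_value else as.numeric(curve)
  K <- length(E)
  if (K == 0) stop("empty curve")
  gains <- c(NA_real_, (E[-1] - E[-K]) / ifelse(E[-K] > 0, E[-K], NA_real_))
  gains[-1][E[-K] == 0 & E[-1] > 0] <- Inf
  pass <- which(gains > threshold)
  stop_index <- if (length(pass)) max(pass) else 1L
  core <- if (is.data.frame(curve)) curve$taxon[seq_len(stop_index)] else NULL
  list(core = core, stop_index = stop_index, gains = gains)
}

#' Occupancy-ranked core microbiome of one temperature group
#'
#' Runs [occupancy_profiles()], [explanatory_curve()] and [select_core()]
#' on one group's samples and bundles the results.
#'
#' @inheritParams occupancy_profiles
#' @param threshold relative-gain cutoff for [select_core()].
#' @return object of class `nc_core`: `profiles`, `curve`, `core`,
#'   `stop_index`, `bc_all`, `group`, `threshold`.
#' @export
core_microbiome <- function(ds, group = NULL, phase = "DNA-enrichment",
                            threshold = 0.02, detection = 1) {
  prof <- occupancy_profiles(ds, group, phase, detection)
  sel <- rep(TRUE, ncol(ds$counts))
  if (!is.null(group)) sel <- sel & ds$metadata$group == group
  if (!is.null(phase) && "phase" %in% colnames(ds$metadata))
    sel <- sel & ds$metadata$phase == phase
  curve <- explanatory_curve(ds$counts[, sel, drop = FALSE], prof$taxon)
  pick <- select_core(curve, threshold)
  structure(list(profiles = prof, curve = curve, core = pick$core,
                 stop_index = pick$stop_index, gains = pick$gains,
                 bc_all = attr(curve, "bc_all"), group = group,
                 threshold = threshold),
            class = "nc_core")
}

#' @export
print.nc_core <- function(x, ...) {
  cat("Core microbiome", if (!is.null(x$group)) paste0("[", x$group, "]"),
      ": ", length(x$core), " of ", nrow(x$profiles),
      " taxa (last >", 100 * x$threshold, "% relative gain rule)\n", sep = "")
  cat("  mean Bray-Curtis similarity (all taxa):", round(x$bc_all, 4), "\n")
  cat("  core:", paste(head(x$core, 8), collapse = ", "),
      if (length(x$core) > 8) "...", "\n")
  invisible(x)
}

#' @export
plot.nc_core <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$curve$k, x$curve$explanatory_value, type = "s",
       xlab = "ranked taxa included (k)", ylab = expression(E[k]), ...)
  abline(v = x$stop_index, lty = 3, col = "blue")
  pr <- x$profiles
  plot(log10(pr$mean_rel_abund), pr$occupancy,
       col = ifelse(pr$taxon %in% x$core, "red", "grey40"),
       xlab = "log10 mean relative abundance", ylab = "occupancy", ...)
}
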