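#' Sloan neutral-model occupancy prediction
#'
#' Expected occupancy of a taxon with mean source relative abundance `p` in
#' a local community of size `N` with migration rate `m`. Two detection
#' models are available:
#' \describe{
#'   \item{`"threshold"`}{the classic continuum form
#'     `1 - I_(d/N)(N m p, N m (1-p))`, the probability that the local
#'     relative abundance (Beta-distributed under the neutral stationary
#'     state) exceeds the detection limit `d/N`.}
#'   \item{`"sampling"`}{the probability that the taxon is observed at
#'     least `d` times in `depth` sequenced reads drawn from that Beta
#'     local abundance, i.e. the Beta-binomial tail
#'     `P(count >= d)`; for `d = 1` this is
#'     `1 - B(a, b + depth)/B(a, b)` with `a = N m p`, `b = N m (1-p)`.
#'     This matches how occupancy is actually measured from count tables;
#'     `depth` may be a vector of per-sample read depths, in which case
#'     the expected occupancy averages the detection probability over
#'     them (the right form under uneven sequencing effort).}
#' }
#'
#' @param p mean relative abundance in the source community (vectorised).
#' @param N local community size (individuals / reads).
#' @param m migration parameter in (0, 1].
#' @param d detection limit in reads (default 1).
#' @param detection `"threshold"` or `"sampling"`.
#' @param depth reads per sample for the sampling model (default `N`).
#' @return predicted occupancy in \[0, 1\].
#' @export
predicted_occupancy <- function(p, N, m, d = 1,
                                detection = c("threshold", "sampling"),
                                depth = N) {
  detection <- match.arg(detection)
  stopifnot(all(p >= 0), all(p <= 1), N > 0, m > 0, m <= 1, d >= 0)
  a <- N * m * p
  b <- N * m * (1 - p)
  out <- numeric(length(a))
  pos <- p > 0 & p < 1
  if (detection == "threshold") {
    out[pos] <- 1 - pbeta(d / N, a[pos], b[pos])
  } else {
    # P(count >= d), count ~ BetaBinomial(D, a, b), averaged over the
    # per-sample depths D
    lb0 <- lbeta(a[pos], b[pos])
    det <- numeric(sum(pos))
    for (D in depth) {
      cdf <- 0
      for (k in seq_len(max(1, d)) - 1)  # k = 0 .. d-1
        cdf <- cdf + exp(lchoose(D, k) + lbeta(a[pos] + k, b[pos] + D - k) - lb0)
      det <- det + (1 - cdf)
    }
    out[pos] <- det / length(depth)
  }
  out[p == 1] <- as.numeric(N > d)
  pmin(pmax(out, 0), 1)
}

# Wilson score interval for a proportion `ph` with `n` trials
wilson_interval <- function(ph, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, ctr - hw), upper = pmin(1, ctr + hw))
}

# Occupancy band around a predicted proportion with n trials. The default
# "binomial" band is the exact acceptance region of the binomial test
# (quantiles of Binomial(n, ph)/n), which keeps its nominal coverage for
# occupancies observed on a finite sample grid - including the saturated
# occupancy = 1 case; "wilson" gives the Wilson score interval.
occupancy_band <- function(ph, n, level = 0.95,
                           band = c("binomial", "wilson")) {
  band <- match.arg(band)
  if (band == "wilson") return(wilson_interval(ph, n, level))
  alpha <- 1 - level
  # the region always contains the prediction itself, so a taxon observed
  # exactly on the fitted curve is never flagged
  cbind(lower = pmin(stats::qbinom(alpha / 2, n, ph) / n, ph),
        upper = pmax(stats::qbinom(1 - alpha / 2, n, ph) / n, ph))
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration parameter `m` by least squares on the
#' abundance-occupancy cloud: `m` minimises
#' `sum_taxa (observed occupancy - predicted occupancy)^2` over
#' `[1e-6, 1]` (coarse log-grid scan followed by bounded refinement).
#' Observed occupancy is the fraction of samples where a taxon has at
#' least `d` reads; `p` is its mean relative abundance over the same
#' samples. Taxa are classified against a 95% band around the fitted
#' prediction, treating occupancy as a binomial proportion with the number
#' of samples as trials: `above` (occupancy above the band:
#' environmentally selected), `below` (dispersal limited) or `neutral`.
#' The default band is the exact binomial acceptance region, which retains
#' nominal coverage for occupancies on the discrete `k/S` grid (a Wilson
#' score band is available via `band = "wilson"`).
#'
#' @param x an `nc_dataset` or a taxa x samples count matrix.
#' @param group optional group label to restrict samples (datasets only).
#' @param phase phase label to restrict samples (datasets only; NULL for
#'   all).
#' @param N local community size; default = mean post-filter sample depth.
#' @param d detection limit in reads.
#' @param detection detection model passed to [predicted_occupancy()];
#'   the default `"sampling"` matches count-based occupancy exactly, the
#'   classic `"threshold"` form is available for comparability.
#' @param ci_level confidence level of the classification band.
#' @param band `"binomial"` (exact acceptance region, default) or
#'   `"wilson"` (score interval).
#' @return an object of class `neutral_fit` with components `m`, `N`, `d`,
#'   `n_samples`, `r_squared`, `taxa` (per-taxon data.frame: `p`,
#'   `occupancy`, `predicted`, `ci_lower`, `ci_upper`, `class`) and
#'   bookkeeping fields. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' sim <- simulate_neutral_dataset(simulation_config(n_taxa = 60, seed = 3,
#'   n_planted_core = 0, n_planted_above = 0, n_planted_below = 0))
#' fit <- fit_neutral(sim$dataset)
#' coef(fit)
#' @export
fit_neutral <- function(x, group = NULL, phase = "DNA-enrichment", N = NULL,
                        d = 1, detection = c("sampling", "threshold"),
                        ci_level = 0.95, band = c("binomial", "wilson")) {
  detection <- match.arg(detection)
  band <- match.arg(band)
  if (inherits(x, "nc_dataset")) {
    sel <- rep(TRUE, ncol(x$counts))
    if (!is.null(group)) sel <- sel & x$metadata$group == group
    if (!is.null(phase) && "phase" %in% colnames(x$metadata))
      sel <- sel & x$metadata$phase == phase
    counts <- x$counts[, sel, drop = FALSE]
  } else counts <- as.matrix(x)
  S <- ncol(counts)
  if (S < 2) stop("need at least 2 samples")
  depth <- colSums(counts)
  if (is.null(N)) N <- mean(depth)
  p <- rowMeans(sweep(counts, 2, depth, "/"))
  occ <- rowMeans(counts >= d)
  keep <- p > 0
  if (sum(keep) < 20) stop("need at least 20 taxa with nonzero abundance")

  fit_neutral_profiles(p, occ, N = N, n_samples = S, d = d,
                       detection = detection, ci_level = ci_level,
                       band = band, depth = depth,
                       taxon = rownames(counts), group = group)
}

#' Fit the neutral model to abundance-occupancy profiles
#'
#' Lower-level interface to [fit_neutral()] taking the per-taxon mean
#' relative abundances and observed occupancies directly (useful for
#' pre-computed profiles or for noise-free self-consistency checks).
#'
#' @param p per-taxon mean relative abundance.
#' @param occupancy per-taxon observed occupancy in \[0, 1\].
#' @param N local community size.
#' @param n_samples number of samples the occupancies were computed from.
#' @param depth per-sample read depths (default `N`).
#' @param taxon optional taxon ids.
#' @inheritParams fit_neutral
#' @return a `neutral_fit` (see [fit_neutral()]).
#' @export
fit_neutral_profiles <- function(p, occupancy, N, n_samples,
                                 d = 1, detection = c("sampling", "threshold"),
                                 ci_level = 0.95,
                                 band = c("binomial", "wilson"),
                                 depth = N, taxon = NULL, group = NULL) {
  detection <- match.arg(detection)
  band <- match.arg(band)
  stopifnot(length(p) == length(occupancy), n_samples >= 2)
  if (is.null(taxon)) taxon <- paste0("taxon_", seq_along(p))
  keep <- p > 0
  if (sum(keep) < 20) stop("need at least 20 taxa with nonzero abundance")
  pk <- p[keep]; ok <- occupancy[keep]
  sse <- function(m)
    sum((ok - predicted_occupancy(pk, N, m, d, detection, depth = depth))^2)
  grid <- exp(seq(log(1e-6), 0, length.out = 100))
  gs <- vapply(grid, sse, numeric(1))
  i <- which.min(gs)
  opt <- optimize(sse, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                  tol = 1e-10)
  m_hat <- opt$minimum
  sst <- sum((ok - mean(ok))^2)
  unreliable <- sst == 0
  r2 <- 1 - opt$objective / ifelse(sst > 0, sst, NA_real_)
  if (unreliable) warning("degenerate occupancy data; fit flagged unreliable")

  pred <- predicted_occupancy(p, N, m_hat, d, detection, depth = depth)
  ci <- occupancy_band(pred, n_samples, ci_level, band)
  cls <- ifelse(occupancy > ci[, "upper"], "above",
                ifelse(occupancy < ci[, "lower"], "below", "neutral"))
  cls[!keep] <- NA
  taxa <- data.frame(taxon = taxon, p = p, occupancy = occupancy,
                     predicted = pred, ci_lower = ci[, "lower"],
                     ci_upper = ci[, "upper"],
                     class = factor(cls, c("neutral", "above", "below")),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(m = m_hat, N = N, d = d, n_samples = n_samples,
                 detection = detection, r_squared = r2, sse = opt$objective,
                 ci_level = ci_level, band = band, taxa = taxa, group = group,
                 unreliable = unreliable, depths = depth,
                 mean_depth = mean(depth)),
            class = "neutral_fit")
}

#' Classify taxa against the neutral prediction band
#'
#' Rebuilds the confidence band of a fitted model at `ci_level` and labels
#' each taxon `above`, `below` or `neutral`.
#'
#' @param fit a `neutral_fit`.
#' @param ci_level confidence level.
#' @param band `"binomial"` or `"wilson"` (defaults to the fitted band).
#' @return factor of classes aligned with `fit$taxa`.
#' @export
classify_taxa <- function(fit, ci_level = 0.95, band = NULL) {
  stopifnot(inherits(fit, "neutral_fit"))
  if (fit$n_samples < 2) stop("need at least 2 samples")
  if (is.null(band)) band <- fit$band
  ci <- occupancy_band(fit$taxa$predicted, fit$n_samples, ci_level, band)
  cls <- ifelse(fit$taxa$occupancy > ci[, "upper"], "above",
                ifelse(fit$taxa$occupancy < ci[, "lower"], "below", "neutral"))
  cls[fit$taxa$p == 0] <- NA
  factor(cls, c("neutral", "above", "below"))
}

#' Tally neutral-model classes at a taxonomic rank
#'
#' @param fit a `neutral_fit`.
#' @param taxonomy taxonomy data.frame (rownames = taxon ids).
#' @param rank rank to tally at.
#' @return data.frame of class counts per rank label.
#' @export
neutral_class_tally <- function(fit, taxonomy, rank = "genus") {
  rank <- match.arg(rank, RANKS)
  lab <- taxonomy[fit$taxa$taxon, rank]
  tab <- table(label = lab, class = fit$taxa$class)
  as.data.frame.matrix(tab)
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model fit (%s detection): m = %.4g, N = %.0f, d = %g\n",
              x$detection, x$m, x$N, x$d))
  cat(sprintf("  %d taxa, %d samples, R2 = %.3f%s\n", nrow(x$taxa),
              x$n_samples, x$r_squared, if (x$unreliable) " [unreliable]" else ""))
  print(table(x$taxa$class))
  invisible(x)
}

#' @export
summary.neutral_fit <- function(object, ...) {
  tab <- table(object$taxa$class)
  structure(list(m = object$m, N = object$N, r_squared = object$r_squared,
                 n_samples = object$n_samples, class_counts = tab,
                 fraction_non_neutral =
                   sum(tab[c("above", "below")]) / sum(tab)),
            class = "summary.neutral_fit")
}

#' @export
print.summary.neutral_fit <- function(x, ...) {
  cat(sprintf("m = %.4g, N = %.0f, R2 = %.3f over %d samples\n",
              x$m, x$N, x$r_squared, x$n_samples))
  print(x$class_counts)
  cat(sprintf("fraction outside band: %.3f\n", x$fraction_non_neutral))
  invisible(x)
}

#' @export
coef.neutral_fit <- function(object, ...) c(m = object$m)

#' @export
predict.neutral_fit <- function(object, p = NULL, ...) {
  if (is.null(p)) return(object$taxa$predicted)
  predicted_occupancy(p, object$N, object$m, object$d, object$detection,
                      depth = object$depths)
}

#' @export
fitted.neutral_fit <- function(object, ...) object$taxa$predicted

#' @export
residuals.neutral_fit <- function(object, ...)
  object$taxa$occupancy - object$taxa$predicted

#' @export
plot.neutral_fit <- function(x, ...) {
  tx <- x$taxa[x$taxa$p > 0, ]
  ord <- order(tx$p)
  cols <- c(neutral = "darkgreen", above = "red", below = "blue")
  plot(log10(tx$p), tx$occupancy, col = cols[as.character(tx$class)],
       xlab = "log10 mean relative abundance", ylab = "occupancy", ...)
  lines(log10(tx$p[ord]), tx$predicted[ord], lwd = 2)
  lines(log10(tx$p[ord]), tx$ci_lower[ord], lty = 2)
  lines(log10(tx$p[ord]), tx$ci_upper[ord], lty = 2)
  legend("bottomright", legend = names(cols), col = cols, pch = 1, bty = "n")
}
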