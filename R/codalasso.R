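#' Pseudocount, closure and log transform
#'
#' Prepares a count table for log-contrast regression: adds a pseudocount
#' to every cell (compositional zero replacement), closes each sample to
#' proportions, and takes natural logs. Output therefore has no `-Inf`
#' entries, and samples with proportional counts map to identical columns.
#'
#' @param table taxa x samples count matrix with positive column sums.
#' @param pseudocount value added to every cell before closure (default 1).
#' @return matrix of log-proportions, same shape and dimnames as the input.
#' @export
zero_replace_and_log <- function(table, pseudocount = 1) {
  table <- as.matrix(table)
  if (any(colSums(table) <= 0)) stop("zero-sum sample")
  x <- table + pseudocount
  log(sweep(x, 2, colSums(x), "/"))
}

#' Zero-sum-constrained L1 log-contrast regression
#'
#' Fits the compositional (log-contrast) lasso
#' `min 0.5 sum_i (y_i - b0 - sum_j b_j x_ij)^2 + lambda sum_j |b_j|`
#' subject to `sum_j b_j = 0`, where `x` holds log-transformed
#' proportions. The zero-sum constraint makes the model invariant to the
#' compositional scale. Optimisation is pairwise coordinate descent:
#' updating coefficients in pairs along `e_j - e_k` keeps the constraint
#' satisfied exactly at every step; each scalar subproblem is solved in
#' closed form and the objective decreases monotonically.
#'
#' @param x numeric matrix, samples x taxa (e.g. the transpose of
#'   [zero_replace_and_log()] output).
#' @param y numeric response (e.g. temperature), one value per sample.
#' @param lambda non-negative L1 penalty weight.
#' @param tol convergence tolerance on the objective decrease per sweep.
#' @param max_sweeps cap on full coordinate sweeps.
#' @param beta_init optional warm start.
#' @return object of class `coda_lasso`: `beta0` (intercept), `beta`
#'   (named, zero-sum), `lambda`, `objective`, `objective_trace`,
#'   `selected_positive` / `selected_negative` (taxa with nonzero
#'   coefficients, sorted by |beta|), `converged`, `sweeps`.
#' @examples
#' x <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("t", 1:6)))
#' fit <- coda_lasso(x, x[, 1] - x[, 2] + rnorm(10, 0, .1), lambda = 0.5)
#' sum(coef(fit)[-1])  # zero-sum constraint
#' @export
coda_lasso <- function(x, y, lambda, tol = 1e-8, max_sweeps = 1000,
                       beta_init = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite inputs")
  if (nrow(x) != length(y)) stop("x and y disagree on the number of samples")
  if (lambda < 0) stop("lambda must be non-negative")
  J <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(J))
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  yc <- y - ym
  if (is.null(beta_init)) beta_init <- numeric(J)
  res <- zs_cd_fit(crossprod(xc), as.numeric(crossprod(xc, yc)),
                   sum(yc^2), beta_init, lambda, tol, max_sweeps)
  if (!res$converged)
    warning("coordinate descent did not converge in ", max_sweeps, " sweeps")
  beta <- setNames(as.numeric(res$beta), colnames(x))
  beta0 <- ym - sum(beta * xm)
  nz <- beta[beta != 0]
  structure(list(beta0 = beta0, beta = beta, lambda = lambda,
                 objective = res$objective,
                 objective_trace = as.numeric(res$trace),
                 selected_positive = names(sort(-nz[nz > 0])),
                 selected_negative = names(sort(nz[nz < 0])),
                 converged = res$converged, sweeps = res$sweeps,
                 n = nrow(x)),
            class = "coda_lasso")
}

#' @export
print.coda_lasso <- function(x, ...) {
  cat(sprintf("zero-sum log-contrast lasso: lambda = %.4g, %d taxa, %d selected\n",
              x$lambda, length(x$beta), sum(x$beta != 0)))
  if (length(x$selected_positive))
    cat("  positive:", paste(head(x$selected_positive, 6), collapse = ", "), "\n")
  if (length(x$selected_negative))
    cat("  negative:", paste(head(x$selected_negative, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.coda_lasso <- function(object, ...)
  c("(Intercept)" = object$beta0, object$beta)

#' @export
predict.coda_lasso <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, names(object$beta), drop = FALSE]
  as.numeric(object$beta0 + newdata %*% object$beta)
}

#' @export
plot.coda_lasso <- function(x, ...) {
  nz <- sort(x$beta[x$beta != 0])
  if (!length(nz)) { message("no nonzero coefficients"); return(invisible(x)) }
  op <- par(mar = c(4, 9, 1, 1)); on.exit(par(op))
  barplot(nz, horiz = TRUE, las = 1,
          col = ifelse(nz > 0, "steelblue", "firebrick"),
          xlab = "log-contrast coefficient", ...)
  invisible(x)
}

#' Cross-validate the lasso penalty
#'
#' K-fold cross-validation over a lambda grid with seeded fold assignment.
#' The grid defaults to 30 log-spaced values from `lambda_max` (the
#' smallest penalty shrinking every coefficient to zero, which for the
#' zero-sum lasso is `max_jk |(x_j - x_k)' y_c| / 2`) down three decades.
#' The selected `lambda` minimises the mean held-out squared error; ties
#' go to the larger (sparser) value. With `repeats > 1` the fold
#' assignment is redrawn that many times and the error curves averaged
#' (repeated K-fold CV), which stabilises the minimum when single-split
#' curves are noisy at small sample sizes.
#'
#' @inheritParams coda_lasso
#' @param lambda optional numeric grid; computed from the data when NULL.
#' @param n_folds number of folds (>= 2).
#' @param seed optional seed fixing the fold assignments.
#' @param repeats number of independent fold assignments to average.
#' @return list with `lambda` (the selected value), `cv_curve`
#'   (data.frame: lambda, mean_error, se), and `fold` (the first
#'   repeat's assignments).
#' @export
cross_validate_lambda <- function(x, y, lambda = NULL, n_folds = 5,
                                  seed = NULL, repeats = 1, tol = 1e-8,
                                  max_sweeps = 400) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (is.null(lambda)) {
    v <- as.numeric(crossprod(sweep(x, 2, colMeans(x)), y - mean(y)))
    lmax <- (max(v) - min(v)) / 2
    if (lmax <= 0) lmax <- 1
    lambda <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 30))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  if (!is.null(seed)) local_seed(seed)
  err <- matrix(NA_real_, length(lambda), n_folds * repeats)
  fold1 <- NULL
  for (r in seq_len(repeats)) {
    fold <- sample(rep(seq_len(n_folds), length.out = n))
    if (r == 1) fold1 <- fold
    if (min(table(fold)) < 2) stop("a fold has fewer than 2 samples")
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      warm <- NULL
      for (i in seq_along(lambda)) {
        fit <- suppressWarnings(
          coda_lasso(x[tr, , drop = FALSE], y[tr], lambda[i],
                     tol = tol, max_sweeps = max_sweeps, beta_init = warm))
        warm <- unname(fit$beta)
        err[i, (r - 1) * n_folds + f] <-
          mean((y[!tr] - predict(fit, x[!tr, , drop = FALSE]))^2)
      }
    }
  }
  mean_err <- rowMeans(err)
  se <- apply(err, 1, sd) / sqrt(ncol(err))
  best <- which(mean_err <= min(mean_err) + 1e-12)[1]  # grid descends: first = largest
  list(lambda = lambda[best],
       cv_curve = data.frame(lambda = lambda, mean_error = mean_err, se = se),
       fold = fold1)
}

#' Temperature-associated compositional signature
#'
#' End-to-end log-contrast analysis of one covariate: aggregates the
#' dataset to a taxonomic rank, keeps the `n_top` most abundant taxa,
#' applies pseudocount/closure/log, selects the penalty by repeated
#' K-fold cross-validation and fits the zero-sum lasso at that penalty.
#' The reported signature keeps the coefficients of meaningful size:
#' taxa with `|beta|` of at least `signature_floor` times the largest
#' `|beta|` (penalised fits at a prediction-optimal lambda routinely
#' carry a fringe of near-zero coefficients that are not reproducible
#' associations). The positively and negatively associated sets are
#' disjoint by construction.
#'
#' @param ds an `nc_dataset`.
#' @param covariate metadata column used as the response.
#' @param n_top number of most-abundant taxa retained (the regression is
#'   run on this subcomposition).
#' @param rank taxonomic rank to aggregate to.
#' @param n_folds,cv_repeats,seed cross-validation controls (fold count,
#'   number of repeated fold assignments averaged, seed). The default
#'   12-fold keeps training folds close to the full sample size, which
#'   matters when taxa outnumber samples: smaller folds make the error
#'   curve erratic and the selected penalty unstable.
#' @param signature_floor relative magnitude below which a nonzero
#'   coefficient is left out of the reported signature (fraction of the
#'   largest `|beta|`; 0 reports every nonzero coefficient).
#' @param pseudocount zero-replacement pseudocount.
#' @return a `coda_lasso` object with extra fields `cv_curve`, `n_folds`,
#'   `seed`, `covariate`.
#' @export
temperature_signature <- function(ds, covariate = "temperature", n_top = 100,
                                  rank = "genus", n_folds = 12,
                                  cv_repeats = 3, seed = 1,
                                  signature_floor = 0.1, pseudocount = 1) {
  stopifnot(inherits(ds, "nc_dataset"))
  y <- ds$metadata[[covariate]]
  if (is.null(y) || anyNA(y)) stop("covariate '", covariate,
                                   "' must be defined for all samples")
  y <- as.numeric(y)
  tab <- aggregate_to_rank(ds, rank)
  if (nrow(tab) < 2) stop("fewer than 2 taxa after aggregation")
  tab <- top_n_taxa(tab, min(n_top, nrow(tab)))
  x <- t(zero_replace_and_log(tab, pseudocount))
  if (var(y) == 0) {
    fit <- coda_lasso(x, y, lambda = 1)  # lambda irrelevant: yc = 0
    fit$cv_curve <- NULL
  } else {
    cv <- cross_validate_lambda(x, y, n_folds = n_folds, seed = seed,
                                repeats = cv_repeats)
    fit <- suppressWarnings(coda_lasso(x, y, cv$lambda, max_sweeps = 5000))
    fit$cv_curve <- cv$cv_curve
  }
  floor_val <- max(signature_floor * max(abs(fit$beta), 0), 1e-8)
  sig <- fit$beta[abs(fit$beta) >= floor_val]
  fit$selected_positive <- names(sort(-sig[sig > 0]))
  fit$selected_negative <- names(sort(sig[sig < 0]))
  fit$signature_floor <- signature_floor
  fit$n_folds <- n_folds
  fit$seed <- seed
  fit$covariate <- covariate
  fit
}
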