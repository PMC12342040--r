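#' Expected rarefied richness
#'
#' Analytic expectation of the number of taxa observed in a random
#' subsample of `depth` reads drawn without replacement:
#' `E[S] = sum_i (1 - choose(N - N_i, depth) / choose(N, depth))`
#' (the hypergeometric expectation, evaluated stably through
#' `vegan::rarefy`). A Monte-Carlo mode performs actual subsampling and is
#' used as an independent cross-check.
#'
#' @param x non-negative integer count vector for one sample, or a taxa x
#'   samples matrix (each column rarefied separately).
#' @param depth subsample size; must not exceed the sample total.
#' @param method `"analytic"` (default, deterministic) or `"montecarlo"`.
#' @param n_draws Monte-Carlo draws.
#' @param seed optional seed for the Monte-Carlo mode.
#' @return expected richness (vector for matrix input). Monte-Carlo
#'   estimates carry the standard error of the mean as attribute `"se"`.
#' @export
rarefied_richness <- function(x, depth, method = c("analytic", "montecarlo"),
                              n_draws = 1000, seed = NULL) {
  method <- match.arg(method)
  if (is.matrix(x))
    return(vapply(seq_len(ncol(x)),
                  function(j) rarefied_richness(x[, j], depth, method, n_draws, seed),
                  numeric(1)))
  x <- as.numeric(x)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  N <- sum(x)
  if (depth > N) stop("rarefaction depth ", depth, " exceeds sample total ", N)
  if (method == "analytic")  # rarefy warns about singleton-free data
    return(as.numeric(suppressWarnings(vegan::rarefy(matrix(x, nrow = 1),
                                                     depth))))
  if (!is.null(seed)) local_seed(seed)
  pool <- rep.int(seq_along(x), x)
  draws <- vapply(seq_len(n_draws),
                  function(i) length(unique(sample(pool, depth))), numeric(1))
  structure(mean(draws), se = sd(draws) / sqrt(n_draws))
}

#' Shannon entropy of a sample
#'
#' `H = -sum p_i log p_i` in nats, over taxa with nonzero counts.
#'
#' @param x count (or proportion) vector, or taxa x samples matrix.
#' @return entropy in nats (vector for matrix input).
#' @export
shannon_entropy <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, shannon_entropy))
  if (sum(x) <= 0) stop("all-zero sample")
  as.numeric(vegan::diversity(matrix(x, nrow = 1), index = "shannon"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y)` on raw counts.
#'
#' @param table taxa x samples count matrix with positive column sums.
#' @return a `dist` object labelled by sample id.
#' @export
bray_curtis <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) < 2) stop("need at least two samples")
  if (any(colSums(table) <= 0)) stop("zero-sum sample")
  vegan::vegdist(t(table), method = "bray")
}

#' Jaccard presence/absence dissimilarity matrix
#'
#' @param table taxa x samples count matrix; counts >= 1 mark presence.
#' @return a `dist` object.
#' @export
jaccard_distance <- function(table) {
  vegan::vegdist(t(as.matrix(table) > 0), method = "jaccard", binary = TRUE)
}

# Per-branch descendant mass for every sample. Returns the edge x sample
# matrix of summed tip values and the matching branch lengths.
edge_sample_mass <- function(tree, table) {
  if (is.null(rownames(table))) stop("table must have taxon rownames")
  missing <- setdiff(rownames(table)[rowSums(table) > 0], tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(head(missing, 5), collapse = ", "))
  extra <- setdiff(tree$tip.label, rownames(table))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  acc <- matrix(0, n_tip + tree$Nnode, ncol(table))
  acc[seq_len(n_tip), ] <- table[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    acc[pa, ] <- acc[pa, ] + acc[ch, ]
  }
  list(mass = acc[tree$edge[, 2], , drop = FALSE], len = tree$edge.length)
}

#' Unweighted UniFrac distances
#'
#' For each sample pair: branch length leading exclusively to taxa present
#' in one of the two samples, divided by the branch length leading to taxa
#' present in either.
#'
#' @param table taxa x samples count matrix; counts >= 1 mark presence.
#' @param tree rooted `phylo` tree containing every detected taxon as a tip.
#' @return a `dist` object with values in \[0, 1\].
#' @export
unweighted_unifrac <- function(table, tree) {
  table <- as.matrix(table)
  es <- edge_sample_mass(tree, (table > 0) * 1)
  pres <- es$mass > 0
  S <- ncol(table)
  d <- matrix(0, S, S, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    uni <- sum(es$len[xor(pres[, i], pres[, j])])
    tot <- sum(es$len[pres[, i] | pres[, j]])
    d[i, j] <- d[j, i] <- if (tot > 0) uni / tot else 0
  }
  as.dist(d)
}

#' Weighted UniFrac distances
#'
#' `sum_b l_b |A_b - B_b|` over branches, where `A_b` is the proportion of
#' sample A's reads descending from branch `b`; when `normalized` the sum
#' is divided by `sum_b l_b (A_b + B_b)`.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized divide by the abundance-weighted total branch length
#'   (bounds the distance to \[0, 1\]).
#' @return a `dist` object.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  rel <- relative_abundance(table)
  es <- edge_sample_mass(tree, rel)
  S <- ncol(rel)
  d <- matrix(0, S, S, dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    num <- sum(es$len * abs(es$mass[, i] - es$mass[, j]))
    if (normalized) {
      den <- sum(es$len * (es$mass[, i] + es$mass[, j]))
      num <- if (den > 0) num / den else 0
    }
    d[i, j] <- d[j, i] <- num
  }
  as.dist(d)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: the squared distance matrix is double-centred,
#' eigendecomposed, and coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues are reported,
#' not silently dropped; the proportion explained is computed over positive
#' eigenvalues.
#'
#' @param d a `dist` object or square symmetric matrix.
#' @param n_axes number of axes to return (default 2).
#' @return an object of class `nc_pcoa` with elements `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending) and
#'   `proportion_explained`.
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (n_axes > n) stop("n_axes exceeds the number of samples")
  fit <- suppressWarnings(cmdscale(d, k = min(n_axes, n - 1), eig = TRUE))
  eig <- fit$eig
  # axes whose eigenvalue is numerically zero carry no structure, only
  # sqrt-amplified rounding noise: zero them out
  tol <- max(abs(eig), 1) * 1e-12
  pos <- sum(eig > tol)
  coords <- matrix(0, n, n_axes,
                   dimnames = list(attr(d, "Labels"),
                                   paste0("PCo", seq_len(n_axes))))
  if (pos > 0 && !is.null(fit$points) && ncol(fit$points) > 0) {
    k <- min(n_axes, ncol(fit$points), pos)
    coords[, seq_len(k)] <- fit$points[, seq_len(k)]
  }
  prop <- if (pos > 0) pmax(eig, 0) / sum(pmax(eig, 0)) else rep(0, length(eig))
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop[seq_len(n_axes)]),
            class = "nc_pcoa")
}

#' @export
print.nc_pcoa <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes\n")
  cat("  proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.nc_pcoa <- function(x, col = 1, ...) {
  plot(x$coordinates[, 1], x$coordinates[, 2], col = col,
       xlab = sprintf("PCo1 (%.1f%%)", 100 * x$proportion_explained[1]),
       ylab = sprintf("PCo2 (%.1f%%)", 100 * x$proportion_explained[2]), ...)
}

# all permutations of 1..n (n small), as a matrix with one row each
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i)) # insert i, shift the rest
  }))
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (McArdle-Anderson). For
#' a categorical covariate with `a` groups the pseudo-F is
#' `F = (SS_between/(a-1)) / (SS_within/(N-a))` with sums of squares from
#' pairwise squared distances; numeric covariates are tested by regression
#' on the double-centred Gower matrix, `SS_model = z'Gz / z'z` for the
#' centred covariate `z`. Significance comes from seeded label
#' permutations, `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`,
#' or from complete enumeration when `permutations = "exhaustive"`.
#' Samples are put in canonical (sorted-label) order internally so results
#' do not depend on input ordering.
#'
#' @param d `dist` object or square matrix of dissimilarities.
#' @param covariate vector aligned with the samples of `d` (names are
#'   matched against the distance labels when present); character/factor
#'   values give the categorical test, numeric values the regression form.
#' @param permutations number of random permutations (>= 99), or
#'   `"exhaustive"` to enumerate all orderings (feasible up to ~8 samples).
#' @param seed optional integer; fixes the permutation stream.
#' @param name covariate name stored in the result.
#' @return object of class `nc_permanova` with fields `covariate`,
#'   `pseudo_f`, `r_squared`, `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, covariate, permutations = 999, seed = NULL,
                      name = deparse(substitute(covariate))) {
  d <- as.matrix(as.dist(d))
  n <- nrow(d)
  if (length(covariate) != n) stop("covariate length does not match distance matrix")
  labs <- rownames(d)
  if (!is.null(names(covariate)) && !is.null(labs)) {
    if (!setequal(names(covariate), labs))
      stop("covariate names do not match distance labels")
    covariate <- covariate[labs]
  }
  # canonical sample order: invariance to input ordering
  if (!is.null(labs)) {
    ord <- order(labs)
    d <- d[ord, ord]
    covariate <- covariate[ord]
  }
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  if (is.numeric(covariate) && !is.factor(covariate)) {
    G <- -0.5 * scale(t(scale(t(d2), scale = FALSE)), scale = FALSE)
    z <- covariate - mean(covariate)
    if (all(z == 0)) stop("constant covariate")
    fstat <- function(zz) {
      ssm <- as.numeric(crossprod(zz, G %*% zz)) / sum(zz^2)
      (ssm) / ((ss_total - ssm) / (n - 2))
    }
    df1 <- 1
    ssb_of <- function(zz) as.numeric(crossprod(zz, G %*% zz)) / sum(zz^2)
    perm_item <- z
  } else {
    f <- factor(covariate)
    if (any(table(f) < 2)) stop("every group needs at least 2 samples")
    a <- nlevels(f)
    if (a < 2) stop("need at least two groups")
    fstat <- function(ff) {
      ssw <- 0
      for (g in levels(ff)) {
        i <- which(ff == g)
        ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
      }
      ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
    }
    df1 <- a - 1
    ssb_of <- function(ff) {
      ssw <- 0
      for (g in levels(ff)) {
        i <- which(ff == g)
        ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
      }
      ss_total - ssw
    }
    perm_item <- f
  }

  f_obs <- fstat(perm_item)
  r2 <- ssb_of(perm_item) / ss_total

  if (identical(permutations, "exhaustive")) {
    if (n > 9) stop("exhaustive enumeration is limited to 9 samples")
    pm <- all_perms(n)
    f_perm <- apply(pm, 1, function(ix) fstat(perm_item[ix]))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- nrow(pm)
  } else {
    if (permutations < 99) stop("use at least 99 permutations")
    if (!is.null(seed)) local_seed(seed)
    f_perm <- vapply(seq_len(permutations),
                     function(i) fstat(perm_item[sample.int(n)]), numeric(1))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + permutations)
    n_perm <- permutations
  }

  structure(list(covariate = name, pseudo_f = f_obs, r_squared = r2,
                 p_value = p, n_permutations = n_perm, seed = seed,
                 df = c(df1, n - df1 - 1)),
            class = "nc_permanova")
}

#' @export
print.nc_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA [%s]: pseudo-F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$covariate, x$df[1], x$df[2], x$pseudo_f, x$r_squared,
              x$p_value, x$n_permutations))
  invisible(x)
}

# run a block of code with a temporary RNG seed, restoring global state
local_seed <- function(seed) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    do.call(on.exit, list(bquote(assign(".Random.seed", .(old), globalenv())),
                          add = TRUE), envir = parent.frame())
  }
  set.seed(seed)
}
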