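# Fixed-metric and learned-linear-metric baseline correspondence scores.
# All baselines share the same contract as the learned network: cells and
# atlas positions in, a C x P matrix of similarities in [0,1] out.

# Convert a distance matrix to similarities in [0,1]. Global scaling by the
# largest distance preserves cross-cell comparability; per-cell scaling is
# available behind the flag. Zero distance always maps to similarity 1.
distance_to_similarity <- function(d, scale = c("global", "per_cell")) {
  scale <- match.arg(scale)
  if (scale == "global") {
    dmax <- max(d)
    if (dmax == 0) {
      return(d + 1)
    }
    return(1 - d / dmax)
  }
  dmax <- apply(d, 1, max)
  dmax[dmax == 0] <- 1
  1 - sweep(d, 1, dmax, `/`)
}

# Distance of every cell to every position under one of the fixed metrics.
pairwise_distances <- function(cells, atlas, kind) {
  cc <- nrow(cells)
  p <- nrow(atlas)
  d <- matrix(0, cc, p)
  for (j in seq_len(p)) {
    diff <- sweep(cells, 2, atlas[j, ])
    d[, j] <- switch(kind,
      two_norm = sqrt(rowSums(diff^2)),
      inf_norm = apply(abs(diff), 1, max),
      percent_diff = {
        denom <- sweep(cells, 2, atlas[j, ], `+`) / 2
        term <- abs(diff) / denom
        term[denom == 0] <- 0  # both silent: no disagreement
        rowMeans(term)
      })
  }
  dimnames(d) <- list(rownames(cells), rownames(atlas))
  d
}

#' Fixed-metric baseline correspondence scores
#'
#' Scores every cell against every atlas position using a predefined
#' dissimilarity in the space of common genes: the Euclidean 2-norm, the
#' infinity norm (largest per-gene deviation), or the mean percent
#' difference `mean(|c - p| / ((c + p)/2))` with 0/0 terms defined as 0.
#' Distances are converted to similarities `S = 1 - d/d_max`; with the
#' default global scaling `d_max` is the largest distance over all pairs.
#'
#' @param cells C x G matrix (or [gene_expression_table]) with values in
#'   [0,1].
#' @param atlas P x G matrix (or [spatial_atlas]) with values in [0,1].
#' @param kind one of `"two_norm"`, `"inf_norm"`, `"percent_diff"`.
#' @param scale `"global"` (default) or `"per_cell"` distance scaling.
#' @return A C x P correspondence matrix with entries in [0,1].
#' @export
fixed_metric_scores <- function(cells, atlas,
                                kind = c("two_norm", "inf_norm",
                                         "percent_diff"),
                                scale = c("global", "per_cell")) {
  kind <- match.arg(kind)
  cells <- as_samples_matrix(cells)
  atlas <- as_samples_matrix(atlas)
  if (nrow(cells) == 0 || nrow(atlas) == 0 || ncol(cells) == 0) {
    stop("empty input")
  }
  if (ncol(cells) != ncol(atlas)) {
    stop("cells and atlas differ in gene dimension")
  }
  d <- pairwise_distances(cells, atlas, kind)
  distance_to_similarity(d, scale)
}

#' Fit a push-only large-margin linear metric on an atlas
#'
#' Learns a linear transform T defining the distance
#' `d(x, y) = ||T (x - y)||_2` by minimizing the push-only hinge objective
#' `sum over ordered pairs i != j of max(0, margin - d(x_i, x_j)^2)`: each
#' atlas position is its own sole target (at distance zero) and every other
#' position is an imposter that must be pushed at least `margin` away in
#' squared distance. The margin defaults to the dimensionality of the fitted
#' space. When the input has more than `pca_components` genes, a PCA
#' reduction to `pca_components` dimensions is applied first and stored in
#' the metric.
#'
#' Optimization is plain gradient descent from the identity transform with
#' backtracking line search; if the hinge is already inactive everywhere the
#' identity is returned unchanged. Coincident positions can never be
#' separated and are counted in the diagnostics.
#'
#' @param atlas P x D matrix (or [spatial_atlas]).
#' @param margin hinge margin on squared distance; default = fitted
#'   dimensionality.
#' @param max_iter maximum gradient iterations.
#' @param step_size initial step size; default set from the gradient scale.
#' @param pca_components dimensionality threshold above which a PCA
#'   reduction is applied first (default 50).
#' @param tol relative objective-improvement tolerance for convergence.
#' @return An object of class `linear_metric` with elements `transform`,
#'   `fitted_dim`, `margin`, `reduction` (`NULL` or PCA rotation/center),
#'   `objective`, `initial_objective`, `n_coincident`, `iterations`,
#'   `converged`.
#' @export
fit_lmnn <- function(atlas, margin = NULL, max_iter = 200L,
                     step_size = NULL, pca_components = 50L, tol = 1e-8) {
  x <- as_samples_matrix(atlas)
  p <- nrow(x)
  if (p < 2) {
    stop("need at least 2 positions to fit a metric")
  }
  reduction <- NULL
  if (ncol(x) > pca_components) {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    keep <- min(pca_components, ncol(pc$rotation))
    reduction <- list(rotation = pc$rotation[, seq_len(keep), drop = FALSE],
                      center = pc$center)
    x <- pc$x[, seq_len(keep), drop = FALSE]
  }
  d_dim <- ncol(x)
  if (is.null(margin)) {
    margin <- d_dim
  }
  pairs <- utils::combn(p, 2L)
  delta <- x[pairs[1, ], , drop = FALSE] - x[pairs[2, ], , drop = FALSE]
  n_coincident <- sum(rowSums(delta^2) == 0)

  objective <- function(tr) {
    s <- rowSums((delta %*% t(tr))^2)
    2 * sum(pmax(0, margin - s))  # both orderings of each pair
  }
  gradient <- function(tr) {
    s <- rowSums((delta %*% t(tr))^2)
    act <- s < margin
    if (!any(act)) {
      return(matrix(0, d_dim, d_dim))
    }
    a <- crossprod(delta[act, , drop = FALSE])
    -4 * tr %*% a
  }

  tr <- diag(d_dim)
  obj <- objective(tr)
  initial_objective <- obj
  step <- step_size %||% (1 / (4 * sum(delta^2) + 1e-12))
  converged <- obj == 0
  iterations <- 0L
  floor_obj <- 2 * n_coincident * margin  # unattainable below this
  for (it in seq_len(max_iter)) {
    if (obj <= floor_obj + tol) {
      converged <- TRUE
      break
    }
    g <- gradient(tr)
    accepted <- FALSE
    for (half in 0:30) {
      cand <- tr - step * g
      obj_cand <- objective(cand)
      if (obj_cand < obj) {
        tr <- cand
        obj <- obj_cand
        step <- step * 1.2
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    iterations <- it
    if (!accepted) {
      converged <- TRUE  # no descent direction improves: local optimum
      break
    }
  }
  if (!converged && obj > floor_obj + tol) {
    warning("metric fit did not converge in ", max_iter,
            " iterations; returning best iterate (objective ",
            format(obj, digits = 4), ")")
  }
  structure(list(transform = tr, fitted_dim = d_dim, margin = margin,
                 reduction = reduction, objective = obj,
                 initial_objective = initial_objective,
                 n_coincident = n_coincident,
                 iterations = iterations, converged = converged),
            class = "linear_metric")
}

#' @export
print.linear_metric <- function(x, ...) {
  cat("linear_metric:", x$fitted_dim, "dims, margin", x$margin,
      ", objective", format(x$objective, digits = 4),
      "after", x$iterations, "iterations\n")
  if (x$n_coincident > 0) {
    cat("  note:", x$n_coincident, "coincident position pair(s) cannot be",
        "separated\n")
  }
  invisible(x)
}

#' Correspondence scores under a fitted linear metric
#'
#' Applies the metric's stored PCA reduction (if any) to both sides, then
#' converts `d = ||T (c - p)||_2` to similarity with the same global
#' `1 - d/d_max` scaling as [fixed_metric_scores]. Rescaling T leaves the
#' similarity matrix unchanged.
#'
#' @param metric a [fit_lmnn] result.
#' @param cells C x D matrix (or [gene_expression_table]).
#' @param atlas P x D matrix (or [spatial_atlas]).
#' @param scale `"global"` or `"per_cell"`.
#' @return A C x P correspondence matrix with entries in [0,1].
#' @export
lmnn_scores <- function(metric, cells, atlas,
                        scale = c("global", "per_cell")) {
  stopifnot(inherits(metric, "linear_metric"))
  cells <- as_samples_matrix(cells)
  atlas <- as_samples_matrix(atlas)
  if (ncol(cells) != ncol(atlas)) {
    stop("cells and atlas differ in gene dimension")
  }
  if (!is.null(metric$reduction)) {
    cells <- sweep(cells, 2, metric$reduction$center) %*%
      metric$reduction$rotation
    atlas <- sweep(atlas, 2, metric$reduction$center) %*%
      metric$reduction$rotation
  }
  if (ncol(cells) != metric$fitted_dim) {
    stop("dimension (", ncol(cells), ") does not match fitted metric (",
         metric$fitted_dim, ")")
  }
  tc <- cells %*% t(metric$transform)
  ta <- atlas %*% t(metric$transform)
  d <- matrix(0, nrow(tc), nrow(ta))
  for (j in seq_len(nrow(ta))) {
    d[, j] <- sqrt(rowSums(sweep(tc, 2, ta[j, ])^2))
  }
  dimnames(d) <- list(rownames(cells), rownames(atlas))
  distance_to_similarity(d, match.arg(scale))
}
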