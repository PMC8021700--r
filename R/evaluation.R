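# The two evaluation frameworks: (1) the performance score, combining
# accuracy, precision, and noise-robustness penalties measured on
# exact-copy simulated cells; (2) k-fold gene-dropout predictive
# reproducibility, which holds out folds of genes, re-scores, and uses the
# correspondence scores as weights to impute the held-out expression.

#' Wrap a scoring function as a uniform scoring method
#'
#' A scoring method is any callable `(cells, atlas) -> C x P matrix` with
#' entries in [0,1], where `cells` and `atlas` are samples x genes matrices
#' over the same genes. All evaluation routines are agnostic to how the
#' matrix was produced.
#'
#' @param fun function of `(cells, atlas)` returning a C x P matrix.
#' @param label short character label for reports.
#' @return An object of class `scoring_method`.
#' @export
scoring_method <- function(fun, label = "custom") {
  stopifnot(is.function(fun))
  structure(list(fun = fun, label = label), class = "scoring_method")
}

#' @export
print.scoring_method <- function(x, ...) {
  cat("scoring_method:", x$label, "\n")
  invisible(x)
}

# Invoke a scoring method and enforce the correspondence-matrix contract.
score_with <- function(method, cells, atlas) {
  stopifnot(inherits(method, "scoring_method"))
  s <- method$fun(as_samples_matrix(cells), as_samples_matrix(atlas))
  s <- as.matrix(s)
  if (nrow(s) != nrow(as_samples_matrix(cells)) ||
      ncol(s) != nrow(as_samples_matrix(atlas))) {
    stop("method '", method$label, "' returned a matrix of wrong shape")
  }
  if (any(!is.finite(s))) {
    stop("method '", method$label, "' returned non-finite scores")
  }
  if (any(s < -1e-8) || any(s > 1 + 1e-8)) {
    warning("method '", method$label,
            "' returned scores outside [0,1]; clipping")
  }
  clip01(s)
}

#' @rdname scoring_method
#' @param kind fixed metric kind, see [fixed_metric_scores].
#' @export
method_fixed_metric <- function(kind = c("two_norm", "inf_norm",
                                         "percent_diff")) {
  kind <- match.arg(kind)
  scoring_method(function(cells, atlas) {
    fixed_metric_scores(cells, atlas, kind = kind)
  }, label = kind)
}

#' @rdname scoring_method
#' @param metric optional fitted [fit_lmnn] metric; when `NULL` the metric
#'   is (re)fitted on the atlas at every call, which is what the gene-fold
#'   reproducibility scheme requires.
#' @param ... further arguments passed to [fit_lmnn].
#' @export
method_lmnn <- function(metric = NULL, ...) {
  scoring_method(function(cells, atlas) {
    m <- metric %||% fit_lmnn(atlas, ...)
    lmnn_scores(m, cells, atlas)
  }, label = "lmnn")
}

#' @rdname scoring_method
#' @param model optional frozen model: a list with elements `params`
#'   (network parameters) and `space` (feature space). When `NULL`, the
#'   feature space and network are re-fitted on the given atlas at every
#'   call using `n_components` and `config`.
#' @param n_components,config used when refitting, see [fit_feature_space]
#'   and [training_config].
#' @export
method_network <- function(model = NULL, n_components = 8L,
                           config = training_config()) {
  scoring_method(function(cells, atlas) {
    if (is.null(model)) {
      space <- fit_feature_space(atlas, n_components = n_components)
      fit <- train_network(project_features(atlas, space, side = "atlas"),
                           config)
      params <- fit$params
    } else {
      space <- model$space
      params <- model$params
    }
    score_cells(params,
                project_features(cells, space, side = "cells"),
                project_features(atlas, space, side = "atlas"))
  }, label = "network")
}

#' @rdname scoring_method
#' @param scores a precomputed C x P matrix, returned as-is (clipped to
#'   [0,1] with a warning if needed) regardless of the inputs.
#' @export
method_external <- function(scores) {
  scores <- as.matrix(scores)
  scoring_method(function(cells, atlas) scores, label = "external")
}

#' @rdname scoring_method
#' @details `method_identity_oracle()` returns the identity correspondence
#'   (likelihood 1 at position i for cell i, 0 elsewhere) regardless of the
#'   input values, making it ideal and noise-invariant; it is the reference
#'   point at which the performance score equals exactly 1.
#' @export
method_identity_oracle <- function() {
  scoring_method(function(cells, atlas) {
    if (nrow(cells) != nrow(atlas)) {
      stop("identity oracle requires C = P")
    }
    diag(1, nrow(cells), nrow(atlas))
  }, label = "identity_oracle")
}

#' Per-cell accuracy penalty
#'
#' For exact-copy simulated cells (cell i originates from position i), the
#' accuracy penalty is `1 - S[i,i]`: did the known origin receive a high
#' likelihood?
#'
#' @param s a C x P correspondence matrix with C = P.
#' @return Numeric vector of per-cell penalties in [0,1].
#' @export
accuracy_penalty <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) {
    stop("accuracy penalty needs C = P (exact-copy simulation)")
  }
  as.numeric(1 - diag(s))
}

#' Per-cell precision penalty
#'
#' `|1 - sum_j S[i,j]| / (P - 1)`: did the other positions receive low
#' likelihoods? An ideal row (1 at the true origin, 0 elsewhere) scores 0;
#' a row of all ones scores 1.
#'
#' @param s a C x P correspondence matrix, P >= 2.
#' @return Numeric vector of per-cell penalties in [0,1].
#' @export
precision_penalty <- function(s) {
  s <- as.matrix(s)
  if (ncol(s) < 2) {
    stop("precision penalty needs at least 2 positions")
  }
  pmin(abs(1 - rowSums(s)) / (ncol(s) - 1), 1)
}

# Shared noise sweep: returns the baseline per-cell mean penalty and the
# cells x grid matrix of mean penalties under noise.
noise_sweep <- function(method, atlas_matrix, noise_grid, replicates, seed) {
  if (length(noise_grid) == 0) {
    stop("noise grid is empty")
  }
  if (any(noise_grid < 0 | noise_grid > 1) || is.unsorted(noise_grid)) {
    stop("noise grid must be increasing values in [0,1]")
  }
  if (replicates < 1) {
    stop("replicates must be >= 1")
  }
  a <- atlas_matrix
  s0 <- score_with(method, a, a)
  m0 <- (accuracy_penalty(s0) + precision_penalty(s0)) / 2
  set.seed(seed)
  m_noise <- matrix(0, nrow(a), length(noise_grid))
  for (g in seq_along(noise_grid)) {
    acc <- numeric(nrow(a))
    for (r in seq_len(replicates)) {
      noisy <- clip01(a + matrix(stats::rnorm(length(a), 0, noise_grid[g]),
                                 nrow(a), ncol(a)))
      s <- score_with(method, noisy, a)
      acc <- acc + (accuracy_penalty(s) + precision_penalty(s)) / 2
    }
    m_noise[, g] <- acc / replicates
  }
  list(baseline = m0, under_noise = m_noise, s0 = s0)
}

#' Per-cell noise-robustness threshold sigma*
#'
#' Exact-copy simulated cells are perturbed with Gaussian noise of
#' increasing standard deviation sigma (clipped back to [0,1]) and
#' re-scored. For each cell, sigma* is the smallest grid sigma at which the
#' mean of its accuracy and precision penalties has risen by at least 0.1
#' over the noise-free value, or 1 if no grid value achieves that. The
#' robustness penalty used in the performance score is `(1 - sigma*)^4`.
#'
#' @param method a [scoring_method].
#' @param atlas a [spatial_atlas] or P x G matrix in [0,1].
#' @param noise_grid increasing noise levels in [0,1]
#'   (default 0.05, 0.10, ..., 1).
#' @param replicates noise replicates averaged per grid level (default 5).
#' @param seed integer seed for the noise draws.
#' @param jump required rise in the mean penalty (default 0.1).
#' @return Numeric vector of per-cell sigma* values in (0,1].
#' @export
sigma_star <- function(method, atlas, noise_grid = seq(0.05, 1, by = 0.05),
                       replicates = 5L, seed = 1L, jump = 0.1) {
  a <- as_samples_matrix(atlas)
  sw <- noise_sweep(method, a, noise_grid, replicates, seed)
  sigma_star_from_sweep(sw, noise_grid, jump)
}

sigma_star_from_sweep <- function(sw, noise_grid, jump = 0.1) {
  rise <- sw$under_noise - sw$baseline
  vapply(seq_len(nrow(rise)), function(i) {
    hit <- which(rise[i, ] >= jump)
    if (length(hit) == 0) 1 else noise_grid[hit[1]]
  }, numeric(1))
}

#' Performance score of a mapping method on a self-mapped atlas
#'
#' Builds exact-copy simulated cells (C = P, cell i identical to position
#' i), scores them, and combines three per-cell penalties into
#' `E_i = 1 - (accuracy + precision + (1 - sigma*)^4) / 3`, averaged into
#' the aggregate score E. E = 1 is an ideal mapping: the true origin gets
#' likelihood 1, every other position 0, robust to noise.
#'
#' @inheritParams sigma_star
#' @param sigma_star_values optional per-cell sigma* vector (recycled if
#'   length 1); when supplied the noise sweep is skipped and the robustness
#'   penalty is computed from these values directly.
#' @return An object of class `performance_breakdown`: aggregate `E`, a
#'   `per_cell` data frame (position id, coordinates, penalties, sigma*,
#'   E_i) suitable for per-position heatmaps, and the noise settings used.
#' @export
performance_score <- function(method, atlas,
                              noise_grid = seq(0.05, 1, by = 0.05),
                              replicates = 5L, seed = 1L,
                              sigma_star_values = NULL) {
  a <- as_samples_matrix(atlas)
  if (is.null(sigma_star_values)) {
    sw <- noise_sweep(method, a, noise_grid, replicates, seed)
    s0 <- sw$s0
    ss <- sigma_star_from_sweep(sw, noise_grid)
  } else {
    s0 <- score_with(method, a, a)
    ss <- rep_len(sigma_star_values, nrow(a))
  }
  acc <- accuracy_penalty(s0)
  prec <- precision_penalty(s0)
  rob <- (1 - ss)^4
  e_i <- 1 - (acc + prec + rob) / 3
  coords <- if (inherits(atlas, "spatial_atlas")) {
    as.data.frame(atlas$coordinates)
  } else {
    data.frame(x = rep(NA_real_, nrow(a)), y = rep(NA_real_, nrow(a)))
  }
  per_cell <- data.frame(
    position_id = rownames(a) %||% paste0("pos_", seq_len(nrow(a))),
    coords,
    accuracy_penalty = acc, precision_penalty = prec,
    sigma_star = ss, robustness_penalty = rob, E_i = e_i,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(E = mean(e_i), per_cell = per_cell,
                 noise_grid = noise_grid, replicates = replicates,
                 seed = seed, method = method$label),
            class = "performance_breakdown")
}

#' @export
print.performance_breakdown <- function(x, ...) {
  cat("performance_breakdown [", x$method, "]: E =",
      format(x$E, digits = 4), "over", nrow(x$per_cell), "positions\n")
  cat("  mean penalties: accuracy",
      format(mean(x$per_cell$accuracy_penalty), digits = 4),
      "| precision", format(mean(x$per_cell$precision_penalty), digits = 4),
      "| robustness", format(mean(x$per_cell$robustness_penalty),
                             digits = 4), "\n")
  invisible(x)
}

#' Seeded balanced k-fold split of genes
#'
#' Partitions the gene identifiers into k folds whose sizes differ by at
#' most one. The same seed always yields the same split, so that every
#' method can be evaluated on identical folds.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param k number of folds (2 <= k <= number of genes).
#' @param seed integer seed.
#' @return Integer vector of fold labels (1..k) named by gene identifier,
#'   in the input gene order.
#' @export
kfold_gene_split <- function(gene_ids, k, seed = 1L) {
  g <- length(gene_ids)
  if (k > g) {
    stop("k (", k, ") exceeds the number of genes (", g, ")")
  }
  if (k < 2) {
    stop("k must be at least 2")
  }
  set.seed(seed)
  ord <- sample.int(g)
  sizes <- rep(g %/% k, k) + c(rep(1L, g %% k), rep(0L, k - g %% k))
  fold <- integer(g)
  fold[ord] <- rep(seq_len(k), times = sizes)
  names(fold) <- gene_ids
  fold
}

#' Score-weighted prediction of cell expression for a held-out gene
#'
#' `chat_i = sum_j S[i,j] p_j / sum_j S[i,j]`: the correspondence scores
#' (computed without the held-out gene's fold) weight the atlas expression
#' of that gene. A cell whose score row is all zero gets prediction 0, with
#' a warning.
#'
#' @param s_k C x P correspondence matrix computed on the retained folds.
#' @param atlas_gene numeric vector of the held-out gene over positions.
#' @return Numeric vector of predicted expression over cells.
#' @export
predict_cell_expression <- function(s_k, atlas_gene) {
  s_k <- as.matrix(s_k)
  if (length(atlas_gene) != ncol(s_k)) {
    stop("atlas gene vector length does not match positions")
  }
  w <- rowSums(s_k)
  pred <- as.numeric(s_k %*% atlas_gene)
  zero <- w == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with all-zero score rows; prediction 0")
    pred[zero] <- 0
    w[zero] <- 1
  }
  pred / w
}

#' Score-weighted prediction of atlas expression for a held-out gene
#'
#' Column-wise analogue of [predict_cell_expression]:
#' `phat_j = sum_i S[i,j] c_i / sum_i S[i,j]`.
#'
#' @param s_k C x P correspondence matrix computed on the retained folds.
#' @param cell_gene numeric vector of the held-out gene over cells.
#' @return Numeric vector of predicted expression over positions.
#' @export
predict_atlas_expression <- function(s_k, cell_gene) {
  s_k <- as.matrix(s_k)
  if (length(cell_gene) != nrow(s_k)) {
    stop("cell gene vector length does not match cells")
  }
  w <- colSums(s_k)
  pred <- as.numeric(crossprod(s_k, cell_gene))
  zero <- w == 0
  if (any(zero)) {
    warning(sum(zero), " position(s) with all-zero score columns; ",
            "prediction 0")
    pred[zero] <- 0
    w[zero] <- 1
  }
  pred / w
}

# One-minus-mean-absolute-error reproducibility terms for one gene, split
# by whether the true value is zero or positive. Empty index sets give NA
# (the gene is then excluded from that aggregate).
reproducibility_terms <- function(truth, pred) {
  zero <- truth == 0
  r_zero <- if (any(zero)) 1 - mean(abs(pred[zero] - truth[zero]))
            else NA_real_
  r_nonzero <- if (any(!zero)) 1 - mean(abs(pred[!zero] - truth[!zero]))
               else NA_real_
  list(zero = r_zero, nonzero = r_nonzero,
       n_zero = sum(zero), n_nonzero = sum(!zero))
}

#' k-fold gene-dropout predictive reproducibility
#'
#' Randomly splits the common genes into k folds. For each fold, the
#' correspondence matrix is recomputed using only the genes of the other
#' folds (trainable methods refit on that reduced atlas). Each held-out
#' gene is then predicted in both directions -- scRNA-seq from the atlas
#' ([predict_cell_expression]) and atlas from the cells
#' ([predict_atlas_expression]) -- and scored as one minus the mean
#' absolute prediction error, separately over entries whose true value is
#' zero versus positive. Averaging over genes (skipping genes whose index
#' set is empty) yields the four aggregates `R_sc_zero`, `R_sc_nonzero`,
#' `R_atlas_zero`, `R_atlas_nonzero`.
#'
#' @param method a [scoring_method].
#' @param cells C x G matrix (or [gene_expression_table]) in [0,1].
#' @param atlas P x G matrix (or [spatial_atlas]) over the same genes.
#' @param k number of folds (typical values 4 or 5).
#' @param seed integer seed for the fold split.
#' @return An object of class `reproducibility_report`: the four
#'   aggregates, a `per_gene` data frame, the fold assignment, `k`, `seed`.
#' @export
reproducibility <- function(method, cells, atlas, k = 4L, seed = 1L) {
  cells <- as_samples_matrix(cells)
  atlas <- as_samples_matrix(atlas)
  if (ncol(cells) != ncol(atlas)) {
    stop("cells and atlas differ in gene dimension")
  }
  if (any(cells < 0 | cells > 1) || any(atlas < 0 | atlas > 1)) {
    stop("reproducibility expects expression values in [0,1]")
  }
  gene_ids <- colnames(atlas) %||% paste0("gene_", seq_len(ncol(atlas)))
  folds <- kfold_gene_split(gene_ids, k, seed)
  per_gene <- data.frame(gene_id = gene_ids, fold = folds,
                         R_sc_zero = NA_real_, R_sc_nonzero = NA_real_,
                         R_atlas_zero = NA_real_, R_atlas_nonzero = NA_real_,
                         stringsAsFactors = FALSE, row.names = NULL)
  for (f in seq_len(k)) {
    keep <- folds != f
    s_f <- score_with(method,
                      cells[, keep, drop = FALSE],
                      atlas[, keep, drop = FALSE])
    for (g in which(folds == f)) {
      chat <- predict_cell_expression(s_f, atlas[, g])
      phat <- predict_atlas_expression(s_f, cells[, g])
      sc <- reproducibility_terms(cells[, g], chat)
      at <- reproducibility_terms(atlas[, g], phat)
      per_gene$R_sc_zero[g] <- sc$zero
      per_gene$R_sc_nonzero[g] <- sc$nonzero
      per_gene$R_atlas_zero[g] <- at$zero
      per_gene$R_atlas_nonzero[g] <- at$nonzero
    }
  }
  structure(list(R_sc_zero = mean(per_gene$R_sc_zero, na.rm = TRUE),
                 R_sc_nonzero = mean(per_gene$R_sc_nonzero, na.rm = TRUE),
                 R_atlas_zero = mean(per_gene$R_atlas_zero, na.rm = TRUE),
                 R_atlas_nonzero = mean(per_gene$R_atlas_nonzero,
                                        na.rm = TRUE),
                 per_gene = per_gene, folds = folds, k = k, seed = seed,
                 method = method$label),
            class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat("reproducibility_report [", x$method, "], k =", x$k, ":\n")
  cat("  R_sc_zero    =", format(x$R_sc_zero, digits = 4), "\n")
  cat("  R_sc_nonzero =", format(x$R_sc_nonzero, digits = 4), "\n")
  cat("  R_atlas_zero =", format(x$R_atlas_zero, digits = 4), "\n")
  cat("  R_atlas_nonzero =", format(x$R_atlas_nonzero, digits = 4), "\n")
  invisible(x)
}
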