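# Gene alignment, normalization, and the shared low-dimensional feature
# space used by the learned correspondence network.

#' Restrict an atlas and a cell table to their common genes
#'
#' Both sides are restricted to the shared gene identifiers, in atlas order,
#' so that expression vectors are directly comparable.
#'
#' @param atlas a [spatial_atlas].
#' @param cells a [gene_expression_table].
#' @return An object of class `aligned_pair`: a list with elements `atlas`
#'   and `cells` carrying identical gene sequences.
#' @export
intersect_genes <- function(atlas, cells) {
  stopifnot(inherits(atlas, "spatial_atlas"),
            inherits(cells, "gene_expression_table"))
  common <- atlas$gene_ids[atlas$gene_ids %in% cells$gene_ids]
  if (length(common) == 0) {
    stop("no genes shared between atlas and cells")
  }
  atlas2 <- spatial_atlas(atlas$expression[, common, drop = FALSE],
                          atlas$coordinates,
                          gene_ids = common,
                          position_ids = atlas$position_ids,
                          is_binary = NULL)
  cells2 <- gene_expression_table(cells$values[common, , drop = FALSE],
                                  gene_ids = common,
                                  sample_ids = cells$sample_ids)
  structure(list(atlas = atlas2, cells = cells2), class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("aligned_pair:", length(x$atlas$gene_ids), "common genes,",
      nrow(x$atlas$expression), "positions,",
      length(x$cells$sample_ids), "cells\n")
  invisible(x)
}

#' Normalize each gene of an expression table onto [0,1]
#'
#' Optionally applies a `log1p` transform, then maps each gene linearly onto
#' the unit interval. Genes that are constant across samples map to zero
#' rather than an arbitrary midpoint, so that no artificial signal is
#' introduced.
#'
#' @param cells a [gene_expression_table].
#' @param log_transform apply `log1p` before rescaling (default `FALSE`).
#' @return A [gene_expression_table] with values in [0,1].
#' @export
normalize_cells <- function(cells, log_transform = FALSE) {
  stopifnot(inherits(cells, "gene_expression_table"))
  v <- cells$values
  if (log_transform) {
    v <- log1p(v)
  }
  lo <- apply(v, 1, min)
  hi <- apply(v, 1, max)
  rng <- hi - lo
  out <- (v - lo) / ifelse(rng > 0, rng, 1)
  out[rng == 0, ] <- 0
  gene_expression_table(out, gene_ids = cells$gene_ids,
                        sample_ids = cells$sample_ids)
}

#' Fit a shared PCA feature space on an atlas
#'
#' Principal components are computed on the atlas expression (positions x
#' genes). Projected atlas features are shifted and scaled so that they lie
#' exactly in [0,1]: the per-component minimum over the fitting atlas is
#' absorbed into the centering vector and the resulting maximum becomes
#' `atlas_scale`. Cell matrices are later projected with the same
#' coefficients (see [project_features]).
#'
#' The default of eight components follows the observation that a small
#' number of principal components of the atlas carries enough structure for
#' position discrimination while keeping network training cheap.
#'
#' @param atlas_common a [spatial_atlas] or a positions x genes matrix
#'   restricted to the common genes.
#' @param n_components requested number of components (default 8); reduced
#'   with a warning if it exceeds `min(P-1, G)` or the effective rank.
#' @param tie_scales if `TRUE`, cells projected through this space are
#'   scaled by `atlas_scale` instead of their own maximum, tying the two
#'   sides onto one scale.
#' @return An object of class `feature_space` with elements `basis`
#'   (genes x N), `centering`, `atlas_scale`, `cell_scale`, `n_components`.
#' @export
fit_feature_space <- function(atlas_common, n_components = 8L,
                              tie_scales = FALSE) {
  x <- as_samples_matrix(atlas_common)
  p <- nrow(x)
  g <- ncol(x)
  if (p < 2) {
    stop("need at least 2 positions to fit a feature space")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-7)
  if (rank == 0) {
    stop("atlas has no variation across positions")
  }
  n_eff <- min(n_components, p - 1L, g, rank)
  if (n_eff < n_components) {
    warning("n_components reduced from ", n_components, " to ", n_eff,
            " (limited by positions, genes, or effective rank)")
  }
  basis <- pc$rotation[, seq_len(n_eff), drop = FALSE]
  scores <- pc$x[, seq_len(n_eff), drop = FALSE]
  offs <- apply(scores, 2, min)
  # Absorb the per-component shift into the centering vector: the basis has
  # orthonormal columns, so (x - (center + B o)) B = (x - center) B - o.
  centering <- as.numeric(pc$center + basis %*% offs)
  shifted <- sweep(scores, 2, offs)
  atlas_scale <- max(shifted)
  structure(list(basis = basis, centering = centering,
                 atlas_scale = atlas_scale,
                 cell_scale = if (tie_scales) atlas_scale else NA_real_,
                 n_components = n_eff,
                 gene_ids = colnames(x)),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat("feature_space:", nrow(x$basis), "genes ->", x$n_components,
      "components (atlas_scale =", format(x$atlas_scale, digits = 4), ")\n")
  invisible(x)
}

#' Project expression data into a fitted feature space
#'
#' Rows are centered, projected onto the stored basis, divided by the
#' side's scale, and clipped to [0,1]. On the `"atlas"` side the scale is
#' `atlas_scale` and the fitting atlas reproduces its fit-time features
#' exactly. On the `"cells"` side the scale defaults to the projected cell
#' matrix's own maximum (each matrix normalized by its largest element)
#' unless the space was fitted with `tie_scales = TRUE`.
#'
#' @param x a [gene_expression_table], [spatial_atlas], or samples x genes
#'   matrix over the space's genes.
#' @param space a [fit_feature_space] result.
#' @param side `"atlas"` or `"cells"`.
#' @param clip clip the scaled features to [0,1] (default `TRUE`); disable
#'   only for numerical diagnostics.
#' @return A samples x N feature matrix with values in [0,1].
#' @export
project_features <- function(x, space, side = c("cells", "atlas"),
                             clip = TRUE) {
  side <- match.arg(side)
  stopifnot(inherits(space, "feature_space"))
  m <- as_samples_matrix(x)
  if (ncol(m) != nrow(space$basis)) {
    stop("gene dimension (", ncol(m), ") does not match feature space (",
         nrow(space$basis), ")")
  }
  raw <- sweep(m, 2, space$centering) %*% space$basis
  if (side == "atlas") {
    scale <- space$atlas_scale
  } else if (!is.na(space$cell_scale)) {
    scale <- space$cell_scale
  } else {
    scale <- max(raw)
    if (!is.finite(scale) || scale <= 0) {
      scale <- space$atlas_scale
    }
  }
  feats <- raw / scale
  if (clip) {
    feats <- clip01(feats)
  }
  rownames(feats) <- rownames(m)
  colnames(feats) <- paste0("F", seq_len(ncol(feats)))
  feats
}

#' Binarize a continuous atlas at a cutoff
#'
#' Values at or above the cutoff become 1 ("on"), values below become 0.
#' The boundary is inclusive.
#'
#' @param atlas a [spatial_atlas].
#' @param cutoff threshold in (0,1); 0.2 is a common choice for sparse
#'   in-situ style atlases.
#' @return A binary [spatial_atlas].
#' @export
binarize_atlas <- function(atlas, cutoff = 0.2) {
  stopifnot(inherits(atlas, "spatial_atlas"))
  if (!(cutoff > 0 && cutoff < 1)) {
    stop("cutoff must lie in (0,1)")
  }
  expr <- ifelse(atlas$expression >= cutoff, 1, 0)
  spatial_atlas(expr, atlas$coordinates, gene_ids = atlas$gene_ids,
                position_ids = atlas$position_ids, is_binary = TRUE)
}

#' Convert a binary atlas to a continuous one by spatial smoothing
#'
#' Each gene is smoothed by a truncated-Gaussian weighted average over
#' positions within `kernel_radius` in coordinate space, then perturbed
#' with a small amount of Gaussian noise and clipped to [0,1]. This mimics
#' graded expression around "on" regions when only a thresholded atlas is
#' available.
#'
#' @param atlas a binary [spatial_atlas].
#' @param kernel_radius truncation radius of the smoothing kernel; default
#'   1.5 x the median nearest-neighbor distance. The Gaussian bandwidth is
#'   half the radius.
#' @param noise_sd standard deviation of the added Gaussian noise
#'   (default 0.05).
#' @param seed optional integer seed for the noise.
#' @return A continuous [spatial_atlas].
#' @export
continuize_atlas <- function(atlas, kernel_radius = NULL, noise_sd = 0.05,
                             seed = NULL) {
  stopifnot(inherits(atlas, "spatial_atlas"))
  if (!atlas$is_binary) {
    stop("continuize_atlas expects a binary atlas")
  }
  d <- as.matrix(stats::dist(atlas$coordinates))
  if (is.null(kernel_radius)) {
    nn <- apply(d + diag(Inf, nrow(d)), 1, min)
    kernel_radius <- 1.5 * stats::median(nn)
  }
  if (kernel_radius <= 0) {
    stop("kernel_radius must be positive")
  }
  h <- kernel_radius / 2
  w <- exp(-(d / h)^2 / 2)
  w[d > kernel_radius] <- 0
  smoothed <- (w %*% atlas$expression) / rowSums(w)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    smoothed <- smoothed + stats::rnorm(length(smoothed), 0, noise_sd)
  }
  smoothed <- clip01(smoothed)
  spatial_atlas(smoothed, atlas$coordinates, gene_ids = atlas$gene_ids,
                position_ids = atlas$position_ids, is_binary = NULL)
}
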