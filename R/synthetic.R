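# Synthetic spatial atlases and matched ground-truth cells. The generator
# emulates the structural regimes the mapping methods face in real systems:
# smooth spatial expression patterns (gradients, stripes, localized bumps)
# on 2-D or 1-D layouts, optional binarization, additive Gaussian noise,
# dropout zeros, and spatially unstructured decoy genes present only in the
# cells.

#' Configuration for the synthetic-data generator
#'
#' @param P number of atlas positions (>= 4).
#' @param G_spatial number of spatially patterned atlas genes (>= 2).
#' @param G_extra number of decoy genes added to the cells only; they carry
#'   spatially unstructured uniform values and exist to exercise gene
#'   intersection and reproducibility bookkeeping.
#' @param layout spatial layout of the positions: `"grid"` (near-square
#'   2-D grid), `"disk"` (sunflower packing of a disk), or `"strip"` (1-D
#'   line).
#' @param patterns pattern types cycled over the genes: `"gradient"`
#'   (affine in the coordinates), `"stripe"` (softly thresholded sinusoid
#'   along a random axis), `"bump"` (Gaussian of distance to a random
#'   center).
#' @param noise_sd Gaussian noise added to cells around their origin's
#'   expression (on the [0,1] scale).
#' @param dropout_prob probability that any cell expression entry is zeroed.
#' @param cells_per_position simulated cells per atlas position.
#' @param binarize_cutoff optional cutoff in (0,1); if given the atlas is
#'   binarized.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(P = 64L, G_spatial = 20L, G_extra = 0L,
                             layout = c("grid", "disk", "strip"),
                             patterns = c("gradient", "stripe", "bump"),
                             noise_sd = 0, dropout_prob = 0,
                             cells_per_position = 1L,
                             binarize_cutoff = NULL, seed = 1L) {
  layout <- match.arg(layout)
  patterns <- match.arg(patterns, several.ok = TRUE)
  if (P < 4) {
    stop("P must be at least 4")
  }
  if (G_spatial < 2) {
    stop("G_spatial must be at least 2")
  }
  if (noise_sd < 0) {
    stop("noise_sd must be nonnegative")
  }
  if (!(dropout_prob >= 0 && dropout_prob <= 1)) {
    stop("dropout_prob must lie in [0,1]")
  }
  if (cells_per_position < 1) {
    stop("cells_per_position must be >= 1")
  }
  if (!is.null(binarize_cutoff) &&
      !(binarize_cutoff > 0 && binarize_cutoff < 1)) {
    stop("binarize_cutoff must lie in (0,1)")
  }
  structure(list(P = as.integer(P), G_spatial = as.integer(G_spatial),
                 G_extra = as.integer(G_extra), layout = layout,
                 patterns = patterns, noise_sd = noise_sd,
                 dropout_prob = dropout_prob,
                 cells_per_position = as.integer(cells_per_position),
                 binarize_cutoff = binarize_cutoff,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

layout_coordinates <- function(p, layout) {
  switch(layout,
    grid = {
      nx <- ceiling(sqrt(p))
      ny <- ceiling(p / nx)
      xy <- expand.grid(x = seq(0, 1, length.out = nx),
                        y = seq(0, 1, length.out = ny))
      as.matrix(xy[seq_len(p), c("x", "y")])
    },
    disk = {
      i <- seq_len(p)
      r <- sqrt((i - 0.5) / p)
      theta <- i * pi * (3 - sqrt(5))
      cbind(x = 0.5 + 0.5 * r * cos(theta),
            y = 0.5 + 0.5 * r * sin(theta))
    },
    strip = cbind(x = seq(0, 1, length.out = p), y = rep(0, p)))
}

# Map raw pattern values to [0,1] per gene; constant genes (possible only
# in degenerate layouts) fall back to zero.
unit_scale <- function(v) {
  rng <- max(v) - min(v)
  if (rng == 0) {
    return(rep(0, length(v)))
  }
  (v - min(v)) / rng
}

#' Generate a synthetic spatial atlas
#'
#' Positions are laid out per the configured layout with coordinates in the
#' unit square; each gene gets one of the configured pattern types with
#' randomized orientation/frequency/center, scaled to span [0,1].
#'
#' @param config a [synthetic_config].
#' @return A [spatial_atlas] with `P` positions and `G_spatial` genes.
#' @export
make_atlas <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  coords <- layout_coordinates(config$P, config$layout)
  expr <- matrix(0, config$P, config$G_spatial)
  for (g in seq_len(config$G_spatial)) {
    pat <- config$patterns[(g - 1L) %% length(config$patterns) + 1L]
    v <- switch(pat,
      gradient = {
        theta <- stats::runif(1, 0, 2 * pi)
        cos(theta) * coords[, 1] + sin(theta) * coords[, 2]
      },
      stripe = {
        theta <- stats::runif(1, 0, pi)
        freq <- sample(2:4, 1)
        phase <- stats::runif(1, 0, 2 * pi)
        proj <- cos(theta) * coords[, 1] + sin(theta) * coords[, 2]
        stats::plogis(10 * sin(2 * pi * freq * proj + phase))
      },
      bump = {
        center <- coords[sample.int(config$P, 1), ]
        width <- stats::runif(1, 0.1, 0.3)
        d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2
        exp(-d2 / (2 * width^2))
      })
    expr[, g] <- unit_scale(v)
  }
  atlas <- spatial_atlas(expr, coords,
                         gene_ids = paste0("gene_", seq_len(config$G_spatial)),
                         position_ids = paste0("pos_", seq_len(config$P)))
  if (!is.null(config$binarize_cutoff)) {
    atlas <- binarize_atlas(atlas, config$binarize_cutoff)
  }
  atlas
}

#' Generate ground-truth cells from a synthetic atlas
#'
#' Each atlas position spawns `cells_per_position` cells: the position's
#' expression plus Gaussian noise (clipped to [0,1]), entries zeroed with
#' probability `dropout_prob`, and `G_extra` spatially unstructured decoy
#' genes appended. Cell generation uses a substream of the configured seed
#' distinct from the atlas draw, so atlas and cells are jointly
#' reproducible.
#'
#' @param atlas a [spatial_atlas], normally from [make_atlas].
#' @param config a [synthetic_config].
#' @return A list with elements `cells` (a [gene_expression_table], genes x
#'   cells) and `truth` (data frame `cell_id`, `position`, `position_id`
#'   with the generation parameters attached as attribute `params`).
#' @export
make_cells <- function(atlas, config = synthetic_config()) {
  stopifnot(inherits(atlas, "spatial_atlas"),
            inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  p <- nrow(atlas$expression)
  n <- p * config$cells_per_position
  origins <- rep(seq_len(p), each = config$cells_per_position)
  expr <- atlas$expression[origins, , drop = FALSE]
  if (config$noise_sd > 0) {
    expr <- clip01(expr + matrix(stats::rnorm(length(expr), 0,
                                              config$noise_sd),
                                 nrow(expr), ncol(expr)))
  }
  if (config$dropout_prob > 0) {
    expr[matrix(stats::runif(length(expr)) < config$dropout_prob,
                nrow(expr), ncol(expr))] <- 0
  }
  if (config$G_extra > 0) {
    decoys <- matrix(stats::runif(n * config$G_extra), n, config$G_extra)
    colnames(decoys) <- paste0("decoy_", seq_len(config$G_extra))
    expr <- cbind(expr, decoys)
  }
  cell_ids <- paste0("cell_", seq_len(n))
  cells <- gene_expression_table(t(expr),
                                 gene_ids = colnames(expr),
                                 sample_ids = cell_ids)
  truth <- data.frame(cell_id = cell_ids, position = origins,
                      position_id = atlas$position_ids[origins],
                      stringsAsFactors = FALSE)
  attr(truth, "params") <- unclass(config)
  list(cells = cells, truth = truth)
}

#' Exact-copy simulated cells from an atlas
#'
#' Returns a C = P cell table where cell i is an exact copy of atlas
#' position i; the evaluation framework's self-mapping regime with known
#' ground-truth origins.
#'
#' @param atlas a [spatial_atlas].
#' @return A [gene_expression_table] whose transposed values equal the
#'   atlas expression bit-for-bit.
#' @export
exact_copy_cells <- function(atlas) {
  stopifnot(inherits(atlas, "spatial_atlas"))
  gene_expression_table(t(atlas$expression),
                        gene_ids = atlas$gene_ids,
                        sample_ids = paste0("cell_",
                                            seq_len(nrow(atlas$expression))))
}
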