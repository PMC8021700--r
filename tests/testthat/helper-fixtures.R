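# Shared fixtures built in code.

# Hand-built 4-position, 3-gene continuous atlas on a unit square.
tiny_atlas <- function() {
  expr <- rbind(c(0.0, 1.0, 0.2),
                c(0.5, 0.8, 0.0),
                c(1.0, 0.2, 0.6),
                c(0.2, 0.0, 1.0))
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  spatial_atlas(expr, coords,
                gene_ids = c("ga", "gb", "gc"),
                position_ids = paste0("p", 1:4))
}

# Deterministic cells table over given genes.
tiny_cells <- function(gene_ids = c("gb", "gc", "gd"), n = 2) {
  set.seed(99)
  vals <- matrix(stats::runif(length(gene_ids) * n, 0, 10),
                 length(gene_ids), n)
  gene_expression_table(vals, gene_ids = gene_ids,
                        sample_ids = paste0("c", seq_len(n)))
}

# Write a dense genes x samples TSV fixture; returns the path.
write_dense_fixture <- function(mat, gene_ids, sample_ids,
                                path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = gene_ids, mat, check.names = FALSE)
  colnames(df) <- c("gene_id", sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A scoring method whose matrix is one-hot at the true position when
# C = P (identity pairing), used as the perfect-prediction oracle.
one_hot_oracle <- function() method_identity_oracle()

# Small feature matrix + trained network shared by slow network tests.
trained_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(P = 12, G_spatial = 12, seed = 3)
      atlas <- make_atlas(cfg)
      space <- fit_feature_space(atlas, 4)
      feats <- project_features(atlas, space, side = "atlas")
      tc <- training_config(max_epochs = 1500, patience = 1500L,
                            batch_size = 256L, train_frac = 1,
                            training_multiple = 199L, seed = 7)
      fit <- suppressWarnings(train_network(feats, tc))
      cache <<- list(atlas = atlas, space = space, feats = feats,
                     fit = fit, config = tc)
    }
    cache
  }
})
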