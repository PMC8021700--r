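# Small internal helpers shared across modules.

# Clamp values into the unit interval. Expression levels and network inputs
# are contractually in [0,1] throughout the package.
clip01 <- function(x) {
  pmin(pmax(x, 0), 1)
}

# Coerce the various sample containers to a plain samples x genes matrix.
# Accepts a spatial_atlas (positions x genes), a gene_expression_table
# (stored genes x samples, so transposed here), or a numeric matrix taken
# to already be samples x genes.
as_samples_matrix <- function(x) {
  if (inherits(x, "spatial_atlas")) {
    return(x$expression)
  }
  if (inherits(x, "gene_expression_table")) {
    return(t(x$values))
  }
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a samples x genes matrix")
}

# Weak fingerprint of a configuration object, used to stamp output files so
# that runs can be matched to the settings that produced them.
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = " ")
  b <- utf8ToInt(s)
  h <- sum(b * (seq_along(b) %% 97 + 1)) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
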