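# Fixed-metric and learned linear-metric baseline scores.

test_that("fixed metrics give similarity 1 at zero distance", {
  atlas <- rbind(c(0, 0), c(1, 1), c(0.4, 0.9))
  cells <- atlas[c(2, 3), ]
  for (kind in c("two_norm", "inf_norm", "percent_diff")) {
    s <- fixed_metric_scores(cells, atlas, kind)
    expect_equal(s[1, 2], 1)
    expect_equal(s[2, 3], 1)
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("two-norm and percent-difference match hand computations", {
  atlas <- rbind(c(0, 0), c(1, 1))
  cell <- rbind(c(0, 0))
  s <- fixed_metric_scores(cell, atlas, "two_norm")
  expect_equal(unname(s[1, ]), c(1, 0))   # d = (0, sqrt(2)), global max sqrt(2)

  # cell (1,0) vs positions (0,0) and (1,0): per-gene terms (2,0) -> mean 1
  a2 <- rbind(c(0, 0), c(1, 0))
  s2 <- fixed_metric_scores(rbind(c(1, 0)), a2, "percent_diff")
  d <- atlasmap:::pairwise_distances(rbind(c(1, 0)), a2, "percent_diff")
  expect_equal(unname(d[1, ]), c(1, 0))   # 0/0 term contributes 0
  expect_equal(unname(s2[1, ]), c(0, 1))
})

test_that("percent difference is symmetric and scores are
           permutation-equivariant", {
  set.seed(14)
  cells <- matrix(runif(4 * 5), 4, 5)
  atlas <- matrix(runif(6 * 5), 6, 5)
  d1 <- atlasmap:::pairwise_distances(cells, atlas, "percent_diff")
  d2 <- atlasmap:::pairwise_distances(atlas, cells, "percent_diff")
  expect_equal(d1, t(d2))

  pc <- sample(4); pa <- sample(6)
  for (kind in c("two_norm", "inf_norm", "percent_diff")) {
    s <- fixed_metric_scores(cells, atlas, kind)
    sp <- fixed_metric_scores(cells[pc, ], atlas[pa, ], kind)
    expect_equal(sp, s[pc, pa])
  }
})

test_that("per-cell scaling maps each row's zero distance to one", {
  atlas <- rbind(c(0, 0), c(0.2, 0.1), c(1, 1))
  s <- fixed_metric_scores(atlas, atlas, "two_norm", scale = "per_cell")
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_equal(min(s), 0)
})

test_that("metric fitting returns the identity when the hinge is inactive", {
  # pairwise squared distances all exceed the margin under the identity
  atlas <- diag(4) * 10
  m <- fit_lmnn(atlas, margin = 4)
  expect_equal(m$transform, diag(4))
  expect_equal(m$objective, 0)
  expect_true(m$converged)
})

test_that("coincident positions are flagged and bound the objective", {
  atlas <- rbind(c(0.2, 0.4), c(0.2, 0.4), c(0.9, 0.1))
  m <- suppressWarnings(fit_lmnn(atlas, max_iter = 50))
  expect_equal(m$n_coincident, 1L)
  expect_gte(m$objective, 2 * m$margin - 1e-8)
})

test_that("metric fitting descends from the identity initialization", {
  set.seed(77)
  atlas <- matrix(runif(5 * 3), 5, 3)
  m <- suppressWarnings(fit_lmnn(atlas, max_iter = 100))
  expect_lte(m$objective, m$initial_objective)
})

test_that("metric scores reduce to the two-norm under the identity and are
           scale-invariant", {
  set.seed(30)
  atlas <- matrix(runif(6 * 4), 6, 4)
  cells <- matrix(runif(3 * 4), 3, 4)
  id <- structure(list(transform = diag(4), fitted_dim = 4L, margin = 4,
                       reduction = NULL, objective = 0,
                       initial_objective = 0, n_coincident = 0L,
                       iterations = 0L, converged = TRUE),
                  class = "linear_metric")
  expect_equal(lmnn_scores(id, cells, atlas),
               fixed_metric_scores(cells, atlas, "two_norm"))

  sc <- id; sc$transform <- 2 * diag(4)
  expect_equal(lmnn_scores(sc, cells, atlas), lmnn_scores(id, cells, atlas))

  # an exact-copy cell attains similarity 1 under any learned transform
  m <- suppressWarnings(fit_lmnn(atlas, max_iter = 25))
  s <- lmnn_scores(m, atlas[2, , drop = FALSE], atlas)
  expect_equal(s[1, 2], 1)
})

test_that("high-dimensional atlases are reduced to 50 components first", {
  set.seed(41)
  atlas <- matrix(runif(20 * 60), 20, 60)
  m <- suppressWarnings(fit_lmnn(atlas, max_iter = 10))
  expect_false(is.null(m$reduction))
  expect_lte(m$fitted_dim, 50L)
  s <- lmnn_scores(m, atlas[1:2, ], atlas)
  expect_equal(dim(s), c(2L, 20L))
  expect_equal(s[1, 1], 1)
})
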