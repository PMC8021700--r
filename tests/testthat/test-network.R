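# Self-supervised pair construction, the pairwise likelihood network, its
# weighted objective, and scoring.

test_that("pair datasets have the stated composition and determinism", {
  set.seed(1)
  f <- matrix(runif(10 * 4), 10, 4)
  cfg <- training_config(train_frac = 0.9, training_multiple = 99L,
                         seed = 5)
  expect_warning(ds <- build_pair_datasets(f, cfg), "replacement")
  expect_equal(nrow(ds$train$inputs), 900L)
  expect_equal(sum(ds$train$match_flags), 9L)
  expect_equal(mean(ds$train$match_flags), 0.01)

  # exhaustive tiny grid
  f2 <- matrix(runif(2 * 3), 2, 3)
  cfg2 <- training_config(train_frac = 1, training_multiple = 1L, seed = 2)
  ds2 <- build_pair_datasets(f2, cfg2)
  expect_equal(nrow(ds2$train$inputs), 4L)
  expect_equal(nrow(ds2$validation$inputs), 0L)

  # determinism: same seed identical, different seed different non-matches
  dsa <- suppressWarnings(build_pair_datasets(f, cfg))
  expect_identical(dsa, ds)
  cfgb <- training_config(train_frac = 0.9, training_multiple = 99L,
                          seed = 6)
  dsb <- suppressWarnings(build_pair_datasets(f, cfgb))
  expect_false(identical(dsb$train$pairs, ds$train$pairs))
})

test_that("training split size and match fraction hold across P", {
  for (p in c(5L, 8L, 13L)) {
    f <- matrix(runif(p * 3), p, 3)
    cfg <- training_config(train_frac = 0.8, training_multiple = 4L,
                           seed = p)
    ds <- suppressWarnings(build_pair_datasets(f, cfg))
    m <- round(0.8 * p)
    expect_equal(nrow(ds$train$inputs), m * 5L)
    expect_equal(mean(ds$train$match_flags), 1 / 5)
    expect_identical(ds$train$targets, as.numeric(ds$train$match_flags))
    # no pair occurs in both splits
    key <- function(prs) paste(prs[, 1], prs[, 2])
    expect_length(intersect(unique(key(ds$train$pairs)),
                            key(ds$validation$pairs)), 0)
  }
})

test_that("forward pass is a deterministic likelihood in (0,1)", {
  params <- init_network(4, seed = 3)
  x <- matrix(runif(6 * 8), 6, 8)
  y <- network_forward(params, x)
  expect_true(all(y > 0 & y < 1))
  expect_identical(y, network_forward(params, x))

  zero <- init_network(4, seed = 1)
  for (nm in c("W1", "W2", "W3")) zero[[nm]] <- zero[[nm]] * 0
  expect_equal(network_forward(zero, runif(4), runif(4)), 0.5)

  expect_error(network_forward(params, runif(3), runif(3)), "dimension")
})

test_that("weighted loss reproduces its printed values and gradient", {
  expect_equal(weighted_loss(c(0.3, 0.9), c(0, 1)) , 0.3^2 / 1.001 +
                 0.1^2 / 0.001)
  expect_equal(weighted_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(weighted_loss(0, 1), 1000)
  expect_equal(weighted_loss(1, 0), 1 / 1.001)
  expect_error(weighted_loss(0.5, 0.5), "targets")

  # analytic vs central-difference gradient
  set.seed(8)
  for (rep in 1:5) {
    y <- runif(6, 0.05, 0.95)
    t <- rbinom(6, 1, 0.3)
    g <- weighted_loss_grad(y, t)
    eps <- 1e-6
    num <- vapply(seq_along(y), function(i) {
      yp <- y; yp[i] <- y[i] + eps
      ym <- y; ym[i] <- y[i] - eps
      (weighted_loss(yp, t) - weighted_loss(ym, t)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - g) / pmax(abs(num), 1e-8)), 1e-5)
  }
})

test_that("network gradients agree with central differences", {
  set.seed(12)
  params <- init_network(3, seed = 4)
  x <- matrix(runif(8 * 6), 8, 6)
  tg <- rep(c(1, 0), 4)
  lam <- 1e-4
  gr <- atlasmap:::network_gradients(params, x, tg, lam)
  lossfn <- function(p) {
    weighted_loss(network_forward(p, x), tg) +
      lam * (sum(p$W1^2) + sum(p$W2^2) + sum(p$W3^2))
  }
  eps <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    num <- params[[nm]] * 0
    for (i in seq_along(num)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num[i] <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
    }
    expect_lt(max(abs(num - gr$grads[[nm]]) / pmax(abs(num), 1e-6)), 1e-5)
  }
})

test_that("training noise respects its probability, scale, and clipping", {
  x <- matrix(0.5, 100, 8)
  expect_identical(apply_training_noise(x, 0.1, 0, seed = 1), x)
  expect_identical(apply_training_noise(x, 0, 1, seed = 1), x)

  big <- matrix(0.5, 10000, 2)
  noisy <- apply_training_noise(big, 0.1, 1, seed = 42)
  expect_true(all(noisy[, 2] == 0.5))      # position half untouched
  dev <- abs(noisy[, 1] - 0.5)
  # folded-normal mean: sigma * sqrt(2/pi); no clipping occurs at 0.5 +/- ~0.4
  mu <- 0.1 * sqrt(2 / pi)
  se <- 0.1 * sqrt(1 - 2 / pi) / sqrt(length(dev))
  expect_lt(abs(mean(dev) - mu), 3 * se)

  clipped <- apply_training_noise(matrix(c(0, 1), 5000, 2, byrow = TRUE),
                                  0.3, 1, seed = 7)
  expect_true(all(clipped >= 0 & clipped <= 1))
})

test_that("training reduces the loss, is seed-reproducible, and separates
           matches from non-matches", {
  toy <- trained_toy()
  h <- toy$fit$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_lte(h$stopped_epoch, toy$config$max_epochs)

  s <- score_cells(toy$fit$params, toy$feats, toy$feats)
  margin <- mean(diag(s)) - mean(s[row(s) != col(s)])
  expect_gt(margin, 0.2)

  # short rerun with the same config is bit-identical
  short_cfg <- training_config(max_epochs = 50L, patience = 50L,
                               batch_size = 128L, train_frac = 1,
                               training_multiple = 20L, seed = 9)
  f <- toy$feats
  fit1 <- suppressWarnings(train_network(f, short_cfg))
  fit2 <- suppressWarnings(train_network(f, short_cfg))
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$history$val_rmse, fit2$history$val_rmse)
})

test_that("scoring produces a row-deterministic C x P likelihood matrix", {
  params <- init_network(4, seed = 2)
  af <- matrix(runif(3 * 4), 3, 4)
  cf <- matrix(runif(1 * 4), 1, 4)
  s <- score_cells(params, cf, af)
  expect_equal(dim(s), c(1L, 3L))
  expect_true(all(s > 0 & s < 1))

  dup <- rbind(cf, cf)
  s2 <- score_cells(params, dup, af)
  expect_equal(s2[1, ], s2[2, ])

  # exact-copy simulated cells score identically to the atlas itself
  expect_equal(score_cells(params, af, af),
               score_cells(params, af + 0, af))
})

test_that("argmax assignment breaks ties toward the lowest index", {
  s <- rbind(c(0.1, 0.9, 0.3), c(0.2, 0.1, 0.05))
  expect_equal(unname(assign_origins(s)), c(2L, 1L))
  expect_warning(idx <- assign_origins(rbind(c(0.5, 0.5))), "tied")
  expect_equal(unname(idx), 1L)
})

test_that("network parameters survive a serialization round trip", {
  params <- init_network(5, seed = 31)
  path <- tempfile(fileext = ".json")
  write_network(params, path)
  back <- read_network(path)
  expect_equal(back, params)
  x <- matrix(runif(4 * 10), 4, 10)
  expect_equal(network_forward(back, x), network_forward(params, x))
})
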