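# SPD geometry, covariance estimation, MDM classifier, model persistence.

test_that("epoch covariance matches hand computation and shrinkage limits", {
  withr::with_seed(5, {
    t1 <- as.numeric(scale(rnorm(500)))  # centred, unit variance
    x <- rbind(t1, -t1)
    c0 <- unclass(epoch_covariance(x, cov_spec(shrinkage = 0)))
    expect_equal(c0, matrix(c(1, -1, -1, 1), 2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    c05 <- epoch_covariance(x, cov_spec(shrinkage = 0.05))
    ev <- eigen(c05, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 0.05 * sum(diag(c0)) / 2 - 1e-12)
    # lambda -> 1 limit: scaled identity
    c99 <- unclass(epoch_covariance(x, cov_spec(shrinkage = 0.999)))
    expect_equal(c99, (sum(diag(c0)) / 2) * diag(2), tolerance = 1e-2,
                 ignore_attr = TRUE)
    # LLN: independent unit-variance channels
    big <- matrix(rnorm(2e5), nrow = 2)
    cl <- unclass(epoch_covariance(big, cov_spec(shrinkage = 0)))
    expect_lt(max(abs(cl - diag(2))), 0.02)
  })
  # constant epoch: singular without shrinkage, SPD with it
  const <- matrix(1, 2, 100)
  expect_error(epoch_covariance(const, cov_spec(shrinkage = 0)),
               "singular")
})

test_that("AIRM satisfies its identities and the metric axioms", {
  withr::with_seed(7, {
    c1 <- random_spd(4)
    expect_equal(airm_distance(c1, c1), 0)
    expect_equal(airm_distance(diag(2), diag(c(exp(2), 1))), 2)
    # congruence invariance
    for (rep in 1:10) {
      a <- random_spd(3); b <- random_spd(3)
      w <- matrix(rnorm(9), 3)
      expect_lt(abs(airm_distance(w %*% a %*% t(w), w %*% b %*% t(w)) -
                      airm_distance(a, b)), 1e-8)
    }
    # axioms on random triples
    for (rep in 1:200) {
      a <- random_spd(3); b <- random_spd(3); c <- random_spd(3)
      dab <- airm_distance(a, b)
      expect_gte(dab, 0)
      expect_equal(dab, airm_distance(b, a), tolerance = 1e-10)
      expect_lte(airm_distance(a, c), dab + airm_distance(b, c) + 1e-8)
    }
  })
  expect_error(airm_distance(diag(2), diag(3)), "dimension")
  expect_error(airm_distance(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive definite")
})

test_that("riemannian mean: singleton, commuting case, local optimality", {
  c1 <- seeded_spd(3, 1)
  expect_equal(unclass(riemannian_mean(list(c1))), unclass(c1))
  m <- riemannian_mean(list(diag(c(1, 4)), diag(c(4, 1))))
  expect_equal(unclass(m), diag(c(2, 2)), tolerance = 1e-7,
               ignore_attr = TRUE)
  # log-Euclidean agrees on the commuting case
  ml <- riemannian_mean(list(diag(c(1, 4)), diag(c(4, 1))),
                        metric = "logeuclid")
  expect_equal(unclass(ml), diag(c(2, 2)), tolerance = 1e-10,
               ignore_attr = TRUE)

  withr::with_seed(12, {
    covs <- replicate(20, random_spd(3), simplify = FALSE)
    m <- riemannian_mean(covs)
    frechet <- function(x) sum(vapply(covs, function(c0) {
      airm_distance(x, c0)^2
    }, numeric(1)))
    f0 <- frechet(m)
    m_half <- diag(3)  # perturb on the manifold around m
    e <- eigen(m, symmetric = TRUE)
    m_half <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
    for (rep in 1:1000) {
      z <- matrix(rnorm(9, sd = 0.02), 3)
      z <- (z + t(z)) / 2
      ez <- eigen(z, symmetric = TRUE)
      expz <- ez$vectors %*% (exp(ez$values) * t(ez$vectors))
      cand <- m_half %*% expz %*% m_half
      expect_gte(frechet(as_spd((cand + t(cand)) / 2)), f0 - 1e-9)
    }
  })
  expect_error(riemannian_mean(list()), "empty")
})

test_that("mdm fit/predict honour the degenerate and tie contracts", {
  cfg <- quiet_cfg(seed = 3, n_channels = 3)
  blk <- make_background(4, cfg)
  e1 <- epoch_timelocked(blk, list(marker_event(0.5, label = "a")),
                         epoch_spec(0, 1))[[1L]]
  e2 <- epoch_timelocked(blk, list(marker_event(2.0, label = "b")),
                         epoch_spec(0, 1))[[1L]]
  # identical copies per class: class means equal those covariances
  model <- mdm_fit(list(e1, e1, e2, e2))
  expect_equal(unclass(model$means[["a"]]),
               unclass(epoch_covariance(e1, model$cov_spec)),
               tolerance = 1e-12)
  # epoch whose covariance equals a class mean -> that class, max score
  pred <- mdm_predict(model, e1)
  expect_equal(pred$class, "a")
  expect_equal(unname(pred$distances["a"]), 0, tolerance = 1e-6)
  expect_gt(pred$scores["a"], max(pred$scores[-1]))
  # permuting epoch order leaves the model unchanged
  model_p <- mdm_fit(list(e2, e1, e2, e1))
  expect_equal(model$means, model_p$means, tolerance = 1e-12)
  # equidistant case: identical class means -> tie to first id, 0.5/0.5
  same <- e1
  same$label <- "b"
  tied <- mdm_fit(list(e1, same))
  p <- mdm_predict(tied, e2)
  expect_equal(p$class, "a")
  expect_equal(unname(p$scores), c(0.5, 0.5))
  expect_error(mdm_fit(list(e1, e1)), "2 classes")
})

test_that("mdm recovers the generating covariances on synthetic sessions", {
  covs <- list(diag(c(4, 1, 1, 1)), diag(c(1, 4, 1, 1)))
  cfg <- quiet_cfg(seed = 17, n_channels = 4)
  ses <- make_mi_session(40, covs, cfg, epoch_duration = 2)
  eps <- epoch_timelocked(ses$eeg, ses$markers, epoch_spec(0, 2))
  model <- mdm_fit(eps, cov_spec(shrinkage = 0.01))
  for (k in 1:2) {
    expect_lte(airm_distance(model$means[[as.character(k)]], covs[[k]]),
               0.3)
  }
})

test_that("accuracy is non-decreasing in the class separation", {
  seps <- c(1, 2, 4)  # variance ratio on the discriminating channel
  accs <- vapply(seps, function(s) {
    covs <- list(diag(c(s, 1, 1, 1)), diag(c(1, s, 1, 1)))
    cfg <- quiet_cfg(seed = 29, n_channels = 4)
    ses <- make_mi_session(30, covs, cfg, epoch_duration = 2)
    eps <- epoch_timelocked(ses$eeg, ses$markers, epoch_spec(0, 2))
    train <- eps[1:30]
    test <- eps[31:60]
    mdm_accuracy(mdm_fit(train), test)
  }, numeric(1))
  deltas <- vapply(seps, function(s) {
    airm_distance(diag(c(s, 1, 1, 1)), diag(c(1, s, 1, 1)))
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
  expect_true(all(diff(accs) >= 0))
})

test_that("model persistence is bit-exact and failure-atomic", {
  cfg <- quiet_cfg(seed = 23, n_channels = 3)
  ses <- make_mi_session(6, NULL, quiet_cfg(seed = 23, n_channels = 2))
  eps <- epoch_timelocked(ses$eeg, ses$markers, epoch_spec(0, 2))
  model <- mdm_fit(eps)
  path <- withr::local_tempfile(fileext = ".mdm.json")
  bundle <- model_bundle(model)
  save_model(bundle, path)
  loaded <- load_model(path)
  expect_identical(loaded$digest, bundle$digest)
  # bit-identical predictions on random epochs
  withr::with_seed(31, {
    for (rep in 1:100) {
      x <- matrix(rnorm(2 * 64), nrow = 2)
      expect_identical(mdm_predict(model, x),
                       mdm_predict(loaded$model, x))
    }
  })
  # truncated file: format error, no partial model
  raw <- readLines(path)
  half <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(raw, collapse = ""), 1, 100), half)
  expect_error(load_model(half), "corrupt|format")
  # digest changes iff the parameters change
  model2 <- mdm_fit(eps)  # same data, same fit
  expect_identical(model_digest(model2), model_digest(model))
  ses3 <- make_mi_session(6, NULL, quiet_cfg(seed = 24, n_channels = 2))
  eps3 <- epoch_timelocked(ses3$eeg, ses3$markers, epoch_spec(0, 2))
  model3 <- mdm_fit(eps3)
  expect_false(identical(model_digest(model3), model_digest(model)))
  # version mismatch
  doc <- jsonlite::read_json(path)
  doc$version <- "99"
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(bad), "version")
})
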