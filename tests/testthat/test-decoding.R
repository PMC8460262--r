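test_that("PCA: noise-free recovery, variance ratios, sign convention", {
  nf <- noisefree_cohort()
  basis <- fit_pca(nf$trials, n_components = 3)
  truth <- nf$ground_truth$atlas$maps[1, ]
  expect_gte(abs(cor(basis$spatial_components[1, ], truth)), 0.999)
  evr <- basis$explained_variance_ratio
  expect_lte(sum(evr), 1 + 1e-9)
  expect_true(all(diff(evr) <= 1e-12))
  for (j in 1:3) {
    v <- basis$spatial_components[j, ]
    expect_gte(v[which.max(abs(v))], 0)
  }
  # orthonormal rows
  G <- basis$spatial_components %*% t(basis$spatial_components)
  expect_equal(G, diag(3), tolerance = 1e-6)
  expect_error(fit_pca(nf$trials, n_components = 1e5), "exceeds")
})

test_that("projection: training scores, constants flagged, single-component loading", {
  co <- small_cohort()
  basis <- fit_pca(co$trials[1:8], n_components = 10)
  s <- project(co$trials[[1]], basis)
  expect_equal(rowMeans(s$scores), rep(0, 10), tolerance = 1e-9)
  expect_equal(apply(s$scores, 1, sd), rep(1, 10), tolerance = 1e-9)
  # zero-signal trial: all rows constant and flagged
  g <- small_geometry()
  z <- new_trial("z", matrix(0, g$n_voxels, 50), rep(0, 50), 1, g)
  sz <- project(z, basis)
  expect_true(all(sz$constant_rows))
  expect_true(all(sz$scores == 0))
  # data shaped like one basis component loads on that component only
  tc <- sin(2 * pi * 0.03 * (0:99))
  d1 <- new_trial("d1", outer(basis$spatial_components[2, ], tc) +
                    basis$mean_map, tc, 1, g)
  sd1 <- project(d1, basis)
  expect_gte(abs(cor(sd1$scores[2, ], tc)), 0.999)
  other <- setdiff(1:10, 2)
  expect_true(all(sd1$constant_rows[other]))
})

test_that("template prediction: identities and per-frame hand oracle", {
  g <- small_geometry()
  tvals <- rnorm(g$n_voxels)
  template <- new_spatial_map(tvals / max(abs(tvals)), g, "correlation")
  fmri <- cbind(template$values, -template$values,
                matrix(rnorm(g$n_voxels * 3), g$n_voxels, 3))
  tr <- new_trial("t", fmri, rnorm(5), 1, g)
  pred <- template_predict(template, tr)
  expect_equal(pred[1], 1.0, tolerance = 1e-12)
  expect_equal(pred[2], -1.0, tolerance = 1e-12)
  for (f in 3:5) {
    expect_equal(pred[f], oracle_pearson(template$values, fmri[, f]),
                 tolerance = 1e-12)
  }
  expect_true(all(pred >= -1 & pred <= 1))
})

test_that("linear fits: OLS exact recovery, ridge oracle, alpha -> 0 limit", {
  set.seed(6)
  K <- 8; T_ <- 200
  X <- matrix(rnorm(K * T_), K, T_)
  w_true <- c(2, -1, 0.5, 0, 0, 1.5, -0.25, 3)
  y <- as.numeric(w_true %*% X)
  ols <- fit_linear(X, y, variant = "ols")
  expect_lte(max(abs(ols$weights - w_true)), 1e-6)
  # ridge closed form vs an independent SVD-path oracle
  yn <- y + rnorm(T_)
  for (alpha in c(19861, 10)) {
    rid <- fit_linear(X, yn, variant = "ridge", alpha = alpha)
    Xc <- X - rowMeans(X); yc <- yn - mean(yn)
    sv <- svd(t(Xc))
    w_or <- sv$v %*% ((sv$d / (sv$d^2 + alpha)) * crossprod(sv$u, yc))
    expect_lte(max(abs(rid$weights - as.numeric(w_or))), 1e-8)
  }
  rid0 <- fit_linear(X, yn, variant = "ridge", alpha = 1e-10)
  olsn <- fit_linear(X, yn, variant = "ols")
  expect_lte(max(abs(rid0$weights - olsn$weights)), 1e-6)
  # singular system advises ridge
  Xs <- rbind(X, X[1, ])
  expect_error(fit_linear(Xs, yn, variant = "ols"), "ridge")
  # lasso shrinks exact zeros under strong penalty
  las <- fit_linear(X, yn, variant = "lasso", alpha = 50)
  expect_true(any(las$weights == 0))
})

test_that("linear predict equals the w.X + b oracle; one-hot selects a row", {
  set.seed(2)
  X <- matrix(rnorm(5 * 60), 5, 60)
  dec <- structure(list(variant = "ridge", alpha = 0,
                        weights = c(0, 0, 1, 0, 0), intercept = 0),
                   class = "LinearDecoder")
  expect_equal(predict(dec, X), X[3, ])
  dec2 <- structure(list(variant = "ridge", alpha = 0,
                         weights = rnorm(5), intercept = 1.3),
                    class = "LinearDecoder")
  expect_equal(predict(dec2, X),
               as.numeric(dec2$weights %*% X) + 1.3, tolerance = 1e-12)
  expect_error(predict(dec2, X[1:3, ]), "mismatch")
})

test_that("cross-validation: fold sizes, leakage guard, noise-free recovery", {
  g <- small_geometry()
  atlas <- small_atlas()
  # one planted state: a global linear decoder can be exact (with several
  # states the coupling differs per state and no single readout fits all)
  co <- generate_cohort(g, atlas, default_state_profiles()[4], 16,
                        T_frames = 200, noise_sd_fmri = 0,
                        noise_sd_pupil = 0, seed = 51)
  spec <- list(methods = "ridge", n_components = 12, alpha = 1e-6)
  sc <- crossval(co$trials[1:12], spec, n_folds = 4,
                 test_trials = co$trials[13:16], seed = 3)
  cv <- sc[sc$split == "cv", ]
  expect_equal(nrow(cv), 12)
  expect_equal(as.numeric(table(cv$fold)), rep(3, 4))
  expect_gte(mean(cv$r), 0.99)
  expect_gte(mean(sc[sc$split == "test", "r"]), 0.99)
  expect_error(crossval(co$trials[1:12], spec, test_trials = co$trials[12:14]),
               "leakage")
})

test_that("shuffled-pupil null cohort scores near zero", {
  co <- small_cohort()
  trials <- lapply(co$trials[1:12], function(tr) {
    set.seed(match(tr$subject_id, sapply(co$trials, `[[`, "subject_id")))
    new_trial(tr$subject_id, tr$fmri, sample(tr$pupil), tr$tr, tr$geometry)
  })
  sc <- crossval(trials, list(methods = "ridge", n_components = 10,
                              alpha = 19861), n_folds = 4, seed = 7)
  T_ <- ncol(trials[[1]]$fmri)
  expect_lte(mean(abs(sc$r)), 2 / sqrt(T_))
})

test_that("shift zero equals plain crossval", {
  co <- small_cohort()
  spec <- list(methods = "ridge", n_components = 10, alpha = 19861)
  sw <- shift_sweep(co$trials[1:8], shifts = 0, model_spec = spec,
                    n_folds = 2, seed = 5)
  plain <- crossval(co$trials[1:8], spec, n_folds = 2, seed = 5)
  expect_equal(sw$mean_r[1], mean(plain$r), tolerance = 1e-12)
})

test_that("paired comparison: identities, degenerate flag, textbook oracle", {
  s <- c(0.3, 0.5, 0.2, 0.8, 0.4)
  res <- compare_methods(s, s)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  resd <- compare_methods(s + 0.1, s)
  expect_true(resd$degenerate)
  a <- c(0.42, 0.51, 0.38, 0.66, 0.47)
  b <- c(0.31, 0.45, 0.40, 0.52, 0.35)
  res2 <- compare_methods(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res2$t, t_hand, tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_error(compare_methods(a[1:2], b[1:2]), "3 pairs")
})

test_that("no-leakage property: test pupil permutation never changes weights", {
  co <- small_cohort()
  train <- co$trials[1:8]
  test <- co$trials[9:12]
  spec <- list(methods = "ridge", n_components = 8, alpha = 19861)
  models1 <- pupilstate:::fit_decoders(train, spec, seed = 1)
  test_perm <- lapply(test, function(tr) {
    new_trial(tr$subject_id, tr$fmri, rev(tr$pupil), tr$tr, tr$geometry)
  })
  models2 <- pupilstate:::fit_decoders(train, spec, seed = 1)
  expect_identical(models1$ridge$weights, models2$ridge$weights)
  sc1 <- crossval(train, spec, n_folds = 2, test_trials = test, seed = 2)
  sc2 <- crossval(train, spec, n_folds = 2, test_trials = test_perm, seed = 2)
  expect_identical(sc1[sc1$split == "cv", "r"], sc2[sc2$split == "cv", "r"])
})
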