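test_that("the analytic ridge solve degenerates to least squares at alpha = 0", {
  dat <- toy_linear_data()
  dat$fss <- dat$fss + c(scale(rnorm(nrow(dat)))) * 0.3
  fit <- ridge_fit(dat, features = c("x1", "x2", "x3"), alpha = 0,
                   standardize = FALSE)
  ols <- lm(fss ~ x1 + x2 + x3, data = dat)
  expect_equal(unname(fit$beta_raw), unname(coef(ols)[-1]), tolerance = 1e-10)
  expect_equal(fit$beta0_raw, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("the analytic solve matches an independent numerical minimizer", {
  study <- apply_exclusions(load_study(), "subject")
  fit <- ridge_fit(study, alpha = 0.1, standardize = TRUE)
  X <- scale(as.matrix(study[, fit$feature_names]))
  y <- c(scale(study$fss))
  expect_equal(unname(fit$beta), ridge_optim_oracle(X, y, 0.1),
               tolerance = 1e-6)
})

test_that("coefficients vanish under heavy regularization", {
  study <- apply_exclusions(load_study())
  fit <- ridge_fit(study, alpha = 1e6, standardize = TRUE)
  expect_lt(sqrt(sum(fit$beta^2)), 1e-3)
  # and predictions collapse to the training mean response
  expect_equal(predict(fit, study), rep(mean(study$fss), nrow(study)),
               tolerance = 1e-3)
})

test_that("the coefficient norm shrinks monotonically in alpha", {
  study <- apply_exclusions(load_study())
  norms <- sapply(c(0, 0.01, 0.1, 1, 10, 100), function(a) {
    sqrt(sum(ridge_fit(study, alpha = a)$beta^2))
  })
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("singular designs at alpha = 0 point the user to alpha > 0", {
  dat <- toy_linear_data()
  dat$x_dup <- dat$x1
  expect_error(
    ridge_fit(dat, features = c("x1", "x_dup"), alpha = 0,
              standardize = FALSE),
    "alpha > 0"
  )
  expect_error(ridge_fit(dat, features = c("x1", "x2"), alpha = -1), "alpha")
})

test_that("prediction honours the centering identity and input contracts", {
  study <- apply_exclusions(load_study())
  fit <- ridge_fit(study, alpha = 0.1)
  centre <- as.data.frame(as.list(colMeans(study[, fit$feature_names])))
  expect_equal(predict(fit, centre), mean(study$fss), tolerance = 1e-10)
  expect_error(predict(fit, study[, c("cf_ch7", "pse_ch7")]), "lacks")
  expect_error(predict(fit, c(1, 2)), "Expected 3")
})

test_that("standardized fits are equivariant under affine feature rescaling", {
  study <- apply_exclusions(load_study())
  fit <- ridge_fit(study, alpha = 0.1, standardize = TRUE)
  rescaled <- dplyr::mutate(study,
                            cf_ch7 = 10 * .data$cf_ch7 - 3,
                            pse_ch10 = 0.01 * .data$pse_ch10 + 1)
  fit2 <- ridge_fit(rescaled, alpha = 0.1, standardize = TRUE)
  expect_equal(predict(fit2, rescaled), predict(fit, study),
               tolerance = 1e-10)
})

test_that("tidy and glance expose the model in broom style", {
  fit <- ridge_fit(apply_exclusions(load_study()), alpha = 0.1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "estimate_raw"))
  expect_equal(td$term[1], "(Intercept)")
  gl <- glance(fit)
  expect_equal(gl$alpha, 0.1)
  expect_equal(gl$n, 23L)
  expect_equal(gl$p, 3L)
})

test_that("models round-trip through JSON serialization", {
  study <- apply_exclusions(load_study())
  fit <- ridge_fit(study, alpha = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fatigue_model(fit, path)
  back <- read_fatigue_model(path)
  expect_equal(predict(back, study), predict(fit, study), tolerance = 1e-12)
  expect_equal(back$alpha, fit$alpha)
})

test_that("cross-validation recovers a noiseless linear response exactly", {
  dat <- toy_linear_data()
  err <- kfold_cv(dat, features = c("x1", "x2", "x3"), alpha = 0, k = 5,
                  metric = "mse", seed = 1, standardize = FALSE)
  expect_lt(as.numeric(err), 1e-10)
  expect_error(kfold_cv(dat, features = "x1", alpha = 0, k = 50, seed = 1),
               "exceed")
})

test_that("leave-one-out CV matches a brute-force refit loop", {
  dat <- toy_linear_data(n = 5, seed = 9)
  dat$fss <- dat$fss + c(0.3, -0.2, 0.1, 0.4, -0.5)
  n <- nrow(dat)
  got <- kfold_cv(dat, features = c("x1", "x2"), alpha = 0.5, k = n,
                  metric = "mae", seed = 2)
  fold <- {
    set.seed(2L)
    sample(rep(1:n, length.out = n))
  }
  brute <- sapply(1:n, function(f) {
    fit <- ridge_fit(dat[fold != f, ], features = c("x1", "x2"), alpha = 0.5)
    abs(predict(fit, dat[fold == f, ]) - dat$fss[fold == f])
  })
  expect_equal(as.numeric(got), mean(brute), tolerance = 1e-12)
})

test_that("CV is deterministic in the fold seed and requires one", {
  study <- apply_exclusions(load_study())
  e1 <- kfold_cv(study, alpha = 0.1, seed = 10)
  e2 <- kfold_cv(study, alpha = 0.1, seed = 10)
  expect_identical(e1, e2)
  expect_error(kfold_cv(study, alpha = 0.1), "seed")
})

test_that("alpha selection minimizes CV MSE on the grid", {
  study <- apply_exclusions(load_study())
  expect_equal(as.numeric(select_alpha(study, grid = 0.1, seed = 1)), 0.1)
  # pure-noise response: heavy shrinkage should win for most fold shuffles
  wins <- sapply(1:50, function(s) {
    set.seed(1000 + s)
    noise <- dplyr::mutate(study, fss = rnorm(dplyr::n()))
    as.numeric(select_alpha(noise, grid = c(0, 1e6), seed = s)) == 1e6
  })
  expect_gt(mean(wins), 0.5)
})

test_that("out-of-fold predictions align with the CV partition", {
  study <- apply_exclusions(load_study())
  cp <- cv_predictions(study, alpha = 0.1, k = 5, seed = 4)
  expect_equal(nrow(cp), nrow(study))
  expect_equal(cp$actual, study$fss)
  expect_equal(sort(unique(cp$fold)), 1:5)
  # consistency with kfold_cv under the same seed and metric
  err <- mean(sapply(1:5, function(f) {
    mean((cp$predicted[cp$fold == f] - cp$actual[cp$fold == f])^2)
  }))
  expect_equal(err, as.numeric(kfold_cv(study, alpha = 0.1, k = 5,
                                        metric = "mse", seed = 4)),
               tolerance = 1e-12)
})
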