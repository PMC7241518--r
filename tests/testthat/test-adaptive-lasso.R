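# Adaptive LASSO machinery: ridge weights, the penalized solver against
# independent oracles, cross-validated grid search, and prediction.

sim_logistic <- function(n, p, beta, intercept = 0) {
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- rbinom(n, 1, plogis(intercept + X %*% beta))
  list(X = X, y = y)
}

test_that("ridge logistic approaches the MLE as the penalty vanishes", {
  set.seed(21)
  d <- sim_logistic(300, 4, c(1, -0.5, 0.25, 0))
  fit <- fit_ridge_logistic(d$X, d$y, 1e-8, standardize = FALSE)
  mle <- glm(d$y ~ d$X, family = binomial)
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - coef(mle))), 1e-6)
})

test_that("a huge ridge penalty shrinks to the null model", {
  set.seed(22)
  d <- sim_logistic(200, 5, rep(0.5, 5))
  fit <- fit_ridge_logistic(d$X, d$y, 1e8)
  expect_lt(max(abs(fit$coefficients)), 1e-5)
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-4)
})

test_that("duplicated predictors share the ridge coefficient by symmetry", {
  set.seed(23)
  d <- sim_logistic(200, 3, c(1, -0.5, 0.25))
  X2 <- cbind(d$X, dup = d$X[, 1])
  fit <- fit_ridge_logistic(X2, d$y, 5)
  expect_equal(fit$coefficients[["x1"]], fit$coefficients[["dup"]],
               tolerance = 1e-6)
})

test_that("adaptive weights invert clamped magnitudes to the gamma power", {
  expect_equal(adaptive_weights(c(2, 0.5), 1), c(0.5, 2))
  expect_equal(adaptive_weights(c(2, 0.5, -3), 0), c(1, 1, 1))
  expect_equal(adaptive_weights(0, 1), 1e6)
  expect_equal(adaptive_weights(c(-2, 4), 2), c(0.25, 0.0625))
  expect_error(adaptive_weights(1, -1), "gamma")
})

test_that("the penalized solver matches the glmnet objective and limits", {
  set.seed(24)
  for (rep in 1:5) {
    n <- sample(60:200, 1)
    p <- sample(3:10, 1)
    d <- sim_logistic(n, p, rnorm(p, 0, 0.7))
    w <- runif(p, 0.3, 3)
    lam <- runif(1, 0.5, 8)
    fit <- fit_weighted_lasso_logistic(d$X, d$y, lam, w, standardize = FALSE)
    obj <- penalized_nll(d$X, d$y, fit$intercept, fit$coefficients, lam, w)
    lam_g <- lam * sum(w) / (n * p)
    g <- glmnet::glmnet(d$X, d$y, family = "binomial", penalty.factor = w,
                        standardize = FALSE, thresh = 1e-13,
                        lambda = exp(seq(log(lam_g * 50), log(lam_g),
                                         length.out = 25)))
    bg <- as.numeric(glmnet::coef.glmnet(g)[, ncol(g$beta)])
    obj_oracle <- penalized_nll(d$X, d$y, bg[1], bg[-1], lam, w)
    expect_lt((obj - obj_oracle) / abs(obj_oracle), 1e-4)
  }
})

test_that("lambda = 0 reproduces the unpenalized MLE", {
  set.seed(25)
  d <- sim_logistic(150, 4, c(1, -1, 0.5, 0))
  fit <- fit_weighted_lasso_logistic(d$X, d$y, 0, standardize = FALSE)
  mle <- glm(d$y ~ d$X, family = binomial)
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - coef(mle))), 1e-5)
})

test_that("a saturating lambda yields the empty model with exact zeros", {
  set.seed(26)
  d <- sim_logistic(120, 6, rep(0.8, 6))
  fit <- fit_weighted_lasso_logistic(d$X, d$y, 1e6)
  expect_identical(unname(fit$coefficients), rep(0, 6))
  expect_length(fit$retained, 0)
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-5)
})

test_that("zero coefficients are exact zeros at moderate penalties too", {
  set.seed(27)
  d <- sim_logistic(200, 10, c(1.5, -1.5, rep(0, 8)))
  fit <- fit_weighted_lasso_logistic(d$X, d$y, 15)
  dropped <- setdiff(names(fit$coefficients), fit$retained)
  expect_gt(length(dropped), 0)
  expect_true(all(fit$coefficients[dropped] == 0))
})

test_that("gamma = 0 with unit weights reduces to the ordinary LASSO", {
  set.seed(28)
  d <- sim_logistic(150, 6, c(1, -0.8, rep(0, 4)))
  lam <- 3
  w1 <- adaptive_weights(rnorm(6), 0)
  expect_equal(unname(w1), rep(1, 6))
  fit <- fit_weighted_lasso_logistic(d$X, d$y, lam, w1, standardize = FALSE)
  lam_g <- lam * 6 / (150 * 6)
  g <- glmnet::glmnet(d$X, d$y, family = "binomial", standardize = FALSE,
                      thresh = 1e-13,
                      lambda = exp(seq(log(lam_g * 50), log(lam_g),
                                       length.out = 25)))
  bg <- as.numeric(glmnet::coef.glmnet(g)[, ncol(g$beta)])
  expect_equal(unname(c(fit$intercept, fit$coefficients)), bg,
               tolerance = 1e-4)
})

test_that("cross-validation on pure noise selects a near-empty model", {
  set.seed(29)
  d <- sim_logistic(300, 15, rep(0, 15))
  fit <- fit_adaptive_lasso(d$X, d$y,
                            penalty_config(n_lambda = 25, fold_seed = 9))
  expect_lte(length(fit$retained), 3)
})

test_that("a single strong predictor is retained across seeds", {
  set.seed(30)
  hits <- 0
  for (s in 1:5) {
    d <- sim_logistic(400, 10, c(1.5, rep(0, 9)))
    fit <- fit_adaptive_lasso(d$X, d$y,
                              penalty_config(n_lambda = 25, fold_seed = s))
    if ("x1" %in% fit$retained) hits <- hits + 1
  }
  expect_gte(hits, 5 * 0.9)
})

test_that("folds are outcome-stratified and sparse outcomes are caught", {
  y <- c(rep(1, 16), rep(0, 48))
  f <- probuse:::stratified_folds(y, 8, seed = 1)
  expect_true(all(table(f, y) > 0))
  expect_error(probuse:::stratified_folds(c(rep(1, 3), rep(0, 60)), 8, 1),
               "single outcome class")
})

test_that("risk prediction is a logistic score with schema checking", {
  set.seed(31)
  d <- sim_logistic(200, 5, c(1, -1, 0.5, 0, 0))
  fit <- fit_weighted_lasso_logistic(d$X, d$y, 2)
  # all-zero row scores the intercept
  z <- matrix(0, 1, 5, dimnames = list("new", paste0("x", 1:5)))
  expect_equal(unname(predict_risk(fit, z)), plogis(fit$intercept))
  # missing column is a schema error naming the column
  expect_error(predict_risk(fit, z[, -2, drop = FALSE]), "x2")
  # monotone in positively weighted predictors
  up <- names(which(fit$coefficients > 0))[1]
  if (!is.na(up)) {
    base <- predict_risk(fit, z)
    z2 <- z; z2[, up] <- 5
    expect_gt(predict_risk(fit, z2), base)
  }
  # scores are probabilities
  s <- predict_risk(fit, d$X)
  expect_true(all(s > 0 & s < 1))
})
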