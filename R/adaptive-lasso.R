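#' Penalty configuration for the adaptive LASSO
#'
#' Controls the ridge step used to derive adaptive penalty weights, the
#' (gamma, lambda) search grids, and the cross-validation design. Gamma is
#' the exponent applied to the inverse ridge coefficient magnitudes (how
#' strongly initial associations steer the penalty); lambda scales overall
#' sparsity. The lambda grid is laid out per gamma as `n_lambda` log-spaced
#' points from `lambda_max` (the smallest lambda zeroing every coefficient)
#' down by `lambda_min_ratio`.
#'
#' @param ridge_penalty L2 penalty for the weight-estimation ridge fit, on
#'   the summed-log-likelihood scale.
#' @param gamma_grid positive exponents to search.
#' @param n_lambda,lambda_min_ratio lambda grid resolution and depth.
#' @param n_folds cross-validation folds (default 8; folds are stratified by
#'   outcome so each contains events).
#' @param standardize standardize columns to unit variance before
#'   penalization (coefficients are reported on the original scale).
#' @param tol optimizer tolerance (coefficient scale).
#' @param max_iter maximum IRLS iterations.
#' @param weight_floor ridge magnitudes below this are clamped before
#'   inversion, so weights stay finite.
#' @param fold_seed optional seed for fold assignment.
#' @return object of class `penalty_config`.
#' @export
penalty_config <- function(ridge_penalty = 10, gamma_grid = c(0.5, 1, 2),
                           n_lambda = 50, lambda_min_ratio = 1e-4,
                           n_folds = 8, standardize = TRUE, tol = 1e-7,
                           max_iter = 250, weight_floor = 1e-6,
                           fold_seed = NULL) {
  if (length(gamma_grid) == 0 || any(gamma_grid < 0))
    stop("penalty_config: gamma_grid must be non-empty and >= 0", call. = FALSE)
  if (n_folds < 2) stop("penalty_config: n_folds must be >= 2", call. = FALSE)
  if (tol <= 0) stop("penalty_config: tol must be > 0", call. = FALSE)
  if (n_lambda < 1 || lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("penalty_config: invalid lambda grid", call. = FALSE)
  structure(list(ridge_penalty = ridge_penalty, gamma_grid = gamma_grid,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 n_folds = n_folds, standardize = standardize, tol = tol,
                 max_iter = max_iter, weight_floor = weight_floor,
                 fold_seed = fold_seed),
            class = "penalty_config")
}

standardize_cols <- function(X) {
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2))
  scale[scale < 1e-12] <- 1
  list(X = sweep(Xc, 2, scale, "/"), center = center, scale = scale)
}

#' Ridge (L2-penalized) logistic regression
#'
#' Fits logistic regression minimizing
#' `sum_i -loglik_i + ridge_penalty * sum_j beta_j^2` by penalized IRLS
#' (Newton) with an unpenalized intercept. Used to obtain the initial
#' coefficient magnitudes for the adaptive penalty weights; with many
#' predictors relative to sample size the ridge fit is well defined where
#' the MLE is not.
#'
#' @param X numeric predictor matrix.
#' @param y binary (0/1 or logical) outcome.
#' @param ridge_penalty L2 penalty (applies on the standardized scale when
#'   `standardize = TRUE`).
#' @param standardize standardize columns first; coefficients are returned
#'   on the original scale either way.
#' @param tol,max_iter convergence control.
#' @return list of class `ridge_logistic`: `intercept`, `coefficients`
#'   (original scale), `std_coefficients` (penalized scale, the input to
#'   [adaptive_weights()]), `iterations`, `converged`.
#' @export
fit_ridge_logistic <- function(X, y, ridge_penalty, standardize = TRUE,
                               tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  std <- if (standardize) standardize_cols(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- cbind(1, std$X)
  p <- ncol(X)
  pen <- c(0, rep(ridge_penalty, p))
  coef <- c(qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)), rep(0, p))
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(Xs %*% coef)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    H <- crossprod(Xs, Xs * w) + 2 * diag(pen)
    coef_new <- solve(H, crossprod(Xs, w * z))
    delta <- max(abs(coef_new - coef))
    coef <- drop(coef_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("fit_ridge_logistic: IRLS did not converge in ", max_iter,
         " iterations (last max coefficient change ",
         signif(delta, 3), ")", call. = FALSE)
  beta_std <- unname(coef[-1])
  beta <- beta_std / std$scale
  intercept <- unname(coef[1]) - sum(beta * std$center)
  structure(list(intercept = intercept,
                 coefficients = stats::setNames(beta, colnames(X)),
                 std_coefficients = stats::setNames(beta_std, colnames(X)),
                 ridge_penalty = ridge_penalty, iterations = it,
                 converged = converged),
            class = "ridge_logistic")
}

#' Adaptive penalty weights from ridge coefficients
#'
#' `w_j = 1 / |beta_j|^gamma`, with magnitudes below `floor` clamped to
#' `floor` before inversion so weights stay finite. `gamma = 0` gives unit
#' weights (ordinary LASSO).
#'
#' @param ridge_coefficients coefficient vector (standardized scale).
#' @param gamma non-negative exponent.
#' @param floor clamping constant (default 1e-6).
#' @return positive weight per coefficient.
#' @export
adaptive_weights <- function(ridge_coefficients, gamma, floor = 1e-6) {
  if (gamma < 0) stop("adaptive_weights: gamma must be >= 0", call. = FALSE)
  1 / pmax(abs(ridge_coefficients), floor)^gamma
}

# Internal: fit the weighted-penalty lasso path on (optionally standardized)
# X and return original-scale intercepts/coefficients at each lambda.
lasso_path <- function(X, y, lambda_seq, weights, standardize = TRUE,
                       tol = 1e-7, max_iter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  std <- if (standardize) standardize_cols(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  res <- .cd_lasso_path(std$X, y, lambda_seq, weights, tol, max_iter, 1000L)
  beta <- res$beta / std$scale          # exact zeros divide to exact zeros
  intercept <- res$intercept - drop(crossprod(std$center, beta))
  rownames(beta) <- colnames(X)
  list(intercept = intercept, beta = beta, lambda = lambda_seq,
       outer_iters = res$outer_iters, converged = res$converged)
}

lambda_max_value <- function(Xstd, y, weights) {
  g <- abs(drop(crossprod(Xstd, y - mean(y))))
  finite <- is.finite(weights) & weights > 0
  max(g[finite] / weights[finite]) * 1.000001
}

#' Weighted-penalty LASSO logistic regression
#'
#' Minimizes `sum_i -loglik_i + lambda * sum_j w_j |beta_j|` with an
#' unpenalized intercept, by IRLS with cyclic coordinate descent and
#' soft-thresholding (compiled path solver, warm-started from `lambda_max`
#' down to the requested `lambda`). Zero coefficients are exact zeros.
#'
#' @param X numeric predictor matrix.
#' @param y binary outcome.
#' @param lambda non-negative penalty scale.
#' @param weights positive per-coefficient penalty weights (default 1:
#'   ordinary LASSO); interpreted on the standardized scale when
#'   `standardize = TRUE`.
#' @param standardize standardize before penalization (default TRUE);
#'   coefficients return on the original scale.
#' @param tol,max_iter convergence control.
#' @return object of class `adlasso_fit`: `intercept`, `coefficients`
#'   (named, exact zeros), `weights`, `lambda`, `gamma` (NA here),
#'   `retained` (names of nonzero coefficients), `iterations`, `converged`.
#' @export
fit_weighted_lasso_logistic <- function(X, y, lambda, weights = NULL,
                                        standardize = TRUE, tol = 1e-7,
                                        max_iter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, ncol(X))
  if (any(weights <= 0)) stop("penalty weights must be > 0", call. = FALSE)
  std <- if (standardize) standardize_cols(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  lam_max <- lambda_max_value(std$X, y, weights)
  lambda_seq <- if (lambda >= lam_max) lambda else
    unique(c(exp(seq(log(lam_max), log(max(lambda, lam_max * 1e-6)),
                     length.out = 15)), lambda))
  path <- lasso_path(X, y, lambda_seq, weights, standardize = standardize,
                     tol = tol, max_iter = max_iter)
  k <- length(lambda_seq)
  if (!path$converged[k])
    stop("fit_weighted_lasso_logistic: coordinate descent did not converge; ",
         "try increasing max_iter or tol", call. = FALSE)
  beta <- stats::setNames(path$beta[, k], colnames(X))
  structure(list(intercept = path$intercept[k], coefficients = beta,
                 weights = stats::setNames(weights, colnames(X)),
                 lambda = lambda, gamma = NA_real_,
                 retained = names(beta)[beta != 0],
                 iterations = path$outer_iters[k],
                 converged = path$converged[k]),
            class = "adlasso_fit")
}

#' @export
print.adlasso_fit <- function(x, ...) {
  cat("<adlasso_fit> lambda =", signif(x$lambda, 4),
      if (!is.na(x$gamma)) paste("gamma =", x$gamma) else "",
      "| retained", length(x$retained), "of", length(x$coefficients),
      "predictors\n")
  invisible(x)
}

#' Penalized negative log-likelihood of a fit
#'
#' The objective value `sum_i [log(1 + exp(eta_i)) - y_i eta_i] +
#' lambda * sum_j w_j |beta_j|` for given coefficients on the scale of the
#' supplied `X`. Used to verify the solver against independent convex
#' optimizers.
#'
#' @param X,y data (same scale the coefficients refer to).
#' @param intercept,beta coefficients.
#' @param lambda,weights penalty.
#' @return numeric scalar.
#' @export
penalized_nll <- function(X, y, intercept, beta, lambda, weights) {
  eta <- drop(intercept + as.matrix(X) %*% beta)
  nll <- sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  nll + lambda * sum(weights * abs(beta))
}

# Outcome-stratified fold assignment.
stratified_folds <- function(y, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  tab <- table(folds, y)
  if (any(tab == 0))
    stop("cv_grid_search: a fold contains a single outcome class; ",
         "use fewer folds or more events per class", call. = FALSE)
  folds
}

#' Cross-validated (gamma, lambda) grid search
#'
#' For every gamma in the grid, adaptive weights are derived from a ridge
#' fit; the lambda grid descends log-spaced from the smallest lambda that
#' zeroes every coefficient. Model fit at each grid point is scored by
#' k-fold cross-validation with the held-out sum of squares
#' `sum_i (y_i - yhat_i)^2`, where `yhat_i` is the predicted probability for
#' a left-out observation from the model estimated on the remaining folds;
#' adaptive weights are re-estimated inside each training fold, so the
#' held-out data never leaks into the weights. The minimizing pair is
#' returned, with ties broken toward larger lambda (sparser), then smaller
#' gamma.
#'
#' @param X,y training data (y binary).
#' @param config a [penalty_config()].
#' @return list of class `cv_adlasso`: `gamma`, `lambda`, `cv_loss` (matrix
#'   gamma x lambda index), `lambda_grids` (per gamma), `folds`, `config`.
#' @export
cv_grid_search <- function(X, y, config = penalty_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  folds <- stratified_folds(y, config$n_folds, config$fold_seed)

  ridge_full <- fit_ridge_logistic(X, y, config$ridge_penalty,
                                   standardize = config$standardize,
                                   max_iter = config$max_iter)
  std_full <- standardize_cols(X)
  gammas <- config$gamma_grid
  lambda_grids <- lapply(gammas, function(g) {
    w <- adaptive_weights(ridge_full$std_coefficients, g, config$weight_floor)
    lmax <- lambda_max_value(std_full$X, y, w)
    exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
            length.out = config$n_lambda))
  })

  loss <- matrix(0, nrow = length(gammas), ncol = config$n_lambda,
                 dimnames = list(paste0("gamma", gammas), NULL))
  for (k in seq_len(config$n_folds)) {
    tr <- folds != k
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    Xval <- X[!tr, , drop = FALSE]
    yval <- y[!tr]
    ridge_k <- fit_ridge_logistic(Xtr, ytr, config$ridge_penalty,
                                  standardize = config$standardize,
                                  max_iter = config$max_iter)
    for (gi in seq_along(gammas)) {
      w <- adaptive_weights(ridge_k$std_coefficients, gammas[gi],
                            config$weight_floor)
      path <- lasso_path(Xtr, ytr, lambda_grids[[gi]], w,
                         standardize = config$standardize, tol = config$tol,
                         max_iter = config$max_iter)
      eta <- sweep(Xval %*% path$beta, 2, path$intercept, "+")
      P <- plogis(eta)
      loss[gi, ] <- loss[gi, ] + colSums((yval - P)^2)
    }
  }
  # minimize; ties -> larger lambda, then smaller gamma
  best <- which(loss <= min(loss) + 1e-12, arr.ind = TRUE)
  best_lambda <- vapply(seq_len(nrow(best)), function(r)
    lambda_grids[[best[r, 1]]][best[r, 2]], numeric(1))
  ord <- order(-best_lambda, gammas[best[, 1]])
  pick <- best[ord[1], ]
  structure(list(gamma = gammas[pick[1]],
                 lambda = lambda_grids[[pick[1]]][pick[2]],
                 cv_loss = loss, lambda_grids = lambda_grids,
                 gamma_grid = gammas, folds = folds, config = config,
                 ridge = ridge_full),
            class = "cv_adlasso")
}

#' Fit the adaptive LASSO with cross-validated (gamma, lambda)
#'
#' Full pipeline: [cv_grid_search()] selects (gamma, lambda); adaptive
#' weights are re-derived from the ridge fit on all training data at the
#' chosen gamma; the final weighted LASSO refit on all training data gives
#' the classification model whose fitted probability is the patient risk
#' score.
#'
#' @param X,y training data.
#' @param config a [penalty_config()].
#' @return an `adlasso_fit` with `gamma` set and the `cv_adlasso` object
#'   attached as `$cv`.
#' @export
fit_adaptive_lasso <- function(X, y, config = penalty_config()) {
  cv <- cv_grid_search(X, y, config)
  w <- adaptive_weights(cv$ridge$std_coefficients, cv$gamma,
                        config$weight_floor)
  fit <- fit_weighted_lasso_logistic(X, y, cv$lambda, w,
                                     standardize = config$standardize,
                                     tol = config$tol,
                                     max_iter = config$max_iter)
  fit$gamma <- cv$gamma
  fit$cv <- cv
  fit$ridge <- cv$ridge
  fit
}

#' Predict risk scores
#'
#' Applies the fitted model to new rows: the risk score is the fitted
#' probability `plogis(intercept + X beta)`.
#'
#' @param fit an `adlasso_fit`.
#' @param X_new matrix or data.frame whose columns include every predictor
#'   of the fit (matched by name).
#' @return numeric vector of probabilities, named by rownames of `X_new`.
#' @export
predict_risk <- function(fit, X_new) {
  stopifnot(inherits(fit, "adlasso_fit"))
  X_new <- as.matrix(X_new)
  need <- names(fit$coefficients)
  missing <- setdiff(need, colnames(X_new))
  if (length(missing) > 0)
    stop("predict_risk: missing predictor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  eta <- drop(fit$intercept + X_new[, need, drop = FALSE] %*% fit$coefficients)
  stats::setNames(plogis(eta), rownames(X_new))
}
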