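#' Elastic-net / LASSO regression by cyclic coordinate descent
#'
#' Minimizes the Gaussian-family objective
#' \deqn{\frac{1}{2N}\sum_i (y_i - \beta_0 - x_i^T\beta)^2 +
#'   \lambda\left[(1-\alpha)\|\beta\|_2^2/2 + \alpha\|\beta\|_1\right]}
#' with `alpha = 1` (pure LASSO) by default. Predictors are standardized
#' internally (mean 0, 1/N-variance 1) and the response centred; returned
#' coefficients are mapped back to the original feature scale, so
#' prediction is invariant to the standardization round-trip. When `lambda`
#' is `NULL` it is chosen by seeded K-fold cross-validation over a
#' log-spaced path from `lambda_max` (the smallest penalty with an all-zero
#' solution) downward, minimizing mean CV squared error (`rule = "min"`) or
#' using the one-standard-error rule (`rule = "1se"`).
#'
#' The solution is verified against the subgradient stationarity (KKT)
#' conditions; the attained residual is stored as `kkt_residual`.
#'
#' @param x data frame / matrix of features (samples x features).
#' @param y numeric response.
#' @param lambda penalty; `NULL` (default) selects by cross-validation.
#' @param alpha elastic-net mixing in `[0, 1]` (1 = LASSO).
#' @param cv_folds number of CV folds (default 10).
#' @param seed integer seed for the CV fold assignment.
#' @param rule `"min"` or `"1se"` for the CV lambda choice.
#' @param n_lambda,lambda_min_ratio path resolution for CV.
#' @param tol coordinate-descent convergence tolerance on the standardized
#'   coefficients (default 1e-9, giving KKT residuals well below 1e-6).
#' @param max_iter sweep cap; exceeding it is an error.
#' @return an object of class `lasso_model`.
#' @export
lasso_fit <- function(x, y, lambda = NULL, alpha = 1, cv_folds = 10,
                      seed = 1, rule = c("min", "1se"), n_lambda = 100,
                      lambda_min_ratio = 1e-4, tol = 1e-9, max_iter = 1e5) {
  rule <- match.arg(rule)
  xm <- as.matrix(as.data.frame(x))
  storage.mode(xm) <- "double"
  n <- nrow(xm)
  stopifnot(n == length(y), alpha >= 0, alpha <= 1)
  std <- standardize_x(xm)
  ybar <- mean(y)
  yc <- y - ybar
  cv <- NULL
  if (is.null(lambda)) {
    stopifnot(n >= cv_folds, cv_folds >= 2)
    cv <- cv_lambda_path(std$xs, yc, alpha, cv_folds, seed, rule,
                         n_lambda, lambda_min_ratio, tol, max_iter)
    lambda <- cv$lambda
  }
  fit <- cd_enet(std$xs, yc, lambda, alpha, tol, max_iter)
  beta_orig <- ifelse(std$scale > 0, fit$beta / std$scale, 0)
  intercept <- ybar - sum(beta_orig * std$center)
  structure(
    list(
      coefficients = setNames(beta_orig, colnames(xm)),
      intercept = intercept, intercept_known = TRUE,
      lambda = lambda, alpha = alpha,
      standardization = list(center = std$center, scale = std$scale),
      kkt_residual = fit$kkt, n_sweeps = fit$sweeps, n = n, p = ncol(xm),
      cv = cv
    ),
    class = "lasso_model"
  )
}

standardize_x <- function(xm) {
  center <- colMeans(xm)
  xs <- sweep(xm, 2, center)
  scale <- sqrt(colMeans(xs^2)) # 1/N variance, glmnet convention
  pos <- scale > 0
  xs[, pos] <- sweep(xs[, pos, drop = FALSE], 2, scale[pos], "/")
  xs[, !pos] <- 0
  list(xs = xs, center = center, scale = scale)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# cyclic coordinate descent on standardized x, centred y; covariance
# (Gram) updates make each coordinate O(p), and `beta` warm-starts the
# solve along a penalty path. gram/xty may be supplied precomputed.
cd_enet <- function(xs, yc, lambda, alpha, tol, max_iter,
                    beta = numeric(ncol(xs)), gram = NULL, xty = NULL) {
  n <- nrow(xs)
  p <- ncol(xs)
  if (is.null(gram)) gram <- crossprod(xs) / n
  if (is.null(xty)) xty <- drop(crossprod(xs, yc)) / n
  gb <- drop(gram %*% beta)
  ggj <- diag(gram) # ~1 for standardized columns, 0 for constant ones
  denom <- ggj + lambda * (1 - alpha)
  thr <- lambda * alpha
  usable <- which(ggj >= 1e-12)
  sweep_once <- function(idx) {
    delta <- 0
    for (j in idx) {
      bj <- beta[j]
      zj <- xty[j] - gb[j] + bj * ggj[j]
      az <- abs(zj) - thr
      bj_new <- if (az > 0) sign(zj) * az / denom[j] else 0
      if (bj_new != bj) {
        gb <<- gb + gram[, j] * (bj_new - bj)
        d <- abs(bj_new - bj)
        if (d > delta) delta <- d
        beta[j] <<- bj_new
      }
    }
    delta
  }
  sweep_i <- 0
  delta <- Inf
  while (sweep_i < max_iter) {
    sweep_i <- sweep_i + 1
    delta <- sweep_once(usable)
    if (delta < tol) break
    # iterate on the active set until stable, then re-check all coordinates
    active <- usable[beta[usable] != 0]
    while (sweep_i < max_iter && length(active)) {
      sweep_i <- sweep_i + 1
      if (sweep_once(active) < tol) break
    }
  }
  if (sweep_i == max_iter && delta >= tol) {
    r <- yc - xs %*% beta
    obj <- sum(r^2) / (2 * n) +
      lambda * ((1 - alpha) * sum(beta^2) / 2 + alpha * sum(abs(beta)))
    stop(sprintf("coordinate descent did not converge (objective %.6g)", obj),
         call. = FALSE)
  }
  list(beta = beta, kkt = kkt_residual(xs, yc, beta, lambda, alpha),
       sweeps = sweep_i)
}

#' KKT (stationarity) residual of an elastic-net solution
#'
#' For active coordinates the gradient condition must vanish; for inactive
#' ones the absolute gradient must not exceed `lambda * alpha`. Returns the
#' largest violation.
#'
#' @param xs standardized design, `yc` centred response, `beta` standardized
#'   coefficients.
#' @param yc,beta,lambda,alpha see [lasso_fit()].
#' @export
kkt_residual <- function(xs, yc, beta, lambda, alpha) {
  n <- nrow(xs)
  r <- yc - xs %*% beta
  g <- crossprod(xs, r) / n - lambda * (1 - alpha) * beta
  active <- beta != 0
  viol_active <- if (any(active)) {
    max(abs(g[active] - lambda * alpha * sign(beta[active])))
  } else 0
  viol_inactive <- if (any(!active)) {
    max(pmax(abs(g[!active]) - lambda * alpha, 0))
  } else 0
  max(viol_active, viol_inactive)
}

cv_lambda_path <- function(xs, yc, alpha, k, seed, rule,
                           n_lambda, lambda_min_ratio, tol, max_iter) {
  n <- nrow(xs)
  lambda_max <- max(abs(crossprod(xs, yc)) / n) / max(alpha, 1e-3)
  if (lambda_max <= 0) lambda_max <- 1
  path <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = n_lambda))
  folds <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sample(rep_len(seq_len(k), n))
  })
  errs <- matrix(NA_real_, k, n_lambda)
  for (f in seq_len(k)) {
    tr <- folds != f
    xtr <- xs[tr, , drop = FALSE]
    ytr <- yc[tr]
    gram <- crossprod(xtr) / sum(tr)
    xty <- drop(crossprod(xtr, ytr)) / sum(tr)
    beta <- numeric(ncol(xs))
    for (li in seq_along(path)) {
      fit <- cd_enet(xtr, ytr, path[li], alpha, tol, max_iter,
                     beta = beta, gram = gram, xty = xty)
      beta <- fit$beta
      pred <- xs[!tr, , drop = FALSE] %*% fit$beta
      errs[f, li] <- mean((yc[!tr] - pred)^2)
    }
  }
  mean_err <- colMeans(errs)
  se_err <- apply(errs, 2, sd) / sqrt(k)
  i_min <- which.min(mean_err)
  i_sel <- if (rule == "min") i_min else {
    which(mean_err <= mean_err[i_min] + se_err[i_min])[1]
  }
  list(lambda = path[i_sel], path = path, mean_cv_error = mean_err,
       se_cv_error = se_err, rule = rule, folds = k)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.lasso_model <- function(x, ...) {
  nz <- x$coefficients[x$coefficients != 0]
  cat(sprintf(
    "LASSO model: %d/%d non-zero features, lambda = %.4g, alpha = %g\n",
    length(nz), x$p, x$lambda, x$alpha
  ))
  if (length(nz)) print(nz)
  if (!isTRUE(x$intercept_known)) cat("(intercept unknown: scores are up to a constant)\n")
  invisible(x)
}

#' Predict from a fitted or published LASSO model
#'
#' @param object a `lasso_model`.
#' @param newdata data frame containing all model feature columns.
#' @param ... unused.
#' @return numeric vector of linear scores. When the model's intercept is
#'   unknown (published two-feature model) the score omits it; every
#'   downstream analysis shipped here (median grouping, rank correlation,
#'   Cox on the score) is invariant to that additive constant.
#' @export
predict.lasso_model <- function(object, newdata, ...) {
  needed <- names(object$coefficients)[object$coefficients != 0]
  missing_f <- setdiff(needed, names(newdata))
  if (length(missing_f)) {
    stop("missing model feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  xm <- as.matrix(as.data.frame(newdata)[, names(object$coefficients)[
    object$coefficients != 0], drop = FALSE])
  score <- drop(xm %*% object$coefficients[object$coefficients != 0])
  if (isTRUE(object$intercept_known)) score <- score + object$intercept
  unname(score)
}

#' @rdname lasso_fit
#' @param x a `lasso_model` (for `tidy`/`glance`).
#' @param ... unused.
#' @export
tidy.lasso_model <- function(x, ...) {
  tibble::tibble(
    term = c(if (isTRUE(x$intercept_known)) "(Intercept)", names(x$coefficients)),
    estimate = c(if (isTRUE(x$intercept_known)) x$intercept, unname(x$coefficients))
  )
}

#' @rdname lasso_fit
#' @export
glance.lasso_model <- function(x, ...) {
  tibble::tibble(
    n = x$n %||% NA_integer_, p = x$p %||% NA_integer_,
    n_nonzero = sum(x$coefficients != 0),
    lambda = x$lambda %||% NA_real_, alpha = x$alpha,
    kkt_residual = x$kkt_residual %||% NA_real_
  )
}
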