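#' Multiple linear regression calibration
#'
#' Ordinary least squares of SPAD on the selected bands, with intercept,
#' solved by QR factorization. Requires more samples than coefficients and a
#' full-column-rank design; collinear bands are reported by name.
#'
#' @param X Sample-by-band numeric matrix (band names taken from columns).
#' @param y SPAD vector.
#' @return An object of class `c("mlr_model", "spad_model")` with elements
#'   `coefficients` (per band), `intercept`, `band_names`, `n_obs`, and the
#'   training fit (`fitted`, `train_score`).
#' @seealso [plsr_fit()], [predict.spad_model()], [score()]
#' @export
mlr_fit <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (nrow(X) != length(y)) abort("`X` and `y` sizes differ.")
  if (nrow(X) <= p + 1) {
    abort("MLR needs more samples than bands + 1.")
  }
  bands <- colnames(X)
  if (is.null(bands)) bands <- paste0("b", seq_len(p))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    bad <- bands[which(is.na(beta[-1]))]
    abort(paste0("Design is rank deficient; collinear band(s): ",
                 paste(bad, collapse = ", "), "."))
  }
  fitted <- as.vector(cbind(1, X) %*% beta)
  structure(list(
    kind = "mlr",
    coefficients = setNames(beta[-1], bands),
    intercept = unname(beta[1]),
    band_names = bands,
    n_obs = length(y),
    fitted = fitted,
    train_score = score(y, fitted)
  ), class = c("mlr_model", "spad_model"))
}

#' Partial least squares regression calibration
#'
#' PLS1 by NIPALS: components are extracted iteratively, each maximizing the
#' covariance between the X-scores and the (centred) response, with rank-one
#' deflation of X after every component. Predictors and response are
#' mean-centred; no variance scaling by default, since post-derivative bands
#' are already commensurate (set `scale = TRUE` to autoscale).
#'
#' @param X Sample-by-band numeric matrix.
#' @param y SPAD vector; must not be constant.
#' @param n_components Number of latent components, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param scale Autoscale columns of `X` to unit variance?
#' @return An object of class `c("plsr_model", "spad_model")` carrying the
#'   regression vector in original units plus the weight/loading/score
#'   matrices (`W`, `P`, `T`).
#' @export
plsr_fit <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) abort("`X` and `y` sizes differ.")
  if (sd(y) == 0) abort("`y` has zero variance; PLSR is undefined.")
  if (n_components < 1 || n_components > min(n - 1, p)) {
    abort("`n_components` must lie in 1..min(nrow(X) - 1, ncol(X)).")
  }
  bands <- colnames(X)
  if (is.null(bands)) bands <- paste0("b", seq_len(p))

  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, sd) else rep(1, p)
  if (any(x_scale == 0)) abort("Zero-variance band cannot be autoscaled.")
  y_center <- mean(y)
  E <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  f <- y - y_center

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # response fully deflated; later components are null
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      break
    }
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    pvec <- crossprod(E, t) / tt
    q[a] <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - q[a] * t
    W[, a] <- w
    P[, a] <- pvec
    Tm[, a] <- t
  }
  # beta in centred/scaled space: W (P'W)^-1 q
  beta_cs <- W %*% solve(crossprod(P, W), q[seq_len(ncol(W))])
  coefficients <- as.vector(beta_cs) / x_scale
  intercept <- y_center - sum(x_center * coefficients)
  fitted <- as.vector(X %*% coefficients + intercept)
  structure(list(
    kind = "plsr",
    coefficients = setNames(coefficients, bands),
    intercept = intercept,
    n_components = ncol(W),
    band_names = bands,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    W = W, P = P, T = Tm, q = q[seq_len(ncol(W))],
    n_obs = n,
    fitted = fitted,
    train_score = score(y, fitted)
  ), class = c("plsr_model", "spad_model"))
}

#' Choose the PLSR component count by validation RMSE
#'
#' Fits PLSR for every allowed component count up to `max_components` and
#' scores each on the validation set.
#'
#' @inheritParams plsr_fit
#' @param X_val,y_val Validation set.
#' @param max_components Upper cap (default 10).
#' @return A list with `n_components` (the RMSE-minimizing count; ties go to
#'   fewer components), `model` (the refitted winner) and `path`, a tibble of
#'   (`n_components`, `rmse`).
#' @export
select_plsr_components <- function(X, y, X_val, y_val, max_components = 10,
                                   scale = FALSE) {
  kmax <- min(max_components, nrow(X) - 1, ncol(X))
  rmse <- vapply(seq_len(kmax), function(k) {
    m <- plsr_fit(X, y, k, scale = scale)
    score(y_val, predict(m, X_val))$rmse
  }, numeric(1))
  best <- which.min(rmse)
  list(
    n_components = best,
    model = plsr_fit(X, y, best, scale = scale),
    path = tibble::tibble(n_components = seq_len(kmax), rmse = rmse)
  )
}

#' Predict SPAD from a fitted calibration model
#'
#' @param object An `mlr_model` or `plsr_model`.
#' @param newdata Matrix (or data frame) whose columns match the bands the
#'   model was fitted on.
#' @param ... Unused.
#' @return Numeric vector of predicted SPAD.
#' @export
predict.spad_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    abort(sprintf("`newdata` has %d columns; model uses %d bands.",
                  ncol(X), length(object$coefficients)))
  }
  as.vector(X %*% object$coefficients + object$intercept)
}

#' @export
print.spad_model <- function(x, ...) {
  cat(sprintf("<%s calibration: %d bands%s, n = %d, train R2 = %.3f>\n",
              toupper(x$kind), length(x$coefficients),
              if (x$kind == "plsr") sprintf(", %d components", x$n_components)
              else "",
              x$n_obs, x$train_score$r2))
  invisible(x)
}

#' Accuracy metrics for SPAD predictions
#'
#' Coefficient of determination R2 = 1 - SSres/SStot and root-mean-square
#' error RMSE = sqrt(mean((yhat - y)^2)) (denominator n). When `y` has zero
#' variance R2 is undefined and reported as `NA`, with RMSE still computed.
#'
#' @param y Observed SPAD.
#' @param y_hat Predicted SPAD (same length, n >= 2).
#' @return One-row tibble with `r2`, `rmse`, `n`.
#' @export
score <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("`y` and `y_hat` lengths differ.")
  if (length(y) < 2) abort("At least 2 samples are required.")
  ss_res <- sum((y_hat - y)^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble::tibble(
    r2 = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
    rmse = sqrt(ss_res / length(y)),
    n = length(y)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted SPAD calibration model
#'
#' @param x An `mlr_model` or `plsr_model`.
#' @param ... Unused.
#' @return A tibble of terms (`"(Intercept)"` then bands) and estimates.
#' @export
tidy.spad_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname tidy.spad_model
#' @return `glance()`: a one-row tibble with `kind`, `n_bands`,
#'   `n_components`, `n_obs`, `r2`, `rmse` (training).
#' @export
glance.spad_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_bands = length(x$coefficients),
    n_components = if (x$kind == "plsr") x$n_components else NA_integer_,
    n_obs = x$n_obs,
    r2 = x$train_score$r2,
    rmse = x$train_score$rmse
  )
}
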