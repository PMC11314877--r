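#' Successive projections chain
#'
#' Grows a chain of columns starting from `start`: at each step every
#' unselected column is projected onto the orthogonal complement of the span
#' of the columns already in the chain, and the column with the largest
#' projected Euclidean norm is appended (ties broken by lowest column index).
#' This is the core of the successive projections algorithm (SPA): each new
#' band carries the most variance not already explained by the chain, so the
#' selected bands are minimally collinear.
#'
#' Columns are used as given; mean-centre beforehand if required (as
#' [spa_select()] does). The chain is truncated with a warning when every
#' remaining projected norm falls below 1e-12.
#'
#' @param X Numeric sample-by-channel matrix.
#' @param start Index of the chain's seed column.
#' @param n_max Chain length.
#' @return Integer vector of column indices, `start` first.
#' @export
spa_chain <- function(X, start, n_max) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (start < 1 || start > p) {
    abort(paste0("`start` must be a column index in 1..", p, "."))
  }
  if (n_max < 1 || n_max > p) abort("`n_max` must lie in 1..ncol(X).")
  R <- X
  sel <- integer(n_max)
  cur <- start
  for (k in seq_len(n_max)) {
    sel[k] <- cur
    if (k == n_max) break
    u <- R[, cur]
    nu <- sum(u * u)
    if (sqrt(nu) < 1e-12) {
      warn(sprintf("spa_chain(): projected norms exhausted after %d bands; chain truncated.", k))
      return(sel[seq_len(k)])
    }
    # Deflate every column by its component along the newly selected one.
    R <- R - u %*% (crossprod(u, R) / nu)
    norms2 <- colSums(R * R)
    norms2[sel[seq_len(k)]] <- -Inf
    if (max(norms2) < 1e-24) {
      warn(sprintf("spa_chain(): projected norms exhausted after %d bands; chain truncated.", k))
      return(sel[seq_len(k)])
    }
    cur <- which.max(norms2)
  }
  sel
}

#' SPA band selection with validation scoring
#'
#' Runs [spa_chain()] from each candidate start column on the mean-centred
#' training matrix, fits an ordinary least-squares model of the response on
#' each chain prefix of length `n_min..n_max` (or only `fixed_n`), scores
#' root-mean-square error on the validation set, and returns the subset with
#' minimal validation RMSE. Ties are broken by smaller subset size, then
#' lower start index.
#'
#' @param X_train,X_val Sample-by-channel matrices with matching columns;
#'   column names, when present, are taken as wavelengths in nm.
#' @param y_train,y_val Response (SPAD) vectors.
#' @param n_min,n_max Smallest and largest subset size considered.
#' @param fixed_n When given, only subsets of exactly this size compete.
#' @param starts Candidate chain seeds: an integer vector of column indices,
#'   `"all"`, or `NULL` (default) for all columns when there are at most 60,
#'   otherwise the `n_starts` columns most correlated (absolutely) with
#'   `y_train`.
#' @param n_starts Number of candidate seeds retained under the default
#'   correlation screen.
#' @param exclude Column indices removed from consideration altogether, e.g.
#'   the `edge_channels` annotated by [fractional_derivative()]. Returned
#'   indices refer to the original columns.
#' @return A one-row tibble with `selected_indices` and
#'   `selected_wavelengths` (list columns), `n_selected`, `start_index`,
#'   `validation_rmse`, and `order_alpha` (`NA`; filled by
#'   [selection_map()]).
#' @export
spa_select <- function(X_train, y_train, X_val, y_val,
                       n_min = 1, n_max = 10, fixed_n = NULL,
                       starts = NULL, n_starts = 20, exclude = NULL) {
  X_train <- as.matrix(X_train)
  X_val <- as.matrix(X_val)
  if (ncol(X_train) != ncol(X_val)) {
    abort("`X_train` and `X_val` must have the same columns.")
  }
  if (n_min < 1) abort("`n_min` must be >= 1.")
  if (!is.null(exclude)) {
    keep <- setdiff(seq_len(ncol(X_train)), exclude)
    if (length(keep) == 0) abort("`exclude` removes every column.")
    res <- spa_select(X_train[, keep, drop = FALSE], y_train,
                      X_val[, keep, drop = FALSE], y_val,
                      n_min = n_min, n_max = n_max, fixed_n = fixed_n,
                      starts = starts, n_starts = n_starts)
    res$selected_indices[[1]] <- keep[res$selected_indices[[1]]]
    res$start_index <- keep[res$start_index]
    return(res)
  }
  if (n_max >= nrow(X_train)) {
    abort("`n_max` must be below the training sample count (rank deficiency).")
  }
  sizes <- if (is.null(fixed_n)) seq(n_min, n_max) else fixed_n
  chain_len <- max(sizes)

  Xc <- scale(X_train, center = TRUE, scale = FALSE)
  starts <- candidate_starts(starts, Xc, y_train, n_starts)

  best <- NULL
  for (s in starts) {
    chain <- suppressWarnings(spa_chain(Xc, s, chain_len))
    for (n in sizes[sizes <= length(chain)]) {
      idx <- chain[seq_len(n)]
      rmse <- ols_val_rmse(X_train[, idx, drop = FALSE], y_train,
                           X_val[, idx, drop = FALSE], y_val)
      if (is.null(best) ||
          rmse < best$rmse ||
          (rmse == best$rmse && (n < best$n ||
                                 (n == best$n && s < best$start)))) {
        best <- list(rmse = rmse, n = n, start = s, idx = idx)
      }
    }
  }
  if (is.null(best)) abort("spa_select(): no admissible subset found.")
  wl <- colnames(X_train)
  tibble::tibble(
    selected_indices = list(best$idx),
    selected_wavelengths = list(
      if (is.null(wl)) as.numeric(best$idx) else as.numeric(wl[best$idx])
    ),
    n_selected = length(best$idx),
    start_index = best$start,
    validation_rmse = best$rmse,
    order_alpha = NA_real_
  )
}

candidate_starts <- function(starts, Xc, y, n_starts) {
  p <- ncol(Xc)
  if (is.null(starts)) {
    if (p <= 60) return(seq_len(p))
    r <- suppressWarnings(as.vector(cor(Xc, y)))
    r[is.na(r)] <- 0
    return(sort(order(-abs(r))[seq_len(min(n_starts, p))]))
  }
  if (identical(starts, "all")) return(seq_len(p))
  starts <- as.integer(starts)
  if (any(starts < 1 | starts > p)) abort("`starts` indices out of range.")
  starts
}

ols_val_rmse <- function(Xtr, ytr, Xva, yva) {
  fit <- stats::lm.fit(cbind(1, Xtr), ytr)
  beta <- fit$coefficients
  if (anyNA(beta)) return(Inf)  # collinear prefix: not admissible
  pred <- cbind(1, Xva) %*% beta
  sqrt(mean((pred - yva)^2))
}

#' SPA selection across a derivative sweep
#'
#' Runs [spa_select()] independently on each order's transformed matrix,
#' with one fixed train/validation split shared across orders, producing the
#' per-order map of selected wavelengths.
#'
#' @param sweep Result of [derivative_sweep()].
#' @param split Result of [split_train_validation()].
#' @param n_bands Number of bands selected at every order.
#' @param ... Passed on to [spa_select()] (e.g. `starts`).
#' @return A tibble with one row per order: `order` plus the [spa_select()]
#'   columns, `order_alpha` filled in.
#' @export
selection_map <- function(sweep, split, n_bands = 10, ...) {
  rows <- purrr::map2(sweep$order, sweep$spectra, function(a, set) {
    parts <- split_spectra(set, split)
    sel <- spa_select(parts$X_train, parts$y_train,
                      parts$X_val, parts$y_val,
                      fixed_n = n_bands, n_max = n_bands, ...)
    sel$order_alpha <- a
    sel
  })
  dplyr::bind_cols(tibble::tibble(order = sweep$order), dplyr::bind_rows(rows))
}

# Partition one spectra table into train/validation design matrices.
split_spectra <- function(data, split) {
  m <- spectra_matrix(data)
  tr <- data$sample_id %in% split$sample_id[split$subset == "train"]
  va <- data$sample_id %in% split$sample_id[split$subset == "validation"]
  list(
    X_train = m[tr, , drop = FALSE], y_train = data$spad[tr],
    X_val = m[va, , drop = FALSE], y_val = data$spad[va],
    id_val = data$sample_id[va]
  )
}
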