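# Independent oracles and small fixture builders, kept deliberately naive so
# they share no code path with the implementation they check.

# G-L weights via the generalized binomial coefficient (closed form).
oracle_gl_weights <- function(alpha, m) {
  vapply(0:m, function(k) (-1)^k * choose(alpha, k), numeric(1))
}

# Expanding-window fractional derivative by direct double summation.
oracle_fractional_derivative <- function(r, alpha, h = 1) {
  n <- length(r)
  vapply(seq_len(n), function(i) {
    k <- 0:(i - 1)
    sum((-1)^k * choose(alpha, k) * r[i - k]) / h^alpha
  }, numeric(1))
}

# SPA chain by re-orthogonalizing against the full selected set from scratch
# at every step (QR residuals), rather than incremental deflation.
oracle_spa_chain <- function(X, start, n_max) {
  sel <- start
  while (length(sel) < n_max) {
    qrS <- qr(X[, sel, drop = FALSE])
    norms <- rep(-Inf, ncol(X))
    for (j in setdiff(seq_len(ncol(X)), sel)) {
      norms[j] <- sum(qr.resid(qrS, X[, j])^2)
    }
    if (max(norms) < 1e-24) break
    sel <- c(sel, which.max(norms))
  }
  sel
}

# OLS by the (numerically naive) normal equations.
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  as.vector(solve(crossprod(X1), crossprod(X1, y)))
}

# Mean of a normal(mu, sigma) truncated to [lo, hi], closed form.
oracle_truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# A small noise-free spectra table over a given SPAD vector.
tiny_config <- function(...) {
  args <- list(n_per_group = 4, noise_sd = 0, burr_rate = 0,
               wavelength_lo = 400, wavelength_hi = 1000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

spectra_from_spad <- function(spads, config = tiny_config()) {
  rows <- lapply(seq_along(spads), function(i) {
    generate_spectrum(spads[i], config, seed = 100 + i,
                      sample_id = sprintf("s%02d", i), group = "g")
  })
  dplyr::bind_rows(rows)
}

# Hand-rolled spectra table from a plain matrix.
spectra_from_matrix <- function(m, wl = seq_len(ncol(m)) + 399,
                                spad = rep(NA_real_, nrow(m))) {
  out <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(nrow(m))),
    group = "g", spad = spad
  )
  out[as.character(wl)] <- as.data.frame(m)
  out
}
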