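test_that("spa_chain hand case: projections and tie-breaking", {
  X <- cbind(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(spa_chain(X, start = 3, n_max = 2), c(3, 1))
})

test_that("orthogonal columns are chained in descending norm order", {
  X <- diag(c(5, 1, 4, 2, 3))
  expect_equal(spa_chain(X, start = 1, n_max = 5), c(1, 3, 5, 4, 2))
})

test_that("spa_chain equals the exhaustive re-orthogonalization oracle", {
  set.seed(3)
  for (rep in 1:100) {
    X <- matrix(rnorm(8 * 5), 8, 5)
    start <- sample(5, 1)
    n <- sample(2:4, 1)
    expect_equal(spa_chain(X, start, n), oracle_spa_chain(X, start, n))
  }
})

test_that("spa_chain truncates on exhausted complements and checks inputs", {
  X <- matrix(rep(c(1, 2, 3), 4), 3, 4)  # all columns identical
  expect_warning(sel <- spa_chain(X, 2, 3), "truncated")
  expect_equal(sel, 2)
  expect_error(spa_chain(X, 9, 2), "column index")
})

test_that("spa_select finds the single informative column exactly", {
  set.seed(4)
  X <- matrix(rnorm(40 * 8), 40, 8)
  j <- 5
  y <- 3 * X[, j]
  tr <- 1:25
  sel <- spa_select(X[tr, ], y[tr], X[-tr, ], y[-tr], fixed_n = 1, n_max = 1)
  expect_equal(sel$selected_indices[[1]], j)
  expect_equal(sel$validation_rmse, 0, tolerance = 1e-10)
})

test_that("spa_select honours fixed_n, tie rules, and guards rank", {
  set.seed(5)
  X <- matrix(rnorm(40 * 12), 40, 12)
  colnames(X) <- 500 + seq_len(12)
  y <- X %*% rnorm(12) + rnorm(40, sd = 0.1)
  tr <- 1:26
  sel <- spa_select(X[tr, ], y[tr], X[-tr, ], y[-tr],
                    fixed_n = 10, n_max = 10)
  expect_equal(sel$n_selected, 10)
  expect_equal(length(unique(sel$selected_indices[[1]])), 10)
  expect_equal(sel$selected_wavelengths[[1]],
               as.numeric(colnames(X)[sel$selected_indices[[1]]]))
  expect_error(
    spa_select(X[1:8, ], y[1:8], X[-(1:8), ], y[-(1:8)], n_max = 10),
    "rank"
  )
})

test_that("spa_select can mask excluded (edge) channels", {
  set.seed(6)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- 2 * X[, 1] + rnorm(30, sd = 0.01)  # column 1 is the signal...
  tr <- 1:20
  sel <- spa_select(X[tr, ], y[tr], X[-tr, ], y[-tr], fixed_n = 2, n_max = 2,
                    exclude = 1)           # ...but is masked out
  expect_false(1 %in% sel$selected_indices[[1]])
})

test_that("selected bands are less collinear than equally informative subsets", {
  # Collinearity control must be judged among channels of comparable signal:
  # informative channels all load on the latent SPAD factor, so the honest
  # reference set is random draws from the most SPAD-correlated channels.
  cfg <- synth_config(n_per_group = 30, seed = 21)
  set <- crop_range(generate_dataset(cfg), 400, 1350)
  g <- set[set$group == "1L", ]
  split <- split_train_validation(g, seed = 21)
  parts <- getFromNamespace("split_spectra", "spadspec")(g, split)
  Xc <- scale(parts$X_train, scale = FALSE)
  kappa_of <- function(cols) {
    M <- Xc[, cols, drop = FALSE]
    kappa(sweep(M, 2, sqrt(colSums(M^2)), "/"), exact = TRUE)
  }
  co <- abs(cor(parts$X_train, parts$y_train))
  co[is.na(co)] <- 0
  top <- order(-co)[1:50]
  sel <- spa_select(parts$X_train, parts$y_train, parts$X_val, parts$y_val,
                    fixed_n = 5, n_max = 5)
  set.seed(99)
  random_kappas <- replicate(50, kappa_of(sample(top, 5)))
  expect_lte(kappa_of(sel$selected_indices[[1]]), median(random_kappas))
})

test_that("selection_map runs one selection per order on a fixed split", {
  cfg <- synth_config(n_per_group = 12, seed = 31, noise_sd = 0.005)
  set <- crop_range(generate_dataset(cfg), 400, 1350)
  g <- set[set$group == "5L", ]
  split <- split_train_validation(g, seed = 31)
  sw <- derivative_sweep(g, 0, 1, 0.5)
  sel_map <- selection_map(sw, split, n_bands = 4)
  expect_equal(nrow(sel_map), 3)
  expect_equal(sel_map$order_alpha, c(0, 0.5, 1))
  expect_true(all(sel_map$n_selected == 4))

  # order 0 row equals spa_select run directly on the untransformed matrix
  parts <- getFromNamespace("split_spectra", "spadspec")(g, split)
  direct <- spa_select(parts$X_train, parts$y_train,
                       parts$X_val, parts$y_val, fixed_n = 4, n_max = 4)
  expect_equal(sel_map$selected_indices[[1]], direct$selected_indices[[1]])
  expect_equal(sel_map$validation_rmse[1], direct$validation_rmse)

  # reproducible bit-exactly
  sel_map2 <- selection_map(sw, split, n_bands = 4)
  expect_identical(sel_map, sel_map2)
})

test_that("SPAD-confined signal keeps selections near the active region", {
  # SPAD only modulates the red edge (700-760 nm) when the green peak and
  # wells are switched off; selections must then intersect 650-800 nm.
  cfg <- synth_config(n_per_group = 20, seed = 41, noise_sd = 0,
                      burr_rate = 0, green_peak_max = 0,
                      well_depth_blue = 0, well_depth_red = 0)
  set <- crop_range(generate_dataset(cfg), 400, 1350)
  split <- split_train_validation(set, seed = 41)
  for (g in c("1L", "control")) {
    gd <- set[set$group == g, ]
    for (a in c(0, 0.5, 1.5)) {
      dset <- fractional_derivative(gd, a)
      parts <- getFromNamespace("split_spectra", "spadspec")(dset, split)
      sel <- spa_select(parts$X_train, parts$y_train,
                        parts$X_val, parts$y_val, fixed_n = 5, n_max = 5)
      wls <- sel$selected_wavelengths[[1]]
      expect_true(any(wls >= 650 & wls <= 800),
                  label = sprintf("group %s order %.1f: %s", g, a,
                                  paste(wls, collapse = ",")))
    }
  }
})
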