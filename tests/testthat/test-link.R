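# PCoA, regression summaries, lag models, random forest, db-RDA,
# hierarchical partitioning

test_that("PCoA of collinear points matches brute-force eigendecomposition", {
  x <- c(0, 1, 3)
  D <- as.matrix(dist(x)); dimnames(D) <- list(letters[1:3], letters[1:3])
  ord <- suppressWarnings(pcoa(D, n_axes = 3))
  expect_equal(ord$n_positive, 1)
  sc <- ord$scores[, 1]
  expect_equal(sort(as.numeric(dist(sc))), c(1, 2, 3))
  # oracle: base R cmdscale on the same matrix
  ref <- cmdscale(D, k = 1)
  expect_equal(abs(as.numeric(sc)), abs(as.numeric(ref[, 1])))
  expect_equal(mean(sc), 0)
})

test_that("PCoA recovers planted 2-D configurations up to rotation", {
  withr::with_seed(51, X <- matrix(rnorm(40), 20, 2))
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- sprintf("s%d", 1:20)
  ord <- pcoa(D, n_axes = 2)
  # Procrustes via SVD of the cross-product
  A <- scale(X, scale = FALSE); B <- ord$scores
  sv <- svd(crossprod(B, A))
  rot <- sv$u %*% t(sv$v)
  expect_lt(sum((B %*% rot - A)^2), 1e-8)
  expect_equal(ord$eigenvalues, sort(ord$eigenvalues, decreasing = TRUE))
})

test_that("duplicated samples get identical PCoA scores", {
  m <- rbind(tiny_counts(), s1b = tiny_counts()["s1", ])
  ord <- suppressWarnings(pcoa(bray_curtis(m), n_axes = 2))
  expect_equal(ord$scores["s1", ], ord$scores["s1b", ],
               ignore_attr = TRUE)
})

test_that("fit_mlr: perfect fit, adjusted R2 closed form, diagnostics", {
  withr::with_seed(52, {
    x1 <- rnorm(30); x2 <- rnorm(30)
  })
  fit <- fit_mlr(2 * x1 - x2, cbind(x1 = x1, x2 = x2))
  expect_equal(fit$r2, 1)
  expect_equal(fit$adj_r2, 1)
  # standardized coefficients: beta_j * sd(x_j)/sd(y)
  y <- 2 * x1 - x2
  expect_equal(unname(fit$coefficients),
               c(2 * sd(x1) / sd(y), -1 * sd(x2) / sd(y)))

  # adjusted R2 formula: n=10, p=3, R2=0.5 -> 0.25; R2=0 -> -0.5
  adj <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)
  expect_equal(adj(0.5, 10, 3), 0.25)
  expect_equal(adj(0, 10, 3), -0.5)

  # adj R2 <= R2 on random fits, can go negative under pure noise
  withr::with_seed(53, {
    negs <- replicate(50, {
      f <- fit_mlr(rnorm(10), matrix(rnorm(30), 10, 3))
      c(f$r2, f$adj_r2)
    })
  })
  expect_true(all(negs[2, ] <= negs[1, ] + 1e-12))
  expect_true(any(negs[2, ] < 0))

  expect_error(fit_mlr(rnorm(10), cbind(a = 1:10, b = 2 * (1:10))),
               "collinear")
  expect_error(fit_mlr(rnorm(4), matrix(rnorm(12), 4, 3)),
               class = "nitrilink_input_error")
})

test_that("composition_models: identity slice reproduces the total model", {
  ds <- simulate_dataset(sim_config(n_days_period1 = 20, n_days_period2 = 0,
                                    n_noise = 20, depth = 5000, seed = 54))
  rate <- setNames(ds$metadata$rate, ds$metadata$sample_id)
  all_set <- structure(list(name = "all", taxa = colnames(ds$counts),
                            provenance = list(anchor = character(0),
                                              cutoff = 0.1, alpha = 0.01,
                                              period = "all")),
                       class = "subcommunity_set")
  res <- composition_models(rate, ds$counts, list("0.1" = all_set))
  tot <- res[res$slice == "total", ]
  asc <- res[res$slice == "associated", ]
  expect_equal(asc$adjR2, tot$adjR2)
  expect_equal(asc$p_model, tot$p_model)
  # one record per slice/cutoff; empty sets produce NA records
  empty <- structure(list(name = "e", taxa = character(0),
                          provenance = list(anchor = character(0),
                                            cutoff = 0.9, alpha = 0.01,
                                            period = "all")),
                     class = "subcommunity_set")
  res2 <- suppressWarnings(
    composition_models(rate, ds$counts, list("0.1" = all_set,
                                             "0.9" = empty)))
  expect_equal(nrow(res2), 3)
  expect_true(is.na(res2$adjR2[which(res2$cutoff == 0.9)]))
})

test_that("diversity_models: exact function of richness gives adj R2 = 1", {
  withr::with_seed(55, {
    a <- data.frame(sample_id = sprintf("s%d", 1:30),
                    richness = sample(5:50, 30, TRUE) + 0,
                    shannon = rnorm(30, 2, 0.3),
                    simpson = runif(30, 0.5, 0.95))
  })
  rate <- setNames(3 * a$richness - 7, a$sample_id)
  res <- diversity_models(rate, list(total = a))
  expect_equal(res$adjR2, 1)
  expect_equal(res$slice, "total")

  # null response: adjusted R2 centered near zero
  withr::with_seed(56, {
    nulls <- replicate(30, {
      rate0 <- setNames(rnorm(30), a$sample_id)
      diversity_models(rate0, list(total = a))$adjR2
    })
  })
  expect_lt(abs(median(nulls)), 0.15)
})

test_that("lag_models: L = 0 reproduces the unlagged model, n shrinks", {
  withr::with_seed(57, {
    n <- 40
    scores <- matrix(rnorm(n * 3), n, 3,
                     dimnames = list(sprintf("d%03d", 1:n), NULL))
    dates <- setNames(as.Date("2020-01-01") + 0:(n - 1), rownames(scores))
    rate <- setNames(rnorm(n) + scores[, 1], rownames(scores))
  })
  res <- lag_models(rate, scores, dates, lags = c(0L, 2L, 4L))
  direct <- fit_mlr(as.numeric(rate), scores)
  expect_equal(res$adjR2[res$lag == 0], direct$adj_r2)
  expect_equal(res$n, c(n, n - 2, n - 4))

  # too few matched pairs -> NA record, no error
  res2 <- lag_models(rate[1:6], scores[1:6, ], dates[1:6], lags = c(5L))
  expect_true(is.na(res2$adjR2))
})

test_that("lag_models recovers a planted 4-day lag", {
  withr::with_seed(58, {
    n <- 80
    scores <- matrix(rnorm(n * 3), n, 3,
                     dimnames = list(sprintf("d%03d", 1:n), NULL))
    dates <- setNames(as.Date("2020-01-01") + 0:(n - 1), rownames(scores))
    # rate at t+4 is driven by composition at t
    rate <- setNames(rep(NA_real_, n), rownames(scores))
    rate[5:n] <- scores[1:(n - 4), 1] * 2 + rnorm(n - 4, 0, 0.3)
    keep <- !is.na(rate)
  })
  res <- lag_models(rate[keep], scores, dates, lags = c(0L, 2L, 4L, 6L, 8L))
  expect_equal(res$lag[which.max(res$adjR2)], 4L)
})

test_that("random forest importance finds the driving variable", {
  withr::with_seed(59, {
    X <- matrix(rnorm(80 * 5), 80, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    y <- 3 * X[, 1] + rnorm(80, 0, 0.5)
  })
  imp <- rf_importance(y, X, n_trees = 100, seed = 60)
  expect_equal(unname(imp$rank["v1"]), 1)
  expect_gt(imp$oob_r2, 0.5)
  expect_equal(sort(unname(imp$rank)), 1:5)

  # duplicated predictor: both copies matter, fit roughly unchanged
  X2 <- cbind(X, v1b = X[, 1])
  imp2 <- rf_importance(y, X2, n_trees = 100, seed = 61)
  expect_gt(imp2$importance["v1"], 0)
  expect_gt(imp2$importance["v1b"], 0)
  expect_lt(abs(imp2$oob_r2 - imp$oob_r2), 0.15)

  # permuted response: importances hover near zero
  withr::with_seed(62, y0 <- sample(y))
  imp0 <- rf_importance(y0, X, n_trees = 100, seed = 63)
  expect_lt(max(imp0$importance), 0.25 * var(y0))

  expect_error(rf_importance(y[1:5], X[1:5, ]),
               class = "nitrilink_input_error")
})

test_that("db-RDA: self-explanation, exact construction, null level", {
  withr::with_seed(64, X <- matrix(rnorm(60), 30, 2,
                                   dimnames = list(sprintf("s%d", 1:30),
                                                   c("e1", "e2"))))
  D <- as.matrix(dist(X))
  fit <- dbrda(D, X)                 # env == coordinates
  expect_equal(fit$fraction, 1, tolerance = 1e-8)

  # coordinates an exact linear function of 3 env variables
  withr::with_seed(65, {
    E <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    Y <- E %*% matrix(c(1, 0.5, -2, 0, 1, 1), 3, 2)
  })
  D2 <- as.matrix(dist(Y)); dimnames(D2) <- list(1:40, 1:40)
  expect_equal(dbrda(D2, E)$fraction, 1, tolerance = 1e-8)

  # single random regressor: fraction near its 1/(n-1) expectation
  withr::with_seed(66, {
    n <- 100
    Dn <- as.matrix(dist(matrix(rnorm(n * 5), n, 5)))
    dimnames(Dn) <- list(1:n, 1:n)
    fr <- dbrda(Dn, matrix(rnorm(n), n, 1,
                           dimnames = list(NULL, "x")))$fraction
  })
  expect_lt(fr, 0.06)

  expect_error(dbrda(D, cbind(X, e3 = X[, 1] + X[, 2])), "collinear")
})

test_that("AIC forward selection finds the planted driver and is stable", {
  withr::with_seed(67, {
    E <- matrix(rnorm(50 * 4), 50, 4,
                dimnames = list(NULL, c("driver", "n1", "n2", "n3")))
    Y <- cbind(2 * E[, 1] + rnorm(50, 0, 0.3), rnorm(50, 0, 0.3))
    D <- as.matrix(dist(Y)); dimnames(D) <- list(1:50, 1:50)
  })
  sel <- aic_select(D, E)
  expect_equal(sel[1], "driver")
  expect_identical(sel, aic_select(D, E))   # deterministic
  expect_lte(length(sel), 4)
})

test_that("hierarchical partitioning: exact cases and the sum identity", {
  # p = 1: individual effect equals the variable's own fraction
  withr::with_seed(68, {
    E1 <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x"))
    D <- as.matrix(dist(cbind(E1 + rnorm(30, 0, 0.8), rnorm(30))))
    dimnames(D) <- list(1:30, 1:30)
  })
  hp1 <- hierarchical_partition(D, E1)
  expect_equal(unname(hp1$effects["x"]), dbrda(D, E1)$fraction)

  # two exactly orthogonal predictors with marginal fractions 0.3 and 0.2
  withr::with_seed(69, {
    q <- qr.Q(qr(scale(matrix(rnorm(40 * 3), 40, 3), scale = FALSE)))
    y <- sqrt(0.3) * q[, 1] + sqrt(0.2) * q[, 2] + sqrt(0.5) * q[, 3]
    Dy <- as.matrix(dist(y)); dimnames(Dy) <- list(1:40, 1:40)
    E <- cbind(u1 = q[, 1], u2 = q[, 2])
  })
  hp2 <- hierarchical_partition(Dy, E)
  expect_equal(unname(hp2$effects), c(0.3, 0.2), tolerance = 1e-8)
  expect_equal(hp2$total, 0.5, tolerance = 1e-8)

  expect_error(hierarchical_partition(Dy, matrix(rnorm(40 * 16), 40, 16)),
               class = "nitrilink_input_error")
})
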