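# The diversity -> function statistical core: principal coordinates
# analysis, composition and diversity regressions across community slices
# and cutoffs, time-lag variants, random-forest permutation importance, and
# distance-based redundancy analysis with AIC forward selection and
# hierarchical partitioning.

#' Principal coordinates analysis
#'
#' Gower double-centering `B = -1/2 J (D o D) J` with `J` the centering
#' projector, followed by eigendecomposition. Scores are eigenvectors scaled
#' by sqrt(eigenvalue) for positive eigenvalues; negative eigenvalues are
#' retained in the report but excluded from scores.
#'
#' @param D square symmetric distance matrix with zero diagonal.
#' @param n_axes number of leading positive axes to return in `scores`
#'   (fewer, with a warning, when not available).
#' @return list of class `ordination`: `scores` (n x m, column means ~ 0),
#'   `eigenvalues` (all, descending), `prop_explained` (per positive axis,
#'   relative to the sum of positive eigenvalues), `n_positive`.
#' @export
pcoa <- function(D, n_axes = 3L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    nl_stop("D must be square and symmetric", "nitrilink_input_error")
  }
  A <- -0.5 * D^2
  B <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  m <- min(n_axes, length(pos))
  if (m < n_axes) {
    nl_warn(sprintf("only %d positive eigenvalue(s); returning %d axes",
                    length(pos), m))
  }
  scores <- e$vectors[, pos[seq_len(m)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(m)]]), m)
  dimnames(scores) <- list(rownames(D), paste0("PCo", seq_len(m)))
  structure(list(scores = scores,
                 eigenvalues = e$values,
                 prop_explained = e$values[pos] / sum(e$values[pos]),
                 n_positive = length(pos)),
            class = "ordination")
}

# full positive-axis coordinates (used as db-RDA response)
pcoa_coords <- function(D) {
  ord <- suppressWarnings(pcoa(D, n_axes = ncol(as.matrix(D))))
  ord$scores
}

standardize_cols <- function(X, what = "design") {
  X <- as.matrix(X)
  const <- apply(X, 2L, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)))
  if (any(const)) {
    nl_stop(sprintf("constant column(s) in %s: %s", what,
                    paste(colnames(X)[const], collapse = ", ")),
            "nitrilink_input_error")
  }
  scale(X)
}

#' Multiple linear regression on standardized variables
#'
#' Response and predictors are centered to mean 0 and scaled to unit
#' variance, so coefficients are standardized (comparable across predictors).
#' Ordinary least squares with the overall F-test p-value.
#'
#' @param y numeric response.
#' @param X matrix or data.frame of predictors; needs `n > p + 1` and no
#'   missing values.
#' @param response name recorded for the response.
#' @return list of class `regression_summary`: `response`, `predictors`,
#'   `coefficients` (standardized), `r2`, `adj_r2`
#'   (`1 - (1 - R2)(n - 1)/(n - p - 1)`), `p` (model F), `n`.
#' @export
fit_mlr <- function(y, X, response = "rate") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  if (anyNA(y) || anyNA(X)) {
    nl_stop("missing values in regression inputs", "nitrilink_input_error")
  }
  if (n != nrow(X) || n <= p + 1) {
    nl_stop(sprintf("need n > p + 1 (n = %d, p = %d)", n, p),
            "nitrilink_input_error")
  }
  Xs <- standardize_cols(X, "design matrix")
  qrX <- qr(Xs)
  if (qrX$rank < p) {
    dropped <- colnames(Xs)[qrX$pivot[(qrX$rank + 1):p]]
    nl_stop(paste("rank-deficient design; collinear column(s):",
                  paste(dropped, collapse = ", ")),
            "nitrilink_input_error")
  }
  ys <- as.numeric(scale(y))
  beta <- qr.coef(qrX, ys)
  fitted <- as.numeric(Xs %*% beta)
  rss <- sum((ys - fitted)^2)
  tss <- sum(ys^2)                          # ys centered
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  fstat <- (r2 / p) / ((1 - r2) / (n - p - 1))
  pval <- stats::pf(fstat, p, n - p - 1, lower.tail = FALSE)
  structure(list(response = response, predictors = colnames(X),
                 coefficients = stats::setNames(as.numeric(beta),
                                                colnames(X)),
                 r2 = r2, adj_r2 = adj, p = pval, n = n),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("<MLR %s ~ %s: R2 %.3f, adj R2 %.3f, p %.3g, n %d>\n",
              x$response, paste(x$predictors, collapse = " + "),
              x$r2, x$adj_r2, x$p, x$n))
  invisible(x)
}

align_rate <- function(rate, sample_ids) {
  if (is.data.frame(rate)) {
    rate <- stats::setNames(rate$rate, rate$sample_id)
  }
  if (!is.null(names(rate))) {
    if (!all(sample_ids %in% names(rate))) {
      nl_stop("rate series does not cover all samples",
              "nitrilink_input_error")
    }
    rate <- rate[sample_ids]
  } else if (length(rate) != length(sample_ids)) {
    nl_stop("unnamed rate series of wrong length", "nitrilink_input_error")
  }
  as.numeric(rate)
}

# one composition model: slice -> Bray-Curtis -> PCoA axes -> MLR
composition_model_one <- function(rate, counts, taxa, n_axes) {
  sub <- counts[, colnames(counts) %in% taxa, drop = FALSE]
  if (ncol(sub) == 0 || all(sub == 0)) return(NULL)
  ord <- suppressWarnings(pcoa(bray_curtis(sub), n_axes = n_axes))
  if (ncol(ord$scores) == 0) return(NULL)
  fit_mlr(align_rate(rate, rownames(counts)), ord$scores)
}

#' Composition-based models across the cutoff sweep
#'
#' For each cutoff's subcommunity: subset table -> Bray-Curtis -> PCoA ->
#' first `n_axes` axes -> standardized multiple linear regression against
#' the nitrification rate. Also fits the two baselines (total community and,
#' when given, the nitrifier subcommunity). Models with p >= 0.05 are
#' flagged non-significant; empty sets are skipped with an NA record.
#'
#' @param rate nitrification-rate series (named vector or data.frame with
#'   `sample_id`, `rate`) covering the table's samples.
#' @param counts samples x taxa abundance matrix (the rarefied table slice
#'   the models should run on).
#' @param sets named list of `subcommunity_set`s (one per cutoff), e.g. from
#'   [cutoff_sweep()] or [core_subcommunity()].
#' @param nitrifiers optional nitrifier `subcommunity_set` baseline.
#' @param n_axes PCoA axes used as predictors.
#' @return data.frame with one row per model: `slice`, `cutoff`, `n_taxa`,
#'   `n`, `R2`, `adjR2`, `p_model`, `significant`.
#' @export
composition_models <- function(rate, counts, sets, nitrifiers = NULL,
                               n_axes = 3L) {
  row_of <- function(slice, cutoff, taxa) {
    fit <- composition_model_one(rate, counts, taxa, n_axes)
    if (is.null(fit)) {
      return(data.frame(slice = slice, cutoff = cutoff,
                        n_taxa = length(taxa), n = NA_integer_,
                        R2 = NA_real_, adjR2 = NA_real_,
                        p_model = NA_real_, significant = NA,
                        stringsAsFactors = FALSE))
    }
    data.frame(slice = slice, cutoff = cutoff, n_taxa = length(taxa),
               n = fit$n, R2 = fit$r2, adjR2 = fit$adj_r2, p_model = fit$p,
               significant = fit$p < 0.05, stringsAsFactors = FALSE)
  }
  out <- list(row_of("total", NA_real_, colnames(counts)))
  if (!is.null(nitrifiers)) {
    out <- c(out, list(row_of("nitrifier", NA_real_, taxa_of(nitrifiers))))
  }
  for (nm in names(sets)) {
    s <- sets[[nm]]
    out <- c(out, list(row_of("associated", s$provenance$cutoff, s$taxa)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Diversity-based models per community slice
#'
#' One standardized regression per slice with predictors richness, Shannon
#' and Simpson. Near-collinear predictors are tolerated (the condition
#' number is logged); an exactly singular design errors.
#'
#' @param rate nitrification-rate series (see [composition_models()]).
#' @param alpha_by_slice named list of [alpha_diversity()] profiles.
#' @return data.frame with `slice`, `n`, `R2`, `adjR2`, `p_model` and the
#'   three standardized coefficients.
#' @export
diversity_models <- function(rate, alpha_by_slice) {
  rows <- lapply(names(alpha_by_slice), function(nm) {
    a <- alpha_by_slice[[nm]]
    X <- as.matrix(a[, c("richness", "shannon", "simpson")])
    kappa_x <- kappa(standardize_cols(X, "alpha metrics"))
    if (kappa_x > 1e6) {
      nl_log(sprintf("slice %s: alpha metrics near-collinear (kappa %.3g)",
                     nm, kappa_x))
    }
    fit <- fit_mlr(align_rate(rate, a$sample_id), X)
    data.frame(slice = nm, n = fit$n, R2 = fit$r2, adjR2 = fit$adj_r2,
               p_model = fit$p,
               coef_richness = fit$coefficients[["richness"]],
               coef_shannon = fit$coefficients[["shannon"]],
               coef_simpson = fit$coefficients[["simpson"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Time-lagged composition models
#'
#' Pairs composition scores at day `t` with the rate at day `t + L` for each
#' lag `L` (set `reverse = TRUE` for the opposite orientation). Days without
#' a partner (including any sampling gap) are dropped; `n` is reported per
#' lag. Lags with fewer than `p + 2` matched pairs are skipped with an NA
#' record.
#'
#' @param rate named rate series or data.frame (`sample_id`, `rate`).
#' @param scores samples x axes score matrix (rownames = sample ids).
#' @param dates `Date` vector named by sample id covering scores and rate.
#' @param lags integer lags in days (default 0 plus 2, 4, 6, 8).
#' @param reverse pair rate(t) with composition(t + L) instead.
#' @return data.frame with `lag`, `n`, `R2`, `adjR2`, `p_model`.
#' @export
lag_models <- function(rate, scores, dates, lags = c(0L, 2L, 4L, 6L, 8L),
                       reverse = FALSE) {
  if (is.data.frame(rate)) rate <- stats::setNames(rate$rate, rate$sample_id)
  ids <- rownames(scores)
  if (is.null(ids) || !all(ids %in% names(dates))) {
    nl_stop("scores need sample-id rownames covered by dates",
            "nitrilink_input_error")
  }
  p <- ncol(scores)
  rows <- lapply(lags, function(L) {
    target <- dates[ids] + if (reverse) -L else L
    partner <- names(dates)[match(target, dates)]
    ok <- !is.na(partner) & partner %in% names(rate)
    n_ok <- sum(ok)
    if (n_ok < p + 2) {
      return(data.frame(lag = L, n = n_ok, R2 = NA_real_, adjR2 = NA_real_,
                        p_model = NA_real_))
    }
    fit <- fit_mlr(as.numeric(rate[partner[ok]]),
                   scores[ok, , drop = FALSE])
    data.frame(lag = L, n = fit$n, R2 = fit$r2, adjR2 = fit$adj_r2,
               p_model = fit$p)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

## ------------------------------------------------------------------------
## regression random forest with out-of-bag permutation importance
## (implemented in-package: no forest library in the runtime environment)

rf_build_tree <- function(X, y, idx, mtry, min_node) {
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(var = NA_integer_, split = NA_real_,
                                         left = NA_integer_,
                                         right = NA_integer_,
                                         pred = NA_real_)
    length(nodes)
  }
  grow <- function(node_id, idx) {
    yv <- y[idx]
    if (length(idx) < 2L * min_node || stats::var(yv) < 1e-12) {
      nodes[[node_id]]$pred <<- mean(yv)
      return(invisible())
    }
    feats <- sample.int(ncol(X), mtry)
    best <- list(red = 0)
    S <- sum(yv); ntot <- length(yv)
    for (f in feats) {
      xo <- order(X[idx, f])
      xs <- X[idx[xo], f]; ys <- yv[xo]
      cs <- cumsum(ys)[-ntot]
      nl <- seq_len(ntot - 1L)
      valid <- xs[-ntot] < xs[-1] & nl >= min_node & (ntot - nl) >= min_node
      if (!any(valid)) next
      red <- cs^2 / nl + (S - cs)^2 / (ntot - nl) - S^2 / ntot
      red[!valid] <- -Inf
      k <- which.max(red)
      if (red[k] > best$red + 1e-12) {
        best <- list(red = red[k], var = f,
                     split = (xs[k] + xs[k + 1]) / 2)
      }
    }
    if (is.null(best$var)) {
      nodes[[node_id]]$pred <<- mean(yv)
      return(invisible())
    }
    go_left <- X[idx, best$var] <= best$split
    l <- new_node(); r <- new_node()
    nodes[[node_id]]$var <<- best$var
    nodes[[node_id]]$split <<- best$split
    nodes[[node_id]]$left <<- l
    nodes[[node_id]]$right <<- r
    grow(l, idx[go_left])
    grow(r, idx[!go_left])
  }
  root <- new_node()
  grow(root, idx)
  nodes
}

rf_predict_tree <- function(nodes, X) {
  vapply(seq_len(nrow(X)), function(i) {
    k <- 1L
    repeat {
      nd <- nodes[[k]]
      if (!is.na(nd$pred)) return(nd$pred)
      k <- if (X[i, nd$var] <= nd$split) nd$left else nd$right
    }
  }, numeric(1))
}

rf_forest <- function(X, y, n_trees, mtry, min_node) {
  n <- nrow(X)
  trees <- vector("list", n_trees)
  oob_sum <- numeric(n); oob_n <- integer(n)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), boot)
    tree <- rf_build_tree(X, y, boot, mtry, min_node)
    trees[[b]] <- list(nodes = tree, oob = oob)
    if (length(oob)) {
      pr <- rf_predict_tree(tree, X[oob, , drop = FALSE])
      oob_sum[oob] <- oob_sum[oob] + pr
      oob_n[oob] <- oob_n[oob] + 1L
    }
  }
  has <- oob_n > 0
  mse <- mean((y[has] - oob_sum[has] / oob_n[has])^2)
  list(trees = trees, oob_mse = mse)
}

#' Random-forest permutation importance for the nitrification rate
#'
#' Ensemble of regression trees on bootstrap resamples. The number of
#' predictors tried at each split (`mtry`) is scanned over a grid and chosen
#' by minimum out-of-bag mean squared error. Importance of a variable is the
#' mean increase in out-of-bag MSE when that variable is permuted; overall
#' fit is reported as out-of-bag R-squared.
#'
#' @param rate numeric response (n >= 10).
#' @param X matrix or data.frame of predictors, no missing values.
#' @param n_trees trees per forest (default 1000).
#' @param mtry_grid candidate `mtry` values; default scans p/3 scaled by
#'   {0.5, 1, 2}.
#' @param min_node minimum observations per leaf.
#' @param seed integer seed.
#' @return list of class `importance_table`: `importance` (named, increase
#'   in OOB MSE), `rank`, `mtry`, `oob_mse`, `oob_r2`.
#' @export
rf_importance <- function(rate, X, n_trees = 1000L, mtry_grid = NULL,
                          min_node = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(rate)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(y) || anyNA(X)) {
    nl_stop("missing values in random-forest inputs",
            "nitrilink_input_error")
  }
  if (n < 10) {
    nl_stop("need n >= 10 for out-of-bag estimation",
            "nitrilink_input_error")
  }
  if (is.null(mtry_grid)) {
    mtry_grid <- unique(pmin(p, pmax(1L, floor(p / 3 * c(0.5, 1, 2)))))
  }
  with_seed(seed, {
    fits <- lapply(mtry_grid, function(m) {
      rf_forest(X, y, n_trees, m, min_node)
    })
    best <- which.min(vapply(fits, `[[`, numeric(1), "oob_mse"))
    fit <- fits[[best]]
    # per-tree OOB permutation importance
    delta <- matrix(0, length(fit$trees), p)
    used <- logical(length(fit$trees))
    for (b in seq_along(fit$trees)) {
      tr <- fit$trees[[b]]
      if (length(tr$oob) < 2) next
      used[b] <- TRUE
      Xo <- X[tr$oob, , drop = FALSE]
      yo <- y[tr$oob]
      base_mse <- mean((yo - rf_predict_tree(tr$nodes, Xo))^2)
      for (v in seq_len(p)) {
        Xp <- Xo
        Xp[, v] <- Xp[sample.int(nrow(Xo)), v]
        delta[b, v] <- mean((yo - rf_predict_tree(tr$nodes, Xp))^2) - base_mse
      }
    }
    imp <- colMeans(delta[used, , drop = FALSE])
  })
  names(imp) <- colnames(X)
  structure(list(importance = imp,
                 rank = rank(-imp, ties.method = "first"),
                 mtry = mtry_grid[best],
                 oob_mse = fit$oob_mse,
                 oob_r2 = 1 - fit$oob_mse / mean((y - mean(y))^2)),
            class = "importance_table")
}

## ------------------------------------------------------------------------
## distance-based redundancy analysis

# fraction of the PCoA-coordinate variance explained by env subset S
dbrda_fraction <- function(coords, Xs) {
  if (ncol(Xs) == 0) return(0)
  qx <- qr(Xs)
  fitted <- qr.fitted(qx, coords)
  sum(fitted^2) / sum(coords^2)
}

#' Distance-based redundancy analysis
#'
#' PCoA of the distance matrix (all positive-eigenvalue axes, unweighted) as
#' the multivariate response; least-squares regression of the coordinates on
#' the standardized environmental variables. The constrained fraction is the
#' trace of the fitted sum of squares over the total trace; constrained axes
#' come from the eigendecomposition of the fitted covariance.
#'
#' @param D distance matrix (e.g. [bray_curtis()]).
#' @param env data.frame/matrix of environmental variables; `n` must exceed
#'   the number of variables.
#' @return list of class `dbrda_result`: `fraction`, `eigenvalues`,
#'   `scores` (constrained axis scores), `variables`.
#' @export
dbrda <- function(D, env) {
  coords <- pcoa_coords(D)
  X <- standardize_cols(env, "env table")
  n <- nrow(coords)
  if (nrow(X) != n || n <= ncol(X)) {
    nl_stop("need more samples than env variables",
            "nitrilink_input_error")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    nl_stop(paste("rank-deficient env; collinear column(s):",
                  paste(dropped, collapse = ", ")),
            "nitrilink_input_error")
  }
  fitted <- qr.fitted(qx, coords)
  frac <- sum(fitted^2) / sum(coords^2)
  e <- eigen(crossprod(fitted) / (n - 1), symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-9
  scores <- fitted %*% e$vectors[, keep, drop = FALSE]
  colnames(scores) <- paste0("dbRDA", seq_len(sum(keep)))
  structure(list(fraction = frac, eigenvalues = e$values[keep],
                 scores = scores, variables = colnames(X)),
            class = "dbrda_result")
}

#' Forward AIC selection of db-RDA variables
#'
#' Greedy forward selection on `AIC = n log(RSS/n) + 2k` where RSS is the
#' residual trace of the multivariate fit and `k` the number of selected
#' variables + 1. Stops when no addition lowers the AIC; may select an empty
#' set. Deterministic given the data.
#'
#' @inheritParams dbrda
#' @return character vector of selected variable names (possibly empty).
#' @export
aic_select <- function(D, env) {
  coords <- pcoa_coords(D)
  X <- standardize_cols(env, "env table")
  n <- nrow(coords)
  vars <- colnames(X)
  tot <- sum(coords^2)
  aic_of <- function(sel) {
    rss <- tot * (1 - dbrda_fraction(coords, X[, sel, drop = FALSE]))
    n * log(rss / n) + 2 * (length(sel) + 1)
  }
  selected <- character(0)
  best_aic <- aic_of(selected)
  repeat {
    remaining <- setdiff(vars, selected)
    if (!length(remaining)) break
    cand <- vapply(remaining, function(v) aic_of(c(selected, v)), numeric(1))
    if (min(cand) >= best_aic) break
    selected <- c(selected, remaining[which.min(cand)])
    best_aic <- min(cand)
  }
  selected
}

#' Hierarchical partitioning of db-RDA constrained variance
#'
#' Individual effect of variable `v` is the Chevan-Sutherland average over
#' all subsets `S` not containing `v` of the gain
#' `fraction(S + v) - fraction(S)` with weights `w(s) = s!(p-s-1)!/p!`.
#' Effects sum exactly to the full-model constrained fraction.
#'
#' @inheritParams dbrda
#' @param env at most 15 variables (2^p subset enumeration).
#' @return list of class `partition_result`: `effects` (named individual
#'   effects) and `total` (full-model constrained fraction).
#' @export
hierarchical_partition <- function(D, env) {
  coords <- pcoa_coords(D)
  X <- standardize_cols(env, "env table")
  p <- ncol(X)
  if (p > 15) {
    nl_stop("more than 15 variables: pre-select (e.g. aic_select) first",
            "nitrilink_input_error")
  }
  nsub <- 2^p
  frac <- numeric(nsub)                    # index = bitmask + 1
  for (mask in seq_len(nsub) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0)
    frac[mask + 1L] <- dbrda_fraction(coords, X[, sel, drop = FALSE])
  }
  w <- factorial(0:(p - 1)) * factorial(p - 1 - 0:(p - 1)) / factorial(p)
  effects <- stats::setNames(numeric(p), colnames(X))
  for (v in seq_len(p)) {
    bit <- bitwShiftL(1L, v - 1L)
    for (mask in seq_len(nsub) - 1L) {
      if (bitwAnd(mask, bit) != 0) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0)
      effects[v] <- effects[v] +
        w[s + 1] * (frac[bitwOr(mask, bit) + 1L] - frac[mask + 1L])
    }
  }
  structure(list(effects = effects, total = frac[nsub]),
            class = "partition_result")
}
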