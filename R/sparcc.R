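# SparCC-style compositional correlation inference, from scratch: Dirichlet
# fraction draws, log-ratio variance matrices, the sparse basis-variance
# approximation with iterative strong-pair exclusion, averaging over draws,
# and permutation significance.

#' Dirichlet posterior fraction draws
#'
#' Each draw samples per-sample fractions from a Dirichlet posterior with
#' counts + 1 pseudocount, so zero counts become strictly positive fractions
#' and each sample's fractions sum to 1.
#'
#' @param counts samples x taxa non-negative count matrix; every sample total
#'   must be > 0.
#' @param n_draws number of posterior draws.
#' @param seed integer seed.
#' @return list of `n_draws` fraction matrices (samples x taxa).
#' @export
estimate_fractions <- function(counts, n_draws = 20L, seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    nl_stop("counts must be non-negative", "nitrilink_input_error")
  }
  if (any(rowSums(counts) == 0)) {
    nl_stop("all-zero sample(s): cannot estimate fractions",
            "nitrilink_input_error")
  }
  n <- nrow(counts); D <- ncol(counts)
  shape <- counts + 1
  with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      g <- matrix(stats::rgamma(n * D, shape = shape), n, D,
                  dimnames = dimnames(counts))
      g / rowSums(g)
    })
  })
}

#' Log-ratio variance matrix
#'
#' `t_ij = Var(log(x_i / x_j))` over samples with the n-1 denominator;
#' symmetric with zero diagonal.
#'
#' @param fractions samples x taxa matrix of strictly positive fractions.
#' @return symmetric D x D matrix.
#' @export
logratio_variance_matrix <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) < 2) {
    nl_stop("need at least 2 samples for a variance", "nitrilink_input_error")
  }
  if (any(fractions <= 0)) {
    nl_stop("fractions must be strictly positive", "nitrilink_input_error")
  }
  L <- log(fractions)
  C <- stats::cov(L)
  v <- diag(C)
  T <- outer(v, v, "+") - 2 * C
  T[T < 0] <- 0                       # numerical guard
  diag(T) <- 0
  dimnames(T) <- list(colnames(fractions), colnames(fractions))
  T
}

#' Basis variances and correlations under the sparsity assumption
#'
#' Solves the SparCC linear system: with `t_i = sum_{j != i} t_ij` and the
#' sparsity assumption `sum_{j != i} rho_ij ~ 0`,
#' `t_i = (D - 2) omega_i + sum_j omega_j`, then
#' `rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))` clamped
#' to [-1, 1]. The most strongly correlated pair exceeding
#' `exclusion_threshold` is then excluded from the sums (adjusting the system
#' coefficients) and the system re-solved, up to `max_exclusions` rounds.
#'
#' @param T log-ratio variance matrix from [logratio_variance_matrix()];
#'   needs D >= 4 taxa.
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded each round.
#' @param max_exclusions maximum exclusion rounds.
#' @return list with `omega` (basis variances, floored at a tiny positive
#'   value if the solution goes negative), `rho` (correlation matrix) and
#'   `excluded` (m x 2 matrix of excluded pair indices).
#' @export
basis_correlations <- function(T, exclusion_threshold = 0.1,
                               max_exclusions = 10L) {
  T <- as.matrix(T)
  D <- ncol(T)
  if (D < 4) {
    nl_stop(paste("SparCC approximation needs >= 4 taxa;",
                  "report raw log-ratio variances instead"),
            "nitrilink_input_error")
  }
  M <- matrix(1, D, D) + diag(D - 2, D)
  Texc <- T
  excluded <- matrix(integer(0), ncol = 2)
  neg_omega <- FALSE

  solve_round <- function() {
    t_i <- rowSums(Texc)
    omega <- solve(M, t_i)
    if (any(omega <= 0)) {
      neg_omega <<- TRUE
      omega[omega <= 0] <- 1e-10
    }
    rho <- (outer(omega, omega, "+") - T) /
      (2 * sqrt(outer(omega, omega)))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    list(omega = omega, rho = rho)
  }

  est <- solve_round()
  n_excl <- integer(D)                   # exclusions per taxon
  for (round in seq_len(max_exclusions)) {
    a <- abs(est$rho)
    diag(a) <- 0
    if (nrow(excluded)) a[excluded] <- 0   # symmetric entries zeroed below
    if (nrow(excluded)) a[excluded[, 2:1, drop = FALSE]] <- 0
    # keep every taxon with at least 2 unexcluded partners so the system
    # stays well-posed
    saturated <- which(n_excl >= D - 3L)
    a[saturated, ] <- 0; a[, saturated] <- 0
    mx <- which.max(a)
    if (a[mx] <= exclusion_threshold) break
    ij <- arrayInd(mx, dim(a))
    i <- ij[1]; j <- ij[2]
    excluded <- rbind(excluded, c(min(i, j), max(i, j)))
    n_excl[c(i, j)] <- n_excl[c(i, j)] + 1L
    Texc[i, j] <- 0; Texc[j, i] <- 0
    M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
    new_est <- tryCatch(solve_round(), error = function(e) NULL)
    if (is.null(new_est)) break          # singular system: keep previous
    est <- new_est
  }
  if (neg_omega) {
    nl_warn("negative basis variance(s) clamped to a small floor")
  }
  dimnames(est$rho) <- dimnames(T)
  list(omega = stats::setNames(est$omega, colnames(T)), rho = est$rho,
       excluded = excluded)
}

#' SparCC correlation estimate
#'
#' Element-wise mean of [basis_correlations()] over `n_draws` Dirichlet
#' fraction tables.
#'
#' @inheritParams estimate_fractions
#' @inheritParams basis_correlations
#' @return D x D correlation matrix.
#' @export
sparcc <- function(counts, n_draws = 20L, exclusion_threshold = 0.1,
                   max_exclusions = 10L, seed = 1L) {
  fr <- estimate_fractions(counts, n_draws = n_draws, seed = seed)
  rhos <- lapply(fr, function(f) {
    basis_correlations(logratio_variance_matrix(f),
                       exclusion_threshold = exclusion_threshold,
                       max_exclusions = max_exclusions)$rho
  })
  Reduce(`+`, rhos) / length(rhos)
}

#' Two-sided permutation p-values for SparCC correlations
#'
#' Each permutation independently shuffles every taxon's counts across
#' samples (destroying all between-taxon association while preserving
#' marginals) and recomputes rho with a single Dirichlet draw. The add-one
#' estimator `p = (1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_perm)` keeps
#' p > 0.
#'
#' @param counts samples x taxa count matrix.
#' @param rho_obs observed correlation matrix from [sparcc()].
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @inheritParams basis_correlations
#' @return D x D matrix of p-values in `[1/(n_perm+1), 1]`.
#' @export
permutation_pvalues <- function(counts, rho_obs, n_perm = 100L,
                                exclusion_threshold = 0.1,
                                max_exclusions = 10L, seed = 1L) {
  counts <- as.matrix(counts)
  if (n_perm < 1) nl_stop("n_perm must be >= 1", "nitrilink_input_error")
  n <- nrow(counts)
  exceed <- matrix(0L, ncol(counts), ncol(counts))
  abs_obs <- abs(rho_obs)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- apply(counts, 2L, function(x) x[sample.int(n)])
      # permuted null tables routinely trigger the negative-variance clamp;
      # that warning is informative only for observed data
      rho_p <- suppressWarnings(
        sparcc(perm, n_draws = 1L,
               exclusion_threshold = exclusion_threshold,
               max_exclusions = max_exclusions,
               seed = stats::runif(1, 1, 2^30)))
      exceed <- exceed + (abs(rho_p) >= abs_obs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  dimnames(p) <- dimnames(rho_obs)
  p
}

#' Build an association network from a count table
#'
#' Runs [sparcc()] and [permutation_pvalues()] and assembles the canonical
#' edge list. All-zero taxon columns are dropped first with a logged list
#' (taxa absent in a period cannot enter that period's network).
#'
#' @inheritParams sparcc
#' @param n_perm permutations for significance.
#' @return list of class `association_network`: `taxa`, `rho`, `p`, and
#'   `edges` (data.frame taxon_a < taxon_b, rho, p).
#' @export
build_network <- function(counts, n_draws = 20L, n_perm = 100L,
                          exclusion_threshold = 0.1, max_exclusions = 10L,
                          seed = 1L) {
  counts <- as.matrix(counts)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    nl_log("dropping all-zero taxa from network: ",
           paste(colnames(counts)[zero], collapse = ", "))
    counts <- counts[, !zero, drop = FALSE]
  }
  rho <- sparcc(counts, n_draws = n_draws,
                exclusion_threshold = exclusion_threshold,
                max_exclusions = max_exclusions, seed = seed)
  p <- permutation_pvalues(counts, rho, n_perm = n_perm,
                           exclusion_threshold = exclusion_threshold,
                           max_exclusions = max_exclusions, seed = seed + 1L)
  taxa <- colnames(counts)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  a <- taxa[idx[, 1]]; b <- taxa[idx[, 2]]
  swap <- a > b
  edges <- data.frame(taxon_a = ifelse(swap, b, a),
                      taxon_b = ifelse(swap, a, b),
                      rho = rho[idx], p = p[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$taxon_a, edges$taxon_b), ]
  rownames(edges) <- NULL
  structure(list(taxa = taxa, rho = rho, p = p, edges = edges),
            class = "association_network")
}
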