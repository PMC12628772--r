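# Fixtures built in code: tiny tables, hand-made networks, and compositional
# data with a known (log-normal) basis for SparCC oracle checks.

tiny_counts <- function() {
  m <- matrix(c(25, 25, 25, 25,
                100, 0, 0, 0,
                10, 20, 30, 40), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("t1", "t2", "t3", "t4")))
  storage.mode(m) <- "double"
  m
}

# hand-made association network (bypasses SparCC)
fake_network <- function(edges) {
  taxa <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  structure(list(taxa = taxa, rho = NULL, p = NULL, edges = edges),
            class = "association_network")
}

# multinomial counts over a softmax composition with a known multivariate
# normal basis on the log scale; returns counts and the true basis
# correlation matrix
lognormal_counts <- function(n, Sigma, mu = NULL, depth = 5000,
                             seed = 1) {
  D <- ncol(Sigma)
  if (is.null(mu)) mu <- seq(0, 2, length.out = D)
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n * D), n, D) %*% chol(Sigma)
    Y <- sweep(Y, 2L, mu, "+")
    P <- exp(Y) / rowSums(exp(Y))
    counts <- t(apply(P, 1L, function(p) rmultinom(1, depth, p)))
  })
  dimnames(counts) <- list(sprintf("s%04d", seq_len(n)),
                           sprintf("t%02d", seq_len(D)))
  list(counts = counts, rho_true = stats::cov2cor(Sigma))
}

# block basis correlation matrix used for the SparCC oracle
oracle_sigma <- function() {
  S <- diag(10)
  S[1, 2] <- S[2, 1] <- 0.7
  S[3, 4] <- S[4, 3] <- -0.5
  S[5, 6] <- S[6, 5] <- 0.4
  S
}

# adjusted Rand index (for clustering tests)
adj_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  nch2 <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / nch2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# unimodality with plateaus: no strict fall followed by a strict rise
is_unimodal <- function(x, tol = 1e-10) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(TRUE)
  d <- diff(x)
  fell <- FALSE
  for (dd in d) {
    if (dd < -tol) fell <- TRUE
    if (dd > tol && fell) return(FALSE)
  }
  TRUE
}
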