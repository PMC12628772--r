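# Repeated rarefaction, alpha diversity and Bray-Curtis dissimilarity for
# any community slice. Downstream analyses run on the averaged-rarefied
# table; subcommunity slices are taken from it without re-rarefying.

# exact multivariate hypergeometric draw for one sample, vectorized over
# `reps` replicates: sequentially condition each taxon's hypergeometric count
# on the remaining reads
rarefy_one <- function(x, depth, reps) {
  D <- length(x)
  out <- matrix(0, reps, D)
  rem_pop <- rep(sum(x), reps)
  rem_draw <- rep(depth, reps)
  for (i in seq_len(D)) {
    if (x[i] == 0) next
    ki <- stats::rhyper(reps, m = x[i], n = rem_pop - x[i], k = rem_draw)
    out[, i] <- ki
    rem_pop <- rem_pop - x[i]
    rem_draw <- rem_draw - ki
    if (all(rem_draw == 0)) break
  }
  out
}

#' Repeated rarefaction, averaged
#'
#' Subsamples each sample to `depth` reads without replacement (multivariate
#' hypergeometric) `reps` times and averages the replicates. Samples whose
#' total is below `depth` are dropped with a warning. Every retained averaged
#' row sums exactly to `depth`.
#'
#' @param counts samples x taxa integer count matrix.
#' @param depth subsample size (default 36,103 reads).
#' @param reps number of rarefaction replicates (default 100).
#' @param seed integer seed; the stream is split per sample.
#' @return real-valued samples x taxa matrix.
#' @export
rarefy_mean <- function(counts, depth = 36103L, reps = 100L, seed = 1L) {
  assert_count_matrix(counts)
  if (depth < 1) nl_stop("depth must be >= 1", "nitrilink_input_error")
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) {
    nl_stop(sprintf("all %d samples are below the rarefaction depth %d",
                    nrow(counts), depth), "nitrilink_input_error")
  }
  if (any(!keep)) {
    nl_warn(sprintf("dropping %d sample(s) below rarefaction depth %d: %s",
                    sum(!keep), depth,
                    paste(rownames(counts)[!keep], collapse = ", ")))
  }
  counts <- counts[keep, , drop = FALSE]
  totals <- totals[keep]
  out <- counts * 0
  for (s in seq_len(nrow(counts))) {
    if (totals[s] == depth) {          # subsample is the full vector
      out[s, ] <- counts[s, ]
    } else {
      out[s, ] <- with_seed(seed + s, colMeans(
        rarefy_one(counts[s, ], depth, reps)))
    }
  }
  out
}

#' Alpha diversity profile
#'
#' Richness is the number of taxa with abundance > 0; Shannon
#' `H = -sum p log p` in nats; Simpson is the complement `1 - sum p^2`
#' (Gini-Simpson, the common ecology default). An all-zero sample scores 0
#' on all three.
#'
#' @param counts samples x taxa non-negative abundance matrix (raw, rarefied
#'   or averaged-rarefied).
#' @return data.frame with `sample_id`, `richness`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    nl_stop("abundances must be non-negative", "nitrilink_input_error")
  }
  tot <- rowSums(counts)
  res <- t(apply(counts, 1L, function(x) {
    s <- sum(x)
    if (s == 0) return(c(0, 0, 0))
    p <- x[x > 0] / s
    c(sum(x > 0), -sum(p * log(p)), 1 - sum(p^2))
  }))
  data.frame(sample_id = rownames(counts) %||% as.character(seq_along(tot)),
             richness = res[, 1], shannon = res[, 2], simpson = res[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = sum |u - v| / sum (u + v)`; a pair of all-zero samples is
#' defined as 0 with a warning.
#'
#' @param counts samples x taxa abundance matrix with at least 2 samples.
#' @return symmetric matrix with zero diagonal, entries in [0, 1], sample ids
#'   as dimnames.
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (n < 2) nl_stop("need at least 2 samples", "nitrilink_input_error")
  rs <- rowSums(counts)
  D <- matrix(0, n, n,
              dimnames = list(rownames(counts), rownames(counts)))
  zero_pair <- FALSE
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    num <- rowSums(abs(sweep(counts[rest, , drop = FALSE], 2L, counts[i, ])))
    den <- rs[rest] + rs[i]
    bc <- ifelse(den == 0, 0, num / den)
    if (any(den == 0)) zero_pair <- TRUE
    D[i, rest] <- bc
    D[rest, i] <- bc
  }
  if (zero_pair) nl_warn("all-zero sample pair(s): dissimilarity set to 0")
  D
}
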