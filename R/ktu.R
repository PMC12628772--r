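# Re-clustering of amplicon sequence variants (ASVs) into k-mer taxonomic
# units (KTUs): tetranucleotide composition profiles, partitioning around
# medoids, silhouette-based model selection, and count aggregation with the
# medoid ASV as each cluster's representative.

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

#' k-mer composition profile of a DNA sequence
#'
#' Sliding-window count of every k-mer over the 4^k DNA k-mers in fixed
#' lexicographic order. Windows containing `N` are skipped.
#'
#' @param sequence character scalar over {A,C,G,T,N}.
#' @param k k-mer length (default 4: tetranucleotide profiles, the norm for
#'   ~250-bp amplicons).
#' @return named integer vector of length `4^k`.
#' @export
kmer_profile <- function(sequence, k = 4L) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < k) {
    nl_stop(sprintf("sequence length %d is shorter than k = %d", L, k),
            "nitrilink_input_error")
  }
  if (grepl("[^ACGTN]", sequence)) {
    nl_stop("sequence contains characters outside {A,C,G,T,N}",
            "nitrilink_input_error")
  }
  kmers <- substring(sequence, 1:(L - k + 1), k:L)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- table(factor(kmers, levels = all_kmers(k)))
  stats::setNames(as.integer(tab), names(tab))
}

# total distance of every point to its nearest medoid
pam_cost <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1L, min))
}

#' Partitioning around medoids (classical PAM: BUILD + SWAP)
#'
#' Euclidean distance between L2-normalized profile vectors. BUILD greedily
#' seeds medoids; SWAP exchanges (medoid, non-medoid) pairs while total
#' within-cluster distance to medoids decreases. Medoids are always data
#' points and the cost is non-increasing across SWAP steps.
#'
#' @param profiles numeric matrix, one row per object (e.g. k-mer profiles).
#' @param n_clusters number of clusters.
#' @param seed unused (PAM is deterministic); kept for interface stability.
#' @param normalize L2-normalize rows before computing distances (default
#'   TRUE; removes length effects among ASVs of unequal length).
#' @return list with `labels` (1..n_clusters), `medoids` (row indices) and
#'   `cost`.
#' @export
pam_cluster <- function(profiles, n_clusters, seed = NULL, normalize = TRUE) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n_clusters < 1) {
    nl_stop("n_clusters must be >= 1", "nitrilink_input_error")
  }
  if (n_clusters > n) {
    nl_stop("n_clusters exceeds the number of profiles",
            "nitrilink_input_error")
  }
  if (normalize) {
    nrm <- sqrt(rowSums(profiles^2))
    nrm[nrm == 0] <- 1
    profiles <- profiles / nrm
  }
  d <- as.matrix(stats::dist(profiles))

  # BUILD: first medoid minimizes total distance; each next maximizes the
  # decrease in cost
  medoids <- unname(which.min(colSums(d)))
  while (length(medoids) < n_clusters) {
    nearest <- apply(d[, medoids, drop = FALSE], 1L, min)
    cand <- setdiff(seq_len(n), medoids)
    gain <- vapply(cand, function(h) sum(pmax(nearest - d[, h], 0)),
                   numeric(1))
    medoids <- c(medoids, cand[which.max(gain)])
  }
  medoids <- unname(medoids)
  # SWAP to convergence: take the best strictly improving swap each pass
  repeat {
    cur <- pam_cost(d, medoids)
    best <- list(delta = 0)
    for (m in medoids) {
      others <- setdiff(medoids, m)
      for (h in setdiff(seq_len(n), medoids)) {
        delta <- pam_cost(d, c(others, h)) - cur
        if (delta < best$delta - 1e-12) best <- list(delta = delta, m = m, h = h)
      }
    }
    if (is.null(best$m)) break
    medoids <- c(setdiff(medoids, best$m), best$h)
  }
  medoids <- sort(medoids)
  labels <- apply(d[, medoids, drop = FALSE], 1L, which.min)
  list(labels = as.integer(labels), medoids = medoids,
       cost = pam_cost(d, medoids))
}

# mean silhouette width; single cluster is defined as 0
mean_silhouette <- function(d, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(0)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != labels[i]],
                    function(kk) mean(d[i, labels == kk]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Re-cluster ASVs into KTUs and aggregate counts
#'
#' Computes k-mer profiles, scans `cluster_range` with [pam_cluster()], keeps
#' the partition with maximal mean silhouette width (ties broken toward fewer
#' clusters; a single cluster scores 0), sums member-ASV counts per sample
#' into KTU counts, and designates each cluster's medoid ASV as its
#' representative (KTU taxonomy is inherited from the medoid).
#'
#' @param sequences named character vector of ASV sequences.
#' @param counts samples x ASVs count matrix; every taxon needs a sequence.
#' @param k k-mer length.
#' @param cluster_range integer vector of cluster numbers to scan; default
#'   `1:min(20, n_ASVs)`.
#' @return list with `counts` (samples x KTUs), `mapping` (data.frame
#'   asv_id, ktu_id, is_medoid) and `silhouette` (named vector of scanned
#'   scores).
#' @export
cluster_asvs <- function(sequences, counts, k = 4L, cluster_range = NULL) {
  assert_count_matrix(counts)
  asvs <- colnames(counts)
  if (!all(asvs %in% names(sequences))) {
    nl_stop("every count-table taxon needs a sequence",
            "nitrilink_input_error")
  }
  n <- length(asvs)
  if (is.null(cluster_range)) cluster_range <- seq_len(min(20L, n))
  cluster_range <- sort(unique(as.integer(cluster_range)))
  if (any(cluster_range < 1) || any(cluster_range > n)) {
    nl_stop(sprintf("cluster_range must lie in [1, %d]", n),
            "nitrilink_input_error")
  }
  prof <- t(vapply(sequences[asvs], kmer_profile, integer(4^k), k = k))
  nrm <- sqrt(rowSums(prof^2))
  nrm[nrm == 0] <- 1
  d <- as.matrix(stats::dist(prof / nrm))

  sil <- stats::setNames(rep(NA_real_, length(cluster_range)),
                         cluster_range)
  fits <- vector("list", length(cluster_range))
  for (i in seq_along(cluster_range)) {
    fits[[i]] <- pam_cluster(prof, cluster_range[i])
    sil[i] <- mean_silhouette(d, fits[[i]]$labels)
  }
  best <- which.max(sil)            # which.max takes the first max: fewer k
  fit <- fits[[best]]

  # deterministic KTU ids: clusters ordered by their medoid ASV id
  ord <- order(asvs[fit$medoids])
  ktu_ids <- sprintf("ktu%04d", seq_along(ord))
  relabel <- integer(length(fit$medoids))
  relabel[ord] <- seq_along(ord)
  lab <- relabel[fit$labels]
  ktu_counts <- vapply(seq_along(ord), function(j) {
    rowSums(counts[, lab == j, drop = FALSE])
  }, numeric(nrow(counts)))
  if (is.null(dim(ktu_counts))) {
    ktu_counts <- matrix(ktu_counts, nrow = nrow(counts))
  }
  dimnames(ktu_counts) <- list(rownames(counts), ktu_ids)
  medoid_asv <- asvs[fit$medoids][ord]
  mapping <- data.frame(asv_id = asvs, ktu_id = ktu_ids[lab],
                        is_medoid = asvs %in% medoid_asv,
                        stringsAsFactors = FALSE)
  list(counts = ktu_counts, mapping = mapping, silhouette = sil)
}
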