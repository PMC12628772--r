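#' Pipeline configuration
#'
#' Defaults follow the analysis protocol: rarefaction 100 times at a depth of
#' 36,103 reads, SparCC correlation cutoffs 0.1-0.9 at significance < 0.01,
#' the first three PCoA axes as compositional predictors, time lags of 2, 4,
#' 6 and 8 days, and a 1,000-tree random forest.
#'
#' @param rarefaction_depth reads per subsample.
#' @param rarefaction_reps number of rarefaction replicates averaged.
#' @param cutoffs SparCC correlation-coefficient cutoffs, each in (0, 1).
#' @param significance_alpha permutation p-value threshold for network edges.
#' @param n_pcoa_axes number of PCoA axes used as regression predictors.
#' @param lags_days time lags (days) applied to composition scores.
#' @param rf_trees trees in the random-forest regression.
#' @param n_draws,n_perm SparCC Dirichlet draws and permutation count.
#' @param seed integer seed for all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(rarefaction_depth = 36103L,
                            rarefaction_reps = 100L,
                            cutoffs = seq(0.1, 0.9, by = 0.1),
                            significance_alpha = 0.01,
                            n_pcoa_axes = 3L,
                            lags_days = c(2L, 4L, 6L, 8L),
                            rf_trees = 1000L,
                            n_draws = 20L,
                            n_perm = 100L,
                            seed = 1L) {
  cfg <- list(rarefaction_depth = as.integer(rarefaction_depth),
              rarefaction_reps = as.integer(rarefaction_reps),
              cutoffs = as.numeric(cutoffs),
              significance_alpha = significance_alpha,
              n_pcoa_axes = as.integer(n_pcoa_axes),
              lags_days = as.integer(lags_days),
              rf_trees = as.integer(rf_trees),
              n_draws = as.integer(n_draws),
              n_perm = as.integer(n_perm),
              seed = as.integer(seed))
  if (any(cfg$cutoffs <= 0) || any(cfg$cutoffs >= 1)) {
    nl_stop("cutoffs must lie strictly inside (0, 1)",
            "nitrilink_config_error")
  }
  if (cfg$significance_alpha <= 0 || cfg$significance_alpha >= 1) {
    nl_stop("significance_alpha must lie in (0, 1)", "nitrilink_config_error")
  }
  if (cfg$n_pcoa_axes < 1) {
    nl_stop("n_pcoa_axes must be >= 1", "nitrilink_config_error")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a samples-by-taxa count table from TSV
#'
#' Expects a header row of taxon ids and a first column of sample ids.
#'
#' @param path TSV file path.
#' @return numeric matrix (samples x taxa) with unique dimnames.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    nl_stop(sprintf("count table not found: %s", path), "nitrilink_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  taxa <- header[-1]
  if (anyDuplicated(taxa)) {
    nl_stop(sprintf("duplicate taxon column(s) in %s: %s", path,
                    paste(unique(taxa[duplicated(taxa)]), collapse = ", ")),
            "nitrilink_format_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) {
    nl_stop(sprintf("duplicate sample id(s) in %s", path),
            "nitrilink_format_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    nl_stop(sprintf("non-numeric count body in %s", path),
            "nitrilink_format_error")
  }
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- taxa
  if (any(m < 0)) {
    nl_stop(sprintf("negative counts in %s", path), "nitrilink_format_error")
  }
  m
}

#' Write a samples-by-taxa count table to TSV
#'
#' Columns are ordered lexicographically by taxon id and rows chronologically
#' (by existing row order) so output is deterministic and diff-friendly.
#'
#' @param counts samples x taxa matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  assert_count_matrix(counts)
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences over {A,C,G,T,N},
#'   preserving record order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    nl_stop(sprintf("FASTA not found: %s", path), "nitrilink_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(lines[1], ">")) {
    nl_stop(sprintf("%s is not FASTA (empty or missing '>' header)", path),
            "nitrilink_format_error")
  }
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    nl_stop(sprintf("record with empty sequence in %s", path),
            "nitrilink_format_error")
  }
  if (any(grepl("[^ACGTN]", seqs))) {
    nl_stop(sprintf("non-IUPAC (non-ACGTN) characters in %s", path),
            "nitrilink_format_error")
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Read the per-taxon annotation table
#'
#' CSV with columns `taxon_id`, `lineage` and/or `genus`, and logical
#' nitrification-gene flags `amo`, `nxr` (this is the interface to gene
#' prediction tools such as PICRUSt2, whose output is consumed, not produced).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    nl_stop(sprintf("annotation not found: %s", path), "nitrilink_io_error")
  }
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "amo", "nxr")
  if (!all(need %in% names(ann))) {
    nl_stop(sprintf("annotation %s must have columns %s", path,
                    paste(need, collapse = ", ")), "nitrilink_format_error")
  }
  ann$amo <- as.logical(ann$amo)
  ann$nxr <- as.logical(ann$nxr)
  ann
}

#' Read per-sample metadata
#'
#' CSV with columns `sample_id`, `date` (ISO-8601), `period` and any
#' environment/chemistry variables.
#'
#' @param path CSV path.
#' @return data.frame with `date` parsed to `Date`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    nl_stop(sprintf("metadata not found: %s", path), "nitrilink_io_error")
  }
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) {
    nl_stop(sprintf("metadata %s must have a sample_id column", path),
            "nitrilink_format_error")
  }
  if ("date" %in% names(md)) md$date <- as.Date(md$date)
  md
}

#' Write a network edge list as TSV
#'
#' One row per unordered taxon pair with `taxon_a < taxon_b`
#' lexicographically; columns `taxon_a`, `taxon_b`, `rho`, `p`.
#'
#' @param net an `association_network` (see [build_network()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
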