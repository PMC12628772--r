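# High-level driver chaining the pipeline stages on one dataset: per-period
# association networks, the nitrifier guild, cutoff-swept associated
# subcommunities and their cross-period core, and the composition/diversity
# regressions against the nitrification rate.

#' Run the full association-filtered diversity analysis
#'
#' From a (rarefied) count table, per-sample metadata (with `period` and
#' `rate`) and a taxon annotation table: builds a SparCC association network
#' per period on that period's samples only, selects the nitrifier guild,
#' sweeps correlation cutoffs to delineate per-period nitrifier-associated
#' subcommunities and the cross-period core, then fits composition models
#' (Bray-Curtis -> PCoA -> MLR) per period for the per-period sweeps and
#' across all samples for the core, plus diversity models for the total
#' community, the nitrifier guild and the best-cutoff core subcommunity.
#'
#' @param counts samples x taxa abundance matrix (typically the
#'   averaged-rarefied table).
#' @param metadata data.frame with `sample_id`, `period` (1/2), `rate`, and
#'   optionally `date`.
#' @param annotation taxon annotation table (see [select_nitrifiers()]).
#' @param config a [pipeline_config()].
#' @return list with `nitrifiers`, `networks`, `sweeps`, `core`,
#'   `composition` (data.frame over slices/cutoffs/periods), `diversity`,
#'   and `lags` (NULL when no `date` column).
#' @export
analyze_dataset <- function(counts, metadata, annotation,
                            config = pipeline_config()) {
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (anyNA(metadata$sample_id)) {
    nl_stop("metadata does not cover all samples", "nitrilink_input_error")
  }
  rate <- stats::setNames(metadata$rate, metadata$sample_id)
  nitr <- select_nitrifiers(annotation)

  periods <- sort(unique(metadata$period))
  networks <- list(); sweeps <- list()
  for (p in periods) {
    idx <- metadata$period == p
    nl_log(sprintf("building period-%s network (%d samples)", p, sum(idx)))
    net <- build_network(counts[idx, , drop = FALSE],
                         n_draws = config$n_draws, n_perm = config$n_perm,
                         seed = config$seed + as.integer(p))
    networks[[as.character(p)]] <- net
    sweeps[[as.character(p)]] <- cutoff_sweep(
      net, nitr, cutoffs = config$cutoffs,
      alpha = config$significance_alpha, period = p)
  }
  core <- if (length(periods) == 2) {
    core_subcommunity(sweeps[[1]], sweeps[[2]])
  } else sweeps[[1]]

  comp <- list()
  for (p in periods) {
    idx <- metadata$period == p
    cm <- composition_models(rate[idx], counts[idx, , drop = FALSE],
                             sweeps[[as.character(p)]], nitrifiers = nitr,
                             n_axes = config$n_pcoa_axes)
    cm$period <- as.character(p)
    comp[[length(comp) + 1L]] <- cm
  }
  cm <- composition_models(rate, counts, core, nitrifiers = nitr,
                           n_axes = config$n_pcoa_axes)
  cm$period <- "core"
  comp[[length(comp) + 1L]] <- cm
  composition <- do.call(rbind, comp)

  core_rows <- composition$period == "core" & composition$slice == "associated"
  best_cut <- if (any(core_rows & !is.na(composition$adjR2))) {
    composition$cutoff[core_rows][
      which.max(composition$adjR2[core_rows])]
  } else NA_real_

  slices <- list(total = counts,
                 nitrifier = subset_table(counts, nitr))
  if (!is.na(best_cut)) {
    best_set <- core[[which(vapply(core, function(s) s$provenance$cutoff,
                                   numeric(1)) == best_cut)]]
    if (length(best_set$taxa)) {
      slices$associated_core <- subset_table(counts, best_set)
    }
  }
  slices <- Filter(function(m) ncol(m) > 0 && any(m > 0), slices)
  diversity <- do.call(rbind, lapply(names(slices), function(nm) {
    tryCatch(
      diversity_models(rate,
                       stats::setNames(list(alpha_diversity(slices[[nm]])),
                                       nm)),
      error = function(e) {
        nl_log(sprintf("diversity model for slice %s skipped: %s", nm,
                       conditionMessage(e)))
        NULL
      })
  }))

  lags <- NULL
  if ("date" %in% names(metadata) && !is.na(best_cut) &&
      "associated_core" %in% names(slices)) {
    ord <- suppressWarnings(
      pcoa(bray_curtis(slices$associated_core), config$n_pcoa_axes))
    dates <- stats::setNames(as.Date(metadata$date), metadata$sample_id)
    lags <- lag_models(rate, ord$scores, dates,
                       lags = c(0L, config$lags_days))
  }
  list(nitrifiers = nitr, networks = networks, sweeps = sweeps,
       core = core, composition = composition, diversity = diversity,
       lags = lags, best_core_cutoff = best_cut)
}
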