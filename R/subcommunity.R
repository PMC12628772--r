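# Delineation of the nitrifier guild and its association-filtered
# subcommunities: genus + gene-flag selection of nitrifiers, cutoff-swept
# nitrifier-associated sets per period, the cross-period core, and count
# table slicing.

#' Default nitrifier genus list
#'
#' Ammonia oxidizers (Nitrosomonas, Nitrosospira, Nitrosovibrio, Nitrosolobus,
#' Nitrosococcus) and nitrite oxidizers (Nitrobacter, Nitrotoga, Nitrococcus,
#' Nitrospira, Nitrospina, Nitrolancea, Ca. Nitromaritima).
#' @export
nitrifier_genera <- function() {
  c("Nitrosomonas", "Nitrosospira", "Nitrosovibrio", "Nitrosolobus",
    "Nitrosococcus",
    "Nitrobacter", "Nitrotoga", "Nitrococcus", "Nitrospira", "Nitrospina",
    "Nitrolancea", "Ca. Nitromaritima")
}

new_subcommunity <- function(name, taxa, anchor = character(0),
                             cutoff = NA_real_, alpha = NA_real_,
                             period = "all") {
  structure(list(name = name, taxa = sort(unique(taxa)),
                 provenance = list(anchor = anchor, cutoff = cutoff,
                                   alpha = alpha, period = period)),
            class = "subcommunity_set")
}

#' @export
print.subcommunity_set <- function(x, ...) {
  cat(sprintf("<subcommunity '%s': %d taxa (cutoff %s, period %s)>\n",
              x$name, length(x$taxa),
              format(x$provenance$cutoff), format(x$provenance$period)))
  invisible(x)
}

taxa_of <- function(set) if (inherits(set, "subcommunity_set")) set$taxa else set

#' Select the nitrifier subcommunity from an annotation table
#'
#' A taxon qualifies when it (i) carries a predicted `amo` or `nxr` gene flag
#' AND (ii) is classified in a known nitrifier genus. The genus is taken from
#' a `genus` column when present, otherwise parsed from the `g__` field of
#' `lineage`.
#'
#' @param annotation data.frame with `taxon_id`, gene flags `amo`/`nxr`, and
#'   `genus` or `lineage`.
#' @param genera character vector of accepted genera
#'   (default [nitrifier_genera()]).
#' @return a `subcommunity_set` named "nitrifier" (empty with a warning when
#'   nothing qualifies).
#' @export
select_nitrifiers <- function(annotation, genera = nitrifier_genera()) {
  if (!all(c("taxon_id", "amo", "nxr") %in% names(annotation))) {
    nl_stop("annotation needs taxon_id, amo, nxr columns",
            "nitrilink_input_error")
  }
  genus <- if ("genus" %in% names(annotation)) {
    annotation$genus
  } else if ("lineage" %in% names(annotation)) {
    sub("^.*g__", "", annotation$lineage)
  } else {
    nl_stop("annotation needs a genus or lineage column",
            "nitrilink_input_error")
  }
  hit <- (annotation$amo | annotation$nxr) & genus %in% genera
  if (!any(hit)) nl_warn("no taxa met the nitrifier criteria; empty set")
  new_subcommunity("nitrifier", annotation$taxon_id[hit])
}

#' Nitrifier-associated subcommunity at one cutoff
#'
#' Non-nitrifier taxa having at least one network edge to any nitrifier with
#' `|rho| > cutoff` (or `rho > cutoff` when `use_abs = FALSE`) and
#' `p < alpha`. May be empty (as at very high cutoffs); the anchor nitrifiers
#' are excluded from their own associated set by construction.
#'
#' @param network an `association_network` from [build_network()].
#' @param nitrifiers a `subcommunity_set` (or character vector) of anchors.
#' @param cutoff correlation cutoff in (0, 1).
#' @param alpha significance level for the permutation p-value.
#' @param use_abs associate on |rho| (default) or positive rho only.
#' @param period provenance label.
#' @return a `subcommunity_set`.
#' @export
associated_subcommunity <- function(network, nitrifiers, cutoff,
                                    alpha = 0.01, use_abs = TRUE,
                                    period = "all") {
  if (cutoff <= 0 || cutoff >= 1) {
    nl_stop("cutoff must lie in (0, 1)", "nitrilink_input_error")
  }
  anchors <- taxa_of(nitrifiers)
  e <- network$edges
  stat <- if (use_abs) abs(e$rho) else e$rho
  keep <- stat > cutoff & e$p < alpha &
    xor(e$taxon_a %in% anchors, e$taxon_b %in% anchors)
  hits <- unique(c(e$taxon_a[keep], e$taxon_b[keep]))
  hits <- setdiff(hits, anchors)
  new_subcommunity(sprintf("associated_c%.2f", cutoff), hits,
                   anchor = anchors, cutoff = cutoff, alpha = alpha,
                   period = period)
}

#' Sweep association cutoffs
#'
#' One [associated_subcommunity()] per cutoff. Because the retention rule is
#' a threshold on the same statistic, the sets are nested: the set at a
#' higher cutoff is a subset of the set at any lower cutoff.
#'
#' @inheritParams associated_subcommunity
#' @param cutoffs ascending cutoffs (default 0.1-0.9 by 0.1).
#' @return named list, one `subcommunity_set` per cutoff.
#' @export
cutoff_sweep <- function(network, nitrifiers,
                         cutoffs = seq(0.1, 0.9, by = 0.1),
                         alpha = 0.01, use_abs = TRUE, period = "all") {
  if (is.unsorted(cutoffs)) {
    nl_stop("cutoffs must be sorted ascending", "nitrilink_input_error")
  }
  out <- lapply(cutoffs, function(cc) {
    associated_subcommunity(network, nitrifiers, cc, alpha = alpha,
                            use_abs = use_abs, period = period)
  })
  stats::setNames(out, format(cutoffs))
}

#' Core nitrifier-associated subcommunity per cutoff
#'
#' Taxa associated with nitrifiers in BOTH periods: the per-cutoff
#' intersection of the two periods' sweeps (same cutoff grid required).
#'
#' @param sets_p1,sets_p2 results of [cutoff_sweep()] for each period.
#' @return named list of `subcommunity_set`s.
#' @export
core_subcommunity <- function(sets_p1, sets_p2) {
  if (!identical(names(sets_p1), names(sets_p2))) {
    nl_stop("the two sweeps must share the same cutoff grid",
            "nitrilink_input_error")
  }
  out <- lapply(names(sets_p1), function(nm) {
    s1 <- sets_p1[[nm]]
    core <- intersect(s1$taxa, sets_p2[[nm]]$taxa)
    new_subcommunity(sub("associated", "core", s1$name), core,
                     anchor = union(s1$provenance$anchor,
                                    sets_p2[[nm]]$provenance$anchor),
                     cutoff = s1$provenance$cutoff,
                     alpha = s1$provenance$alpha, period = "core")
  })
  stats::setNames(out, names(sets_p1))
}

#' Restrict a count table to a subcommunity
#'
#' @param counts samples x taxa matrix.
#' @param set `subcommunity_set` or character vector of taxon ids; must be a
#'   subset of the table's taxa.
#' @return the table with columns restricted to the set (samples preserved,
#'   values unchanged). An empty set yields a zero-column table with a
#'   warning.
#' @export
subset_table <- function(counts, set) {
  taxa <- taxa_of(set)
  unknown <- setdiff(taxa, colnames(counts))
  if (length(unknown)) {
    nl_stop(paste("taxa not in table:", paste(unknown, collapse = ", ")),
            "nitrilink_input_error")
  }
  if (length(taxa) == 0) nl_warn("empty subcommunity: zero-column table")
  counts[, colnames(counts) %in% taxa, drop = FALSE]
}

#' Write subcommunity memberships as CSV
#'
#' One row per (taxon, cutoff): `taxon_id`, `set_name`, `cutoff`, `period`.
#'
#' @param sets named list of `subcommunity_set`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    if (length(s$taxa) == 0) return(NULL)
    data.frame(taxon_id = s$taxa, set_name = s$name,
               cutoff = s$provenance$cutoff,
               period = as.character(s$provenance$period),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(taxon_id = character(0), set_name = character(0),
                       cutoff = numeric(0), period = character(0))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
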