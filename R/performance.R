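# Nitrification chemistry metrics, qPCR copy-number normalization, and the
# univariate statistics used for the between-period comparison tables.

#' Nitrification production, efficiency and rate
#'
#' Nitrate production is the difference between the sum of organic nitrogen,
#' NH4+-N and NO2--N in the influent and effluent; efficiency divides
#' production by the influent sum; rate divides production by the hydraulic
#' retention time. Negative production (effluent exceeding influent) is
#' passed through with `flag = TRUE` rather than clamped, preserving
#' mass-balance anomalies for QC.
#'
#' @param rec data.frame (or list) with `org_n_in`, `nh4_in`, `no2_in`,
#'   `org_n_out`, `nh4_out`, `no2_out` (mg-N/L) and `hrt` (days); vectorized
#'   over rows.
#' @return data.frame with `production` (mg-N/L), `efficiency` (fraction),
#'   `rate` (mg-N/L/day) and `flag` (negative production).
#' @export
nitrification_metrics <- function(rec) {
  rec <- as.data.frame(rec)
  need <- c("org_n_in", "nh4_in", "no2_in", "org_n_out", "nh4_out",
            "no2_out", "hrt")
  if (!all(need %in% names(rec))) {
    nl_stop(paste("record needs columns:", paste(need, collapse = ", ")),
            "nitrilink_input_error")
  }
  if (any(rec$hrt <= 0)) {
    nl_stop("hydraulic retention time must be > 0", "nitrilink_input_error")
  }
  n_in <- rec$org_n_in + rec$nh4_in + rec$no2_in
  n_out <- rec$org_n_out + rec$nh4_out + rec$no2_out
  if (any(n_in == 0)) {
    nl_stop("zero influent nitrogen sum: efficiency undefined",
            "nitrilink_input_error")
  }
  production <- n_in - n_out
  data.frame(production = production,
             efficiency = production / n_in,
             rate = production / rec$hrt,
             flag = production < 0)
}

#' Cells per mL from gene copies per mL
#'
#' Normalizes qPCR gene abundances by the average copies per genome (e.g.
#' one copy for AOA amoA, 2.5 for Nitrosomonas amoA, one for comammox amoA).
#' Guild totals are plain sums of the per-guild cell abundances.
#'
#' @param copies_per_mL numeric vector of gene copies per mL.
#' @param copies_per_genome average gene copies per genome (> 0), recycled.
#' @return cells per mL.
#' @export
cells_from_copies <- function(copies_per_mL, copies_per_genome) {
  if (any(copies_per_genome <= 0)) {
    nl_stop("copies_per_genome must be > 0", "nitrilink_input_error")
  }
  copies_per_mL / copies_per_genome
}

#' Between-period comparison with normality-gated test choice
#'
#' Shapiro-Wilk normality within each period; if both p > 0.05 an independent
#' t-test is used (pooled variance when the F test of variance homogeneity
#' has p > 0.05, Welch otherwise), else the Wilcoxon rank-sum test. Constant
#' input (normality test undefined) falls back to Wilcoxon with a warning.
#'
#' @param values numeric vector.
#' @param period_labels two-level grouping, same length; >= 3 values per
#'   group.
#' @return list with `test` ("t-test" or "Wilcoxon"), `statistic`, `p`, and
#'   `decision_path` recording the Shapiro-Wilk and F-test p-values.
#' @export
between_period_test <- function(values, period_labels) {
  g <- split(values, period_labels)
  if (length(g) != 2) {
    nl_stop("period_labels must have exactly 2 levels",
            "nitrilink_input_error")
  }
  if (any(lengths(g) < 3)) {
    nl_stop("need >= 3 values per period", "nitrilink_input_error")
  }
  sw <- lapply(g, function(x) {
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  })
  sw_p <- unlist(sw)
  if (anyNA(sw_p)) {
    nl_warn("normality test undefined (constant input): using Wilcoxon")
    normal <- FALSE
  } else {
    normal <- all(sw_p > 0.05)
  }
  f_p <- NA_real_
  if (normal) {
    f_p <- stats::var.test(g[[1]], g[[2]])$p.value
    ht <- stats::t.test(g[[1]], g[[2]], var.equal = f_p > 0.05)
    test <- "t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]]))
    test <- "Wilcoxon"
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       decision_path = list(shapiro_p = sw_p, f_test_p = f_p,
                            pooled = if (normal) f_p > 0.05 else NA))
}

#' Spearman rank-correlation screen
#'
#' Tie-corrected Spearman rho of each variable against a response series,
#' with two-sided p-values. Constant variables are reported with `rho = NA`.
#'
#' @param x_table data.frame or matrix of candidate variables (columns).
#' @param y_series numeric response, same number of observations (>= 4).
#' @return data.frame with `variable`, `rho`, `p`.
#' @export
spearman_screen <- function(x_table, y_series) {
  x_table <- as.data.frame(x_table)
  if (nrow(x_table) != length(y_series) || nrow(x_table) < 4) {
    nl_stop("need paired observations, n >= 4", "nitrilink_input_error")
  }
  rows <- lapply(names(x_table), function(v) {
    x <- x_table[[v]]
    if (stats::sd(x) == 0 || stats::sd(y_series) == 0) {
      return(data.frame(variable = v, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y_series, method = "spearman", exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Per-period summary statistics table
#'
#' Mean and SD of each variable per period plus the [between_period_test()]
#' decision and p-value, mirroring the usual operating-summary layout.
#'
#' @param metadata data.frame with a `period` column.
#' @param variables character vector of numeric columns to summarize.
#' @return data.frame with one row per variable.
#' @export
period_summary <- function(metadata, variables) {
  rows <- lapply(variables, function(v) {
    x <- metadata[[v]]
    bt <- between_period_test(x, metadata$period)
    g <- split(x, metadata$period)
    data.frame(variable = v,
               mean_p1 = mean(g[[1]]), sd_p1 = stats::sd(g[[1]]),
               mean_p2 = mean(g[[2]]), sd_p2 = stats::sd(g[[2]]),
               test = bt$test, p = bt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
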