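#' Configuration for the synthetic activated-sludge community generator
#'
#' Builds a validated configuration for [simulate_dataset()] and friends. The
#' generator emulates the statistical structure the downstream analysis
#' assumes: two operating periods with shifted environmental means, a small
#' chemolithoautotrophic nitrifier guild responding to ammonium and inorganic
#' carbon, non-nitrifying taxa correlated with the nitrifiers at planted
#' strengths, independent "noise" taxa carrying their own community drift, and
#' a nitrification-rate series driven by the associated taxa.
#'
#' Defaults mirror a full-scale anoxic/oxic plant sampled daily over two
#' periods (44 and 48 days separated by a 33-day gap), with per-period
#' environmental means and SDs for inorganic carbon (mg/L), ammonium (mg-N/L),
#' temperature (deg C) and salinity (permil) taken from the two-period summary
#' statistics of such a plant.
#'
#' @param n_days_period1,n_days_period2 number of sampled days per period.
#' @param n_nitrifiers,n_associates,n_noise taxon counts per ecological role.
#' @param association_strengths target latent correlation in (0, 1] between
#'   each associate and its anchor nitrifier; length `n_associates`.
#' @param depth sequencing reads per sample (multinomial total).
#' @param env_means,env_sds named lists (`period1`, `period2`) of per-period
#'   means/SDs for `IC`, `NH4`, `temperature`, `salinity`.
#' @param env_ar1 lag-1 autocorrelation of each environmental series, in [0,1).
#' @param rate_weights per-associate contribution (mg-N/L/day per unit relative
#'   abundance) to the nitrification rate.
#' @param rate_intercept baseline nitrification rate (mg-N/L/day).
#' @param rate_noise_sd SD of Gaussian noise on the rate series (mg-N/L/day).
#' @param seed integer seed; all outputs are deterministic given the config.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_days_period1 = 44L,
                       n_days_period2 = 48L,
                       n_nitrifiers = 6L,
                       n_associates = 15L,
                       n_noise = 90L,
                       association_strengths = seq(0.3, 0.9,
                                                   length.out = n_associates),
                       depth = 50000L,
                       env_means = list(
                         period1 = c(IC = 92.5, NH4 = 44.4,
                                     temperature = 34.4, salinity = 1.7),
                         period2 = c(IC = 62.7, NH4 = 70.7,
                                     temperature = 31.8, salinity = 1.7)),
                       env_sds = list(
                         period1 = c(IC = 12.5, NH4 = 12.9,
                                     temperature = 1.5, salinity = 0.2),
                         period2 = c(IC = 7.0, NH4 = 29.6,
                                     temperature = 1.1, salinity = 0.3)),
                       env_ar1 = 0.6,
                       rate_weights = rep(80, n_associates),
                       rate_intercept = 10,
                       rate_noise_sd = 1.5,
                       seed = 1L) {
  cfg <- list(
    n_days_period1 = as.integer(n_days_period1),
    n_days_period2 = as.integer(n_days_period2),
    n_nitrifiers = as.integer(n_nitrifiers),
    n_associates = as.integer(n_associates),
    n_noise = as.integer(n_noise),
    association_strengths = as.numeric(association_strengths),
    depth = as.integer(depth),
    env_means = env_means,
    env_sds = env_sds,
    env_ar1 = env_ar1,
    rate_weights = as.numeric(rate_weights),
    rate_intercept = rate_intercept,
    rate_noise_sd = rate_noise_sd,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) nl_stop(paste0("invalid sim_config: ", msg),
                               "nitrilink_config_error")
  with(cfg, {
    if (n_days_period1 < 1 || n_days_period2 < 0) bad("day counts")
    if (n_nitrifiers < 0 || n_associates < 0 || n_noise < 0) {
      bad("taxon counts must be >= 0")
    }
    if (depth < 1) bad("depth must be >= 1")
    if (length(association_strengths) != n_associates) {
      bad("association_strengths length must equal n_associates")
    }
    if (n_associates > 0 &&
        (any(association_strengths <= 0) || any(association_strengths > 1))) {
      bad("association_strengths must lie in (0, 1]")
    }
    if (length(rate_weights) != n_associates) {
      bad("rate_weights length must equal n_associates")
    }
    if (env_ar1 < 0 || env_ar1 >= 1) bad("env_ar1 must lie in [0, 1)")
    if (n_associates > 0 && n_nitrifiers == 0) {
      bad("associates require at least one nitrifier anchor")
    }
    vars <- c("IC", "NH4", "temperature", "salinity")
    for (p in c("period1", "period2")) {
      if (!all(vars %in% names(env_means[[p]])) ||
          !all(vars %in% names(env_sds[[p]]))) {
        bad(sprintf("env_means/env_sds$%s must name %s", p,
                    paste(vars, collapse = ", ")))
      }
      if (any(env_sds[[p]][vars] < 0)) bad("env_sds must be >= 0")
    }
  })
  invisible(cfg)
}

ENV_VARS <- c("IC", "NH4", "temperature", "salinity")

sim_days <- function(cfg) {
  # period 2 starts after a 33-day unsampled gap, mirroring a plant campaign
  # with a mid-summer hiatus
  d1 <- seq_len(cfg$n_days_period1)
  d2 <- if (cfg$n_days_period2 > 0) {
    cfg$n_days_period1 + 33L + seq_len(cfg$n_days_period2)
  } else integer(0)
  data.frame(
    sample_id = sprintf("d%03d", c(d1, d2)),
    day = c(d1, d2),
    date = as.Date("2018-05-01") + c(d1, d2) - 1L,
    period = rep(1:2, c(cfg$n_days_period1, cfg$n_days_period2)),
    stringsAsFactors = FALSE)
}

#' Simulate the environmental time series
#'
#' Each variable follows a stationary first-order autoregressive process
#' around its period mean: `x[t] = mu[t] + phi * (x[t-1] - mu[t-1]) +
#' sqrt(1 - phi^2) * sd[t] * eps`, so the marginal SD equals the configured
#' per-period SD and the lag-1 autocorrelation equals `env_ar1`.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per sampled day: `sample_id`, `day`,
#'   `date`, `period` and the four environmental variables.
#' @export
simulate_environment <- function(config) {
  validate_sim_config(config)
  days <- sim_days(config)
  n <- nrow(days)
  phi <- config$env_ar1
  with_seed(config$seed, {
    for (v in ENV_VARS) {
      mu <- ifelse(days$period == 1, config$env_means$period1[[v]],
                   config$env_means$period2[[v]])
      sdv <- ifelse(days$period == 1, config$env_sds$period1[[v]],
                    config$env_sds$period2[[v]])
      x <- numeric(n)
      x[1] <- mu[1] + sdv[1] * stats::rnorm(1)
      if (n > 1) {
        eps <- stats::rnorm(n - 1)
        for (t in 2:n) {
          x[t] <- mu[t] + phi * (x[t - 1] - mu[t - 1]) +
            sqrt(1 - phi^2) * sdv[t] * eps[t - 1]
        }
      }
      days[[v]] <- x
    }
  })
  days
}

# deterministic taxon ids per role, zero-padded for stable lexicographic order
sim_taxon_ids <- function(cfg) {
  list(nit = sprintf("nit%02d", seq_len(cfg$n_nitrifiers)),
       asc = sprintf("asc%02d", seq_len(cfg$n_associates)),
       noi = sprintf("noi%02d", seq_len(cfg$n_noise)))
}

HETEROTROPH_GENERA <- c(
  "Sphingobium", "Gemmata", "Defluviicoccus", "Reyranella", "Pirellula",
  "Saprospira", "Chitinophaga", "Flavobacterium", "Zoogloea", "Thauera",
  "Acidovorax", "Dechloromonas", "Rhodobacter", "Novosphingobium",
  "Terrimonas")

#' Simulate taxon count table with planted association structure
#'
#' Latent log-abundances: each nitrifier responds linearly to standardized
#' ammonium and inorganic carbon (plus residual noise); each associate `j` is
#' `rho_j * s + sqrt(1 - rho_j^2) * eps` where `s` is its anchor nitrifier's
#' standardized latent, so the latent correlation equals the planted strength
#' in expectation; noise taxa load on two smooth community-drift factors
#' independent of the nitrifier guild. Compositions are softmax-transformed
#' latents over log base abundances; counts are drawn multinomially per sample
#' at the configured depth, so every sample sums exactly to `depth`.
#'
#' @param config a [sim_config()].
#' @param env environment table from [simulate_environment()]; must cover all
#'   sampled days.
#' @return list with `counts` (samples x taxa integer matrix), `annotation`
#'   (taxon_id, lineage, genus, amo, nxr), and `truth` (taxon_id, role,
#'   planted_correlation, anchor, rate_weight).
#' @export
simulate_counts <- function(config, env) {
  validate_sim_config(config)
  days <- sim_days(config)
  if (!all(days$sample_id %in% env$sample_id)) {
    nl_stop("env does not cover all sampled days", "nitrilink_config_error")
  }
  env <- env[match(days$sample_id, env$sample_id), ]
  n <- nrow(env)
  ids <- sim_taxon_ids(config)
  taxa <- c(ids$nit, ids$asc, ids$noi)
  D <- length(taxa)
  if (config$depth < D) {
    nl_warn(sprintf("depth (%d) is below the number of taxa (%d)",
                    config$depth, D))
  }
  s_nh4 <- zscore(env$NH4)
  s_ic <- zscore(env$IC)
  s_temp <- zscore(env$temperature)

  with_seed(config$seed + 1000L, {
    Z <- matrix(0, n, D, dimnames = list(days$sample_id, taxa))
    # nitrifiers: weak linear response to standardized NH4 and IC plus a
    # dominant idiosyncratic autocorrelated component (guild dynamics are
    # driven by more than the measured chemistry)
    if (config$n_nitrifiers > 0) {
      b_nh4 <- stats::runif(config$n_nitrifiers, 0.3, 0.6)
      b_ic <- stats::runif(config$n_nitrifiers, 0.2, 0.4)
      for (i in seq_len(config$n_nitrifiers)) {
        own <- zscore(as.numeric(stats::arima.sim(list(ar = 0.6), n)))
        Z[, ids$nit[i]] <- b_nh4[i] * s_nh4 + b_ic[i] * s_ic + own
      }
    }
    # associates: planted correlation with a round-robin anchor nitrifier
    anchors <- if (config$n_associates > 0) {
      ids$nit[((seq_len(config$n_associates) - 1L) %% config$n_nitrifiers) + 1L]
    } else character(0)
    for (j in seq_len(config$n_associates)) {
      rho <- config$association_strengths[j]
      s <- zscore(Z[, anchors[j]])
      Z[, ids$asc[j]] <- rho * s + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    # noise taxa: environmentally filtered (taxon-specific response to NH4,
    # IC and temperature) plus loadings on smooth community-drift factors
    # and idiosyncratic noise; independent of the nitrifier guild's own
    # dynamics, so the broad community's dominant axes are rate-irrelevant
    if (config$n_noise > 0) {
      f <- vapply(1:3, function(k) {
        zscore(as.numeric(stats::arima.sim(list(ar = 0.9), n)))
      }, numeric(n))
      lam <- stats::runif(config$n_noise, 0.4, 0.8) *
        sample(c(-1, 1), config$n_noise, replace = TRUE)
      which_f <- sample.int(3L, config$n_noise, replace = TRUE)
      gam <- matrix(stats::rnorm(config$n_noise * 3, 0, 0.4),
                    config$n_noise, 3)
      env_sig <- cbind(s_nh4, s_ic, s_temp)
      for (k in seq_len(config$n_noise)) {
        resid_var <- max(0.1, 1 - lam[k]^2 - sum(gam[k, ]^2))
        Z[, ids$noi[k]] <- as.numeric(env_sig %*% gam[k, ]) +
          lam[k] * f[, which_f[k]] +
          sqrt(resid_var) * stats::rnorm(n)
      }
    }
    # log base abundances: a log-normal rank-abundance curve spanning orders
    # of magnitude, so rare taxa sit near the detection limit and richness
    # varies between samples. Nitrifiers are a small guild (~1-3% total),
    # associates moderately abundant, noise taxa fill the remainder.
    b_nit <- exp(stats::rnorm(config$n_nitrifiers, log(0.003), 1.0))
    b_asc <- exp(stats::rnorm(config$n_associates, log(0.004), 1.0))
    w_noi <- exp(stats::rnorm(config$n_noise, 0, 2))
    rem <- max(0.05, 1 - sum(b_nit) - sum(b_asc))
    b_noi <- if (config$n_noise > 0) rem * w_noi / sum(w_noi) else numeric(0)
    alpha <- log(c(b_nit, b_asc, b_noi))
    P <- softmax_rows(sweep(Z, 2L, alpha, "+"))
    counts <- t(apply(P, 1L, function(p) {
      as.integer(stats::rmultinom(1L, config$depth, p))
    }))
    dimnames(counts) <- list(days$sample_id, taxa)

    genus <- c(
      rep(c("Nitrosomonas", "Nitrospira"),
          length.out = config$n_nitrifiers),
      sample(HETEROTROPH_GENERA, config$n_associates, replace = TRUE),
      sample(HETEROTROPH_GENERA, config$n_noise, replace = TRUE))
  })

  role <- rep(c("nitrifier", "associate", "noise"),
              c(config$n_nitrifiers, config$n_associates, config$n_noise))
  amo <- role == "nitrifier" & genus == "Nitrosomonas"
  nxr <- role == "nitrifier" & genus == "Nitrospira"
  lineage <- ifelse(
    genus == "Nitrosomonas",
    "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Nitrosomonadales;f__Nitrosomonadaceae;g__Nitrosomonas",
    ifelse(genus == "Nitrospira",
           "d__Bacteria;p__Nitrospirota;c__Nitrospiria;o__Nitrospirales;f__Nitrospiraceae;g__Nitrospira",
           paste0("d__Bacteria;p__Unassigned;c__Unassigned;o__Unassigned;f__Unassigned;g__", genus)))
  annotation <- data.frame(
    taxon_id = taxa, lineage = lineage, genus = genus,
    amo = amo, nxr = nxr, stringsAsFactors = FALSE)
  anchors_full <- rep(NA_character_, D)
  planted <- rep(NA_real_, D)
  rate_w <- rep(0, D)
  if (config$n_associates > 0) {
    idx <- config$n_nitrifiers + seq_len(config$n_associates)
    anchors_full[idx] <-
      ids$nit[((seq_len(config$n_associates) - 1L) %% config$n_nitrifiers) + 1L]
    planted[idx] <- config$association_strengths
    rate_w[idx] <- config$rate_weights
  }
  truth <- data.frame(
    taxon_id = taxa, role = role, planted_correlation = planted,
    anchor = anchors_full, rate_weight = rate_w, stringsAsFactors = FALSE)
  list(counts = counts, annotation = annotation, truth = truth)
}

#' Simulate the nitrification-rate series
#'
#' `rate(day) = intercept + sum_taxa rate_weight * relative abundance +
#' N(0, rate_noise_sd)`. With `rate_noise_sd = 0` the series is an exact dot
#' product of the relative-abundance matrix with the ground-truth weights.
#'
#' @param config a [sim_config()].
#' @param counts samples x taxa count matrix.
#' @param truth ground-truth data.frame from [simulate_counts()].
#' @return data.frame with `sample_id` and `rate` (mg-N/L/day).
#' @export
simulate_rate <- function(config, counts, truth) {
  validate_sim_config(config)
  if (!setequal(colnames(counts), truth$taxon_id)) {
    nl_stop("counts and truth must share the same taxa",
            "nitrilink_config_error")
  }
  w <- truth$rate_weight[match(colnames(counts), truth$taxon_id)]
  rel <- counts / rowSums(counts)
  base <- config$rate_intercept + as.numeric(rel %*% w)
  noise <- with_seed(config$seed + 2000L,
                     stats::rnorm(nrow(counts), 0, config$rate_noise_sd))
  data.frame(sample_id = rownames(counts), rate = base + noise,
             stringsAsFactors = FALSE)
}

# random representative ~250-bp sequences; members of a role share no
# structure (sequence content is irrelevant to the planted statistics)
simulate_sequences <- function(config, taxa) {
  with_seed(config$seed + 3000L, {
    stats::setNames(vapply(taxa, function(t) {
      paste(sample(c("A", "C", "G", "T"), 250L, replace = TRUE),
            collapse = "")
    }, character(1)), taxa)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_environment()], [simulate_counts()] and [simulate_rate()]
#' and assembles the per-sample metadata table (date, period, environment,
#' rate). Identical configs (including seed) yield byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `env`, `counts`, `annotation`, `truth`,
#'   `rate`, `metadata`, `sequences`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  env <- simulate_environment(config)
  cm <- simulate_counts(config, env)
  rate <- simulate_rate(config, cm$counts, cm$truth)
  metadata <- merge(env, rate, by = "sample_id", sort = FALSE)
  metadata <- metadata[order(metadata$day), ]
  rownames(metadata) <- NULL
  list(config = config, env = env, counts = cm$counts,
       annotation = cm$annotation, truth = cm$truth, rate = rate,
       metadata = metadata,
       sequences = simulate_sequences(config, colnames(cm$counts)))
}

#' Write a synthetic dataset to a directory
#'
#' Writes `counts.tsv` (samples as rows), `annotation.csv`, `metadata.csv`,
#' `ground_truth.csv`, `sequences.fasta` and `config.json` under `dir`.
#'
#' @param ds result of [simulate_dataset()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(ds$counts, file.path(dir, "counts.tsv"))
  utils::write.csv(ds$annotation, file.path(dir, "annotation.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  write_fasta(ds$sequences, file.path(dir, "sequences.fasta"))
  cfg <- ds$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
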