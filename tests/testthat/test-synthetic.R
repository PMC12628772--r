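# synthetic community generator: AR(1) environment, planted correlations,
# multinomial closure, rate model, determinism

test_that("degenerate AR(1): zero noise pins every day at its period mean", {
  cfg <- sim_config(n_days_period1 = 5, n_days_period2 = 4,
                    env_ar1 = 0,
                    env_sds = list(period1 = c(IC = 0, NH4 = 0,
                                               temperature = 0, salinity = 0),
                                   period2 = c(IC = 0, NH4 = 0,
                                               temperature = 0, salinity = 0)))
  env <- simulate_environment(cfg)
  expect_equal(env$IC, ifelse(env$period == 1, 92.5, 62.7))
  expect_equal(env$NH4, ifelse(env$period == 1, 44.4, 70.7))
})

test_that("same config + same seed gives identical outputs", {
  cfg <- sim_config(n_days_period1 = 10, n_days_period2 = 10,
                    n_noise = 10, depth = 2000, seed = 42)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("AR(1) lag-1 autocorrelation matches theory at long horizon", {
  cfg <- sim_config(n_days_period1 = 10000, n_days_period2 = 0,
                    n_associates = 0, rate_weights = numeric(0),
                    env_ar1 = 0.8, seed = 3)
  env <- simulate_environment(cfg)
  r1 <- stats::acf(env$IC, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1 - 0.8), 0.05)
})

test_that("multinomial closure: every sample sums to depth", {
  cfg <- sim_config(n_days_period1 = 8, n_days_period2 = 8, n_noise = 20,
                    depth = 1234, seed = 5)
  cm <- simulate_counts(cfg, simulate_environment(cfg))
  expect_true(all(rowSums(cm$counts) == 1234))
  expect_true(all(cm$counts >= 0))
})

test_that("planted correlation 0.9 is visible in log relative abundances", {
  cfg <- sim_config(n_days_period1 = 200, n_days_period2 = 0,
                    n_nitrifiers = 2, n_associates = 1, n_noise = 20,
                    association_strengths = 0.9, rate_weights = 80,
                    depth = 50000, seed = 11)
  cm <- simulate_counts(cfg, simulate_environment(cfg))
  lr <- log(cm$counts + 0.5) - log(rowSums(cm$counts))
  tr <- cm$truth[cm$truth$role == "associate", ]
  expect_gt(cor(lr[, tr$taxon_id], lr[, tr$anchor]), 0.6)
})

test_that("n_associates = 0 leaves only nitrifier and noise roles", {
  cfg <- sim_config(n_days_period1 = 5, n_days_period2 = 0,
                    n_associates = 0, rate_weights = numeric(0),
                    association_strengths = numeric(0), n_noise = 5,
                    depth = 500)
  cm <- simulate_counts(cfg, simulate_environment(cfg))
  expect_setequal(unique(cm$truth$role), c("nitrifier", "noise"))
  expect_true(all(cm$truth$rate_weight == 0))
})

test_that("rate is a noiseless dot product when rate_noise_sd = 0", {
  cfg <- sim_config(n_days_period1 = 10, n_days_period2 = 0, n_noise = 10,
                    depth = 2000, rate_noise_sd = 0, seed = 9)
  cm <- simulate_counts(cfg, simulate_environment(cfg))
  rate <- simulate_rate(cfg, cm$counts, cm$truth)
  w <- cm$truth$rate_weight[match(colnames(cm$counts), cm$truth$taxon_id)]
  manual <- cfg$rate_intercept +
    as.numeric((cm$counts / rowSums(cm$counts)) %*% w)
  expect_equal(rate$rate, manual)

  # all-zero weights give a constant series at the intercept
  cfg0 <- sim_config(n_days_period1 = 6, n_days_period2 = 0,
                     n_associates = 0, rate_weights = numeric(0),
                     association_strengths = numeric(0), n_noise = 5,
                     depth = 500, rate_noise_sd = 0)
  cm0 <- simulate_counts(cfg0, simulate_environment(cfg0))
  r0 <- simulate_rate(cfg0, cm0$counts, cm0$truth)
  expect_equal(r0$rate, rep(cfg0$rate_intercept, 6))
})

test_that("rate regresses on associates better than on noise taxa", {
  wins <- 0L
  for (s in 1:20) {
    ds <- simulate_dataset(sim_config(seed = s))
    rel <- ds$counts / rowSums(ds$counts)
    asc <- ds$truth$taxon_id[ds$truth$role == "associate"]
    noi <- ds$truth$taxon_id[ds$truth$role == "noise"][seq_along(asc)]
    a1 <- summary(lm(ds$metadata$rate ~ rel[, asc]))$adj.r.squared
    a0 <- summary(lm(ds$metadata$rate ~ rel[, noi]))$adj.r.squared
    wins <- wins + (a1 > a0)
  }
  expect_gte(wins, 18L)
})

test_that("planted correlations are recovered in rank across a grid", {
  strengths <- rep(seq(0.1, 0.9, by = 0.1), length.out = 50)
  cfg <- sim_config(n_days_period1 = 200, n_days_period2 = 0,
                    n_nitrifiers = 5, n_associates = 50, n_noise = 20,
                    association_strengths = strengths,
                    rate_weights = rep(80, 50), depth = 50000, seed = 21)
  cm <- simulate_counts(cfg, simulate_environment(cfg))
  lr <- log(cm$counts + 0.5) - log(rowSums(cm$counts))
  tr <- cm$truth[cm$truth$role == "associate", ]
  emp <- vapply(seq_len(nrow(tr)), function(j) {
    cor(lr[, tr$taxon_id[j]], lr[, tr$anchor[j]])
  }, numeric(1))
  expect_gte(cor(tr$planted_correlation, emp, method = "spearman"), 0.9)
})

test_that("invalid configs are rejected", {
  expect_error(sim_config(depth = 0), class = "nitrilink_config_error")
  expect_error(sim_config(env_ar1 = 1), class = "nitrilink_config_error")
  expect_error(sim_config(association_strengths = c(0.5, 0.5)),
               class = "nitrilink_config_error")
  expect_error(sim_config(n_associates = 2,
                          association_strengths = c(0.5, 1.5),
                          rate_weights = c(1, 1)),
               class = "nitrilink_config_error")
})

test_that("write_dataset round-trips counts and metadata", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(sim_config(n_days_period1 = 6, n_days_period2 = 5,
                                    n_noise = 8, depth = 800, seed = 2))
  write_dataset(ds, dir)
  back <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(back[rownames(ds$counts), colnames(ds$counts)], ds$counts)
  md <- read_metadata(file.path(dir, "metadata.csv"))
  expect_equal(md$rate, ds$metadata$rate)
  expect_s3_class(md$date, "Date")
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  expect_setequal(names(seqs), colnames(ds$counts))
})
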