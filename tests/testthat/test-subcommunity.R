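# nitrifier selection, associated subcommunities, cutoff sweeps, core sets

test_that("select_nitrifiers requires both gene flag and genus", {
  ann <- data.frame(
    taxon_id = c("k1", "k2", "k3", "k4"),
    genus = c("Nitrosomonas", "Escherichia", "Nitrospira", "Nitrospira"),
    amo = c(TRUE, TRUE, FALSE, FALSE),
    nxr = c(FALSE, FALSE, FALSE, TRUE))
  s <- select_nitrifiers(ann)
  expect_setequal(s$taxa, c("k1", "k4"))  # k2 fails genus, k3 fails flag

  # genus parsed from lineage when no genus column
  ann2 <- data.frame(taxon_id = "x",
                     lineage = "d__Bacteria;f__Nitrosomonadaceae;g__Nitrosomonas",
                     amo = TRUE, nxr = FALSE)
  expect_equal(select_nitrifiers(ann2)$taxa, "x")

  ann$amo <- FALSE; ann$nxr <- FALSE
  expect_warning(empty <- select_nitrifiers(ann), "no taxa met")
  expect_length(empty$taxa, 0)
})

test_that("associated_subcommunity thresholds rho and gates on p", {
  net <- fake_network(data.frame(
    taxon_a = c("A", "B", "C", "D"), taxon_b = c("N", "N", "N", "A"),
    rho = c(0.75, 0.50, 0.75, 0.99), p = c(0.001, 0.001, 0.05, 0.001)))
  nit <- structure(
    list(name = "nitrifier", taxa = "N",
         provenance = list(anchor = character(0), cutoff = NA, alpha = NA,
                           period = "all")), class = "subcommunity_set")
  s <- associated_subcommunity(net, nit, cutoff = 0.6, alpha = 0.01)
  expect_equal(s$taxa, "A")          # B below cutoff, C fails alpha,
                                     # D-A edge has no nitrifier endpoint
  s9 <- associated_subcommunity(net, nit, cutoff = 0.95)
  expect_length(s9$taxa, 0)          # high cutoff: empty, no error
  expect_error(associated_subcommunity(net, nit, cutoff = 0),
               class = "nitrilink_input_error")
})

test_that("negative correlations count under |rho| but not positive-only", {
  net <- fake_network(data.frame(taxon_a = "A", taxon_b = "N",
                                 rho = -0.8, p = 0.001))
  nit <- structure(list(name = "n", taxa = "N",
                        provenance = list(anchor = character(0), cutoff = NA,
                                          alpha = NA, period = "all")),
                   class = "subcommunity_set")
  expect_equal(associated_subcommunity(net, nit, 0.6)$taxa, "A")
  expect_length(associated_subcommunity(net, nit, 0.6,
                                        use_abs = FALSE)$taxa, 0)
})

test_that("cutoff sweeps are nested on random networks", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      taxa <- sprintf("t%02d", 1:15)
      nit <- taxa[1:3]
      pairs <- t(combn(taxa, 2))
      net <- fake_network(data.frame(
        taxon_a = pairs[, 1], taxon_b = pairs[, 2],
        rho = runif(nrow(pairs), -1, 1), p = runif(nrow(pairs), 0, 0.05)))
      sw <- cutoff_sweep(net, nit, cutoffs = seq(0.1, 0.9, 0.1))
      sizes <- vapply(sw, function(s) length(s$taxa), 1L)
      expect_true(all(diff(sizes) <= 0))
      for (i in seq_len(length(sw) - 1)) {
        expect_true(all(sw[[i + 1]]$taxa %in% sw[[i]]$taxa))
      }
      # nitrifiers never appear in their own associated sets
      expect_false(any(nit %in% unlist(lapply(sw, `[[`, "taxa"))))
    }
  })
})

test_that("core sets are intersections and obey subset laws", {
  mk <- function(taxa, cutoff) structure(
    list(name = "a", taxa = taxa,
         provenance = list(anchor = "N", cutoff = cutoff, alpha = 0.01,
                           period = 1)), class = "subcommunity_set")
  s1 <- list("0.1" = mk(c("A", "B"), 0.1), "0.2" = mk(c("A"), 0.2))
  s2 <- list("0.1" = mk(c("B", "C"), 0.1), "0.2" = mk(c("D"), 0.2))
  core <- core_subcommunity(s1, s2)
  expect_equal(core[["0.1"]]$taxa, "B")
  expect_length(core[["0.2"]]$taxa, 0)   # disjoint -> empty
  for (nm in names(core)) {
    expect_true(all(core[[nm]]$taxa %in% s1[[nm]]$taxa))
    expect_true(all(core[[nm]]$taxa %in% s2[[nm]]$taxa))
  }
  expect_error(core_subcommunity(s1, s2[1]),
               class = "nitrilink_input_error")
})

test_that("subset_table slices columns faithfully", {
  m <- tiny_counts()
  expect_identical(subset_table(m, colnames(m)), m)
  sub <- subset_table(m, c("t2", "t4"))
  expect_identical(sub, m[, c("t2", "t4")])
  expect_warning(z <- subset_table(m, character(0)), "empty")
  expect_equal(ncol(z), 0)
  expect_equal(nrow(z), 3)
  expect_error(subset_table(m, "nope"), class = "nitrilink_input_error")
})

test_that("recall of true associates declines past their planted strengths", {
  cfg <- sim_config(seed = 33)
  ds <- simulate_dataset(cfg)
  p2 <- ds$metadata$sample_id[ds$metadata$period == 2]
  suppressMessages(
    net <- build_network(ds$counts[p2, ], n_draws = 10, n_perm = 100,
                         seed = 34))
  nit <- select_nitrifiers(ds$annotation)
  sw <- cutoff_sweep(net, nit)
  truth_asc <- ds$truth$taxon_id[ds$truth$role == "associate"]
  recall <- vapply(sw, function(s) mean(truth_asc %in% s$taxa), numeric(1))
  expect_gt(mean(recall[1:3]), mean(recall[7:9]))
  expect_true(all(diff(recall) <= 0))
})
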