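test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_counts(sim_config(seed = 3L))
  b <- simulate_counts(sim_config(seed = 3L))
  expect_identical(a$counts, b$counts)
  c <- simulate_counts(sim_config(seed = 4L))
  expect_false(identical(a$counts, c$counts))

  pa <- simulate_reference_panel(panel_sim_config(seed = 3L))
  pb <- simulate_reference_panel(panel_sim_config(seed = 3L))
  expect_identical(pa, pb)
})

test_that("law of large numbers: sample means recover baseline * 2^lfc", {
  # near-Poisson, no depth noise, many animals
  cfg <- sim_config(n_per_group = 10000L,
                    profiles = list(cont = "null", trt = "gthc_like"),
                    dispersion = 1e9, library_size_sd = 0, seed = 5L)
  sim <- simulate_counts(cfg)
  lfc <- attr(sim, "truth")["trt", ]
  for (grp in c("cont", "trt")) {
    mean_obs <- colMeans(sim$counts[sim$groups == grp, marker_genes()])
    shift <- if (grp == "trt") 2^lfc else rep(1, 12)
    expected <- cfg$baseline_mean[marker_genes()] * shift
    expect_lt(max(abs(mean_obs / expected - 1)), 0.01)
  }
})

test_that("NB moments are recovered (mean m, variance m + m^2/k)", {
  cfg <- sim_config(n_per_group = 20000L, profiles = list(a = "null",
                                                          b = "null"),
                    baseline_mean = c(Dazap2 = 1000,
                                      setNames(rep(500, 12), marker_genes())),
                    dispersion = 10, library_size_sd = 0, seed = 6L)
  sim <- simulate_counts(cfg)
  x <- sim$counts[, "Aen"]
  m <- 500; k <- 10
  expect_lt(abs(mean(x) / m - 1), 0.02)
  expect_lt(abs(var(x) / (m + m^2 / k) - 1), 0.05)
})

test_that("preset profiles have the documented shapes", {
  pr <- preset_profiles()
  expect_true(all(unclass(pr$null) == 0))
  up <- names(pr$gthc_like)[unclass(pr$gthc_like) > 0]
  expect_setequal(up, c("Aen", "Bax", "Btg2", "Ccng1", "Gdf15", "Mbd1",
                        "Phlda3", "Tubb4b"))
  expect_length(up, 8L)
  expect_true(all(pr$gthc_like[up] >= 1 & pr$gthc_like[up] <= 3))
  nz <- names(pr$ngthc_like)[unclass(pr$ngthc_like) != 0]
  expect_identical(nz, "Gdf15")
})

test_that("null profile through the pipeline stays near zero", {
  cfg <- sim_config(n_per_group = 5L,
                    profiles = list(cont = "null", trt = "null"), seed = 8L)
  sim <- simulate_counts(cfg)
  r <- ratio_vs_control(normalize_by_gene(log2_transform(sim)), "cont")
  trt <- unclass(r)[attr(r, "groups") == "trt", ]
  se <- apply(trt, 2, sd) / sqrt(nrow(trt))
  expect_true(all(abs(colMeans(trt)) < 3 * pmax(se, 0.05)))
})

test_that("panel generator honors counts, timepoints and covariance", {
  p <- simulate_reference_panel(
    panel_sim_config(n_per_class = c(10L, 14L, 22L),
                     timepoints = c("24h", "29d"), seed = 2L)
  )
  expect_equal(nrow(p), 92L)
  expect_equal(as.vector(table(p$class)[c("GTHC", "NGTHC", "NGTNHC")]),
               c(20L, 28L, 44L))
  expect_setequal(unique(p$time), c("24h", "29d"))
  expect_false(anyDuplicated(p$point_id) > 0)

  # default layout emulates the 124-point reference panel
  expect_equal(nrow(simulate_reference_panel(panel_sim_config(seed = 1L))),
               124L)

  # zero covariance collapses each class onto its mean
  p0 <- simulate_reference_panel(
    panel_sim_config(n_per_class = c(3L, 3L, 3L), timepoints = "24h",
                     class_sds = 0, seed = 2L)
  )
  truth <- attr(p0, "truth")
  for (cl in rownames(truth)) {
    rows <- as.matrix(p0[p0$class == cl, marker_genes()])
    expect_equal(rows, matrix(truth[cl, ], nrow(rows), 12, byrow = TRUE),
                 ignore_attr = TRUE)
  }

  # non-positive-definite covariance is fatal
  bad <- matrix(1, 12, 12); bad[1, 2] <- 2; bad[2, 1] <- 2
  expect_error(
    simulate_reference_panel(panel_sim_config(
      class_sds = list(GTHC = bad, NGTHC = diag(12), NGTNHC = diag(12)),
      seed = 1L)),
    "positive definite", class = "gtx_numeric_error"
  )
})

test_that("fixed score separates a large simulated panel at >99% accuracy", {
  p <- simulate_reference_panel(
    panel_sim_config(n_per_class = c(500L, 500L, 500L), seed = 30L)
  )
  m <- as.matrix(as.data.frame(p)[, marker_genes()])
  rownames(m) <- p$point_id
  sb <- score_batch(m)
  truth <- ifelse(p$class == "GTHC", "GTHC-like", "non-GTHC-like")
  expect_gt(mean(sb$label == truth), 0.99)
})

test_that("config validation catches bad parameters", {
  expect_error(sim_config(n_per_group = 1L), class = "gtx_data_error")
  expect_error(sim_config(dispersion = 0), class = "gtx_data_error")
  expect_error(sim_config(profiles = list(cont = "nope")),
               class = "gtx_data_error")
  expect_error(effect_profile("x", c(Aen = 1)), "missing gene",
               class = "gtx_data_error")
})
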