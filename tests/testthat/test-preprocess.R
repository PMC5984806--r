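test_that("beta-values follow M/(M+U) with missing propagation", {
  U <- matrix(c(500, 1000, 0, 300), 4, 1)
  M <- matrix(c(500, 0, 0, 700), 4, 1)
  probes <- c("cg000001", "cg000002", "cg000003", "cg000004")
  dimnames(U) <- dimnames(M) <- list(probes, "s1")
  ds <- tiny_dataset(n_samples = 1)
  ds$U[probes, ] <- U; ds$M[probes, ] <- M
  beta <- compute_beta(ds)
  expect_equal(beta["cg000001", "s1"], 0.5)   # equal halves
  expect_equal(beta["cg000002", "s1"], 0.0)   # fully unmethylated
  expect_true(is.na(beta["cg000003", "s1"]))  # 0/0 is missing, not 0
  expect_equal(beta["cg000004", "s1"], 0.7)
})

test_that("beta is invariant under common positive rescaling of (U, M)", {
  set.seed(3)
  ds <- tiny_dataset(U = matrix(runif(12, 100, 5000), 6, 2),
                     M = matrix(runif(12, 100, 5000), 6, 2))
  b1 <- compute_beta(ds)
  ds$U <- ds$U * 7.3; ds$M <- ds$M * 7.3
  expect_equal(compute_beta(ds), b1, tolerance = 1e-12)
})

test_that("dye-bias correction recovers an injected multiplicative red bias", {
  sim <- simulate_dataset(simulation_config(n_samples = 6, red_bias = 2,
                                            seed = 21))
  truth <- simulate_dataset(simulation_config(n_samples = 6, red_bias = 1,
                                              seed = 21))
  corrected <- correct_dye_bias(sim$dataset)
  mf <- sim$manifest
  red_probes <- mf$probe_id[mf$channel_design == "typeI_red" &
                            mf$probe_class != "control"]
  tU <- truth$dataset$U[red_probes, ]
  rel_err <- abs(corrected$U[red_probes, ] - tU) / tU
  # judged on well-measured probes; relative error on near-zero
  # intensities (fully methylated loci) is not meaningful
  expect_lt(median(rel_err[tU >= 150]), 0.05)
  # green channel untouched
  grn_probes <- mf$probe_id[mf$channel_design == "typeI_green" &
                            mf$probe_class != "control"]
  expect_equal(corrected$U[grn_probes, ], sim$dataset$U[grn_probes, ])
})

test_that("dye-bias correction is the identity when channels already agree", {
  sim <- simulate_dataset(simulation_config(n_samples = 4, seed = 5))
  ds <- sim$dataset
  # force identical control readings across channels
  pairs <- methylscreen:::dye_bias_pairs(ds$manifest)
  ds$controls_red[pairs$red, ] <- ds$controls_grn[pairs$grn, ]
  out <- correct_dye_bias(ds)
  expect_equal(out$U, ds$U, tolerance = 1e-9)
  expect_equal(out$M, ds$M, tolerance = 1e-9)
})

test_that("dye-bias correction preserves within-channel ranks", {
  sim <- simulate_dataset(simulation_config(n_samples = 4, red_bias = 1.7,
                                            seed = 9))
  out <- correct_dye_bias(sim$dataset)
  mf <- sim$manifest
  red_probes <- mf$probe_id[mf$channel_design == "typeI_red" &
                            mf$probe_class != "control"]
  for (n in 1:4)
    expect_equal(order(out$U[red_probes, n]),
                 order(sim$dataset$U[red_probes, n]))
})

test_that("dye-bias correction skips samples with too few control pairs", {
  ds <- tiny_dataset()  # only negative controls, no staining/extension pairs
  expect_warning(out <- correct_dye_bias(ds), "skipped")
  expect_equal(attr(out, "dye_bias_skipped"), c("s1", "s2"))
  expect_equal(out$U, ds$U)
})

test_that("detection p-values are calibrated against negative controls", {
  ds <- tiny_dataset(neg_level = 100)
  # type II probe at the null mean of its total-intensity background
  ng <- mean(ds$controls_grn[, "s1"]); nr <- mean(ds$controls_red[, "s1"])
  ds$U["cg000001", ] <- ng; ds$M["cg000001", ] <- nr
  # probe far above background
  top <- 10 * max(ds$controls_grn, ds$controls_red)
  ds$U["cg000003", ] <- top; ds$M["cg000003", ] <- top
  p <- detection_pvalues(ds)
  expect_equal(p["cg000001", "s1"], 0.5, tolerance = 0.05)
  expect_lt(p["cg000003", "s1"], 0.01)
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
})

test_that("detection p-values are non-increasing in total intensity", {
  ds <- tiny_dataset(n_samples = 1)
  totals <- c(50, 150, 400, 1200, 5000, 20000)
  ds$U[, 1] <- totals / 2; ds$M[, 1] <- totals / 2
  p <- detection_pvalues(ds)
  # compare within a channel-design class (same null for all type II here)
  t2 <- c("cg000001", "cg000003", "rs0001", "rs0002")
  ord <- order(totals[match(t2, rownames(ds$U))])
  expect_true(all(diff(p[t2, 1][ord]) <= 0))
})

test_that("a signal-collapsed sample exceeds the 1% undetected rule", {
  sim <- simulate_dataset(simulation_config(n_samples = 10,
                                            failed_samples = 4L, seed = 13))
  p <- detection_pvalues(sim$dataset)
  det <- undetected_fraction(p)
  expect_true(det$flagged[4])
  expect_gt(det$fraction_undetected[4], 0.5)
  # Y probes aside, clean samples are essentially fully detected
  not_y <- !rownames(p) %in% probe_subset(sim$manifest, "chrY")
  det_clean <- undetected_fraction(p[not_y, , drop = FALSE])
  expect_false(any(det_clean$flagged[-4]))
})

test_that("detection p-values require negative controls", {
  ds <- tiny_dataset()
  ds$controls_grn <- ds$controls_grn[0, , drop = FALSE]
  ds$controls_red <- ds$controls_red[0, , drop = FALSE]
  expect_error(detection_pvalues(ds), "negative")
})
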