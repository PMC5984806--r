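test_that("normalized intensities are ratios of chromosome means", {
  ds <- tiny_dataset()  # all probes at equal total intensity
  ints <- normalized_chr_intensities(ds)
  expect_equal(ints$tX_norm, c(1, 1))
  expect_equal(ints$tY_norm, c(1, 1))
  # female-like pattern: Y probes at a tenth of the autosomal level
  ds$U["cg000004", ] <- 100; ds$M["cg000004", ] <- 100
  ints <- normalized_chr_intensities(ds)
  expect_equal(ints$tY_norm, c(0.1, 0.1))
})

test_that("normalized intensities are invariant to per-sample rescaling", {
  sim <- simulate_dataset(simulation_config(n_samples = 8, seed = 41))
  ds <- sim$dataset
  i1 <- normalized_chr_intensities(ds)
  ds$U[, 3] <- ds$U[, 3] * 4.2; ds$M[, 3] <- ds$M[, 3] * 4.2
  i2 <- normalized_chr_intensities(ds)
  expect_equal(i2$tX_norm, i1$tX_norm, tolerance = 1e-12)
  expect_equal(i2$tY_norm, i1$tY_norm, tolerance = 1e-12)
})

test_that("Hodges-Lehmann cutoff equals the brute-force pairwise oracle", {
  expect_equal(hodges_lehmann_cutoff(c(2, 4), c("male", "female")), 3)
  expect_equal(hodges_lehmann_cutoff(c(1, 2, 5, 7),
                                     c("male", "male", "female", "female")),
               3.75)  # median of {3, 4, 3.5, 4.5}
  set.seed(6)
  vals <- c(rnorm(90, 1), rnorm(110, 4))
  sex <- c(rep("male", 90), rep("female", 110))
  oracle <- median(outer(vals[sex == "male"], vals[sex == "female"], `+`) / 2)
  expect_identical(hodges_lehmann_cutoff(vals, sex), oracle)
  expect_error(hodges_lehmann_cutoff(c(1, 2), c("male", "male")), "female")
})

test_that("the cutoff resists a large fraction of swapped labels", {
  set.seed(12)
  n <- 100
  true_sex <- rep(c("male", "female"), each = n / 2)
  vals <- ifelse(true_sex == "male", rnorm(n, 1, 0.05), rnorm(n, 4, 0.05))
  clean <- hodges_lehmann_cutoff(vals, true_sex)
  swapped <- true_sex
  swap <- c(sample(which(true_sex == "male"), 20),
            sample(which(true_sex == "female"), 20))  # 40% of each class
  swapped[swap] <- ifelse(true_sex[swap] == "male", "female", "male")
  robust <- hodges_lehmann_cutoff(vals, swapped)
  expect_lt(abs(robust - clean), 0.2)
  expect_true(robust > 1.5 && robust < 3.5)  # still separates the clusters
})

test_that("quadrant logic assigns sex, unclear, and mismatches", {
  ints <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                     tX_norm = c(0.55, 1.00, 1.00, 0.55, 0.75),
                     tY_norm = c(0.90, 0.12, 0.90, 0.12, 0.50))
  res <- predict_sex(ints, cutoff_X = 0.75, cutoff_Y = 0.5,
                     recorded_sex = c("male", "female", "male", "male", "female"))
  expect_equal(res$predicted_sex, c("male", "female", "unclear", "unclear",
                                    "unclear"))  # exact ties are unclear
  expect_equal(res$mismatch, rep(FALSE, 5))
  # recorded female predicted male -> mismatch
  res2 <- predict_sex(ints[1, ], 0.75, 0.5, "female")
  expect_true(res2$mismatch)
  expect_equal(res2$status, "mismatch")
})

test_that("cross-sex label swaps are detected exactly on a synthetic cohort", {
  sim <- simulate_dataset(simulation_config(n_samples = 80, sex_swaps = 4,
                                            seed = 43))
  res <- check_sex(sim$dataset)
  expect_equal(sum(res$mismatch), 4L)
  expect_equal(which(res$mismatch), which(sim$truth$samples$sex_mismatch))
  expect_equal(sum(res$status == "unclear"), 0L)
  # predictions match biological truth everywhere
  expect_equal(res$predicted_sex, sim$truth$samples$true_sex)
})

test_that("sex predictions are invariant to per-sample rescaling", {
  sim <- simulate_dataset(simulation_config(n_samples = 30, seed = 47))
  r1 <- check_sex(sim$dataset)
  ds <- sim$dataset
  ds$U[, 5] <- ds$U[, 5] * 9; ds$M[, 5] <- ds$M[, 5] * 9
  r2 <- check_sex(ds)
  expect_equal(r2$predicted_sex, r1$predicted_sex)
})
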