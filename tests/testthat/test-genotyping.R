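simulate_mixture <- function(n, weights = c(0.3, 0.4, 0.25, 0.05),
                             means = c(0.05, 0.5, 0.95), sd = 0.05,
                             seed = 42) {
  set.seed(seed)
  comp <- sample(1:4, n, replace = TRUE, prob = weights)
  x <- runif(n)  # outlier draws; genotype components overwrite below
  for (k in 1:3) {
    nk <- sum(comp == k)
    m <- means[k]; v <- sd^2
    nu <- m * (1 - m) / v - 1
    x[comp == k] <- rbeta(nk, m * nu, (1 - m) * nu)
  }
  list(x = x, comp = comp)
}

test_that("EM recovers the generating mixture at n = 5000", {
  sim <- simulate_mixture(5000)
  fit <- fit_snp_mixture(sim$x)
  expect_lt(max(abs(fit$means - c(0.05, 0.5, 0.95))), 0.02)
  expect_lt(max(abs(fit$weights - c(0.3, 0.4, 0.25, 0.05))), 0.03)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(diff(fit$means) > 0))  # labeled by ascending mean
})

test_that("EM log-likelihood is monotone across repeated fits", {
  for (seed in 1:3) {
    sim <- simulate_mixture(800, seed = seed)
    fit <- fit_snp_mixture(sim$x)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("mixture fit beats hard k-means assignment in held-out likelihood", {
  sim <- simulate_mixture(3000, seed = 11)
  train <- sim$x[1:2000]; test <- sim$x[2001:3000]
  fit <- fit_snp_mixture(train)
  test_c <- pmin(pmax(test, 1e-6), 1 - 1e-6)
  dens <- cbind(dbeta(test_c, fit$shape1[1], fit$shape2[1]),
                dbeta(test_c, fit$shape1[2], fit$shape2[2]),
                dbeta(test_c, fit$shape1[3], fit$shape2[3]), 1)
  ll_em <- sum(log(dens %*% fit$weights))

  km <- kmeans(train, centers = sort(c(0.05, 0.5, 0.95)))
  ll_km <- 0
  for (k in 1:3) {
    xs <- train[km$cluster == k]
    m <- mean(xs); v <- max(var(xs), 1e-6)
    nu <- m * (1 - m) / v - 1
    w <- length(xs) / length(train)
    ll_km <- ll_km  # per-component hard model evaluated on test below
    assign(paste0("p", k), c(m * nu, (1 - m) * nu, w))
  }
  dens_km <- sapply(1:3, function(k) {
    p <- get(paste0("p", k)); p[3] * dbeta(test_c, p[1], p[2])
  })
  ll_km <- sum(log(rowSums(dens_km)))
  expect_gt(ll_em, ll_km)
})

test_that("degenerate one-cluster data yields the documented behavior", {
  x <- rep(0.5, 200) + rnorm(200, 0, 1e-4)
  x <- pmin(pmax(x, 0), 1)
  res <- tryCatch(fit_snp_mixture(x), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "mixture fit failed")
  } else {
    # all mass must end up in components sitting on the single cluster
    # (labels among coincident components are arbitrary) or in the
    # uniform outlier component
    near_half <- abs(res$means - 0.5) < 0.05
    captured <- sum(res$weights[1:3][near_half]) + res$weights["outlier"]
    expect_gt(captured, 0.95)
  }
})

test_that("posteriors follow Bayes' rule and normalize", {
  sim <- simulate_mixture(2000, seed = 5)
  fit <- fit_snp_mixture(sim$x)
  beta_snp <- matrix(c(0.02, 0.5, 0.97, NA), 4, 1,
                     dimnames = list(paste0("rs", 1:4), "s1"))
  posts <- call_genotypes(fit, beta_snp)
  expect_gt(posts["s1", "rs1", "AA"], 0.9)
  expect_gt(posts["s1", "rs3", "BB"], 0.9)
  sums <- apply(posts[, 1:3, , drop = FALSE], c(1, 2), sum)
  expect_equal(unname(as.vector(sums)), rep(1, 3), tolerance = 1e-8)
  expect_true(all(is.na(posts[, "rs4", ])))
  # hand-computed Bayes rule for one value
  x <- 0.02
  d <- c(dbeta(x, fit$shape1[1], fit$shape2[1]),
         dbeta(x, fit$shape1[2], fit$shape2[2]),
         dbeta(x, fit$shape1[3], fit$shape2[3]), 1) * fit$weights
  expect_equal(unname(posts["s1", "rs1", "AA"]), unname(d[1] / sum(d)),
               tolerance = 1e-10)
  expect_error(call_genotypes(fit, matrix(1.5)), "0, 1")
})

test_that("outlier score is the average log2 odds of the outlier component", {
  calls <- matrix(1L, 2, 4, dimnames = list(c("a", "b"), paste0("rs", 1:4)))
  posts <- hard_posteriors(calls, outlier = 0.5)
  o <- snp_outliers(posts)
  expect_equal(unname(o), c(0, 0))  # p = 0.5 everywhere -> log-odds 0
  posts2 <- hard_posteriors(calls, outlier = 0.2)
  expect_equal(unname(snp_outliers(posts2)), rep(log2(0.2 / 0.8), 2))
  # missing probes are skipped
  posts2["a", 1, ] <- NA
  expect_equal(unname(snp_outliers(posts2))[1], log2(0.2 / 0.8))
})

test_that("clean trimodal cohorts score far below the -4 outlier cutoff", {
  sim <- simulate_dataset(simulation_config(n_samples = 40, seed = 31))
  bs <- compute_beta(sim$dataset)[probe_subset(sim$manifest, "snp"), ]
  fit <- fit_snp_mixture(bs)
  o <- snp_outliers(call_genotypes(fit, bs))
  expect_true(all(o < -4))
})

test_that("agreement is symmetric, bounded, and exact for hard calls", {
  set.seed(8)
  calls <- matrix(sample(1:3, 6 * 20, replace = TRUE), 6, 20,
                  dimnames = list(sprintf("s%d", 1:6), sprintf("rs%02d", 1:20)))
  calls[2, ] <- calls[1, ]            # duplicate pair
  calls[4, ] <- 4L - calls[3, ]       # homozygous-opposite at every probe?
  calls[4, calls[3, ] == 2L] <- sample(c(1L, 3L), sum(calls[3, ] == 2L), TRUE)
  posts <- hard_posteriors(calls)
  donor <- c("d1", "d1", "d2", "d3", "d4", "d5")
  res <- check_snp_agreement(posts, donor)
  p <- res$pairs
  get_pair <- function(a, b) p$agreement[p$sample_a == a & p$sample_b == b |
                                         p$sample_a == b & p$sample_b == a]
  expect_equal(get_pair("s1", "s2"), 1.0)
  frac_match <- mean(calls[3, ] == calls[4, ])
  expect_equal(get_pair("s3", "s4"), frac_match)
  expect_true(all(p$agreement >= 0 & p$agreement <= 1))
  expect_equal(nrow(p), choose(6, 2))
})

test_that("partial outlier mass softly excludes probes from both sides", {
  calls <- matrix(1L, 2, 10, dimnames = list(c("a", "b"), sprintf("rs%02d", 1:10)))
  posts <- hard_posteriors(calls)
  # probe 1 of sample a becomes half outlier: contributes 0.5 to num and den
  posts["a", 1, "AA"] <- 0.5
  posts["a", 1, "outlier"] <- 0.5
  res <- check_snp_agreement(posts, c("d1", "d2"))
  expect_equal(res$pairs$agreement, (9 + 0.5) / (9 + 0.5))
  expect_equal(res$pairs$n_effective, 9.5)
})

test_that("conflicts are classified against donor metadata", {
  calls <- matrix(sample(1:3, 4 * 30, replace = TRUE), 4, 30,
                  dimnames = list(sprintf("s%d", 1:4), sprintf("rs%02d", 1:30)))
  calls[2, ] <- calls[1, ]
  posts <- hard_posteriors(calls)
  # s1/s2 identical but labeled different donors; s3/s4 same donor, unrelated
  res <- check_snp_agreement(posts, c("d1", "d2", "d3", "d3"))
  types <- setNames(res$conflicts$conflict_type,
                    paste(res$conflicts$sample_a, res$conflicts$sample_b))
  expect_equal(unname(types["s1 s2"]), "unexpected_agreement")
  expect_equal(unname(types["s3 s4"]), "unexpected_disagreement")
})

test_that("unrelated-pair agreement matches the Hardy-Weinberg enumeration oracle", {
  # brute force over genotype pairs: P(match) = sum_k HWE(k)^2
  p_allele <- 0.5
  hwe <- c((1 - p_allele)^2, 2 * p_allele * (1 - p_allele), p_allele^2)
  expected <- sum(hwe^2)
  sim <- simulate_dataset(simulation_config(n_samples = 120, seed = 37))
  bs <- compute_beta(sim$dataset)[probe_subset(sim$manifest, "snp"), ]
  posts <- call_genotypes(fit_snp_mixture(bs), bs)
  res <- check_snp_agreement(posts, sim$dataset$samples$donor_id)
  expect_equal(mean(res$pairs$agreement), expected, tolerance = 0.03)
})
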