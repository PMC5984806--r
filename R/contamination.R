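# Quantifying single-source DNA contamination from SNP-probe beta-values.
#
# When a sample is mixed with foreign DNA, its SNP-probe beta-values are
# pulled away from the host genotype's cluster toward the methylation
# level of the foreign DNA at that locus. The generative model is
#
#   beta[n, j] ~ Normal((1 - gamma[n]) * mu[k[n, j]] + gamma[n] * c[j],
#                       (1 - gamma[n]) * sigma[k[n, j]])
#
# with gamma[n] the contamination degree of sample n, c[j] the foreign
# methylation level at SNP j (shared by all samples: the single-source
# assumption), mu/sigma the per-genotype cluster means/sds and k[n, j]
# the latent genotype. Parameters are estimated by a random-walk
# Metropolis sampler with discrete Gibbs updates of the genotypes.

GAMMA_MAX <- 0.99
SIGMA_MIN <- 1e-4

reflect <- function(x, lo, hi) {
  # reflect a random-walk proposal into [lo, hi]
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  lo + ifelse(x > span, 2 * span - x, x)
}

contamination_mean_sd <- function(gamma, cj, mu, sigma, genotypes) {
  g <- matrix(gamma, nrow(genotypes), ncol(genotypes))
  cm <- matrix(cj, nrow(genotypes), ncol(genotypes), byrow = TRUE)
  list(mean = (1 - g) * mu[genotypes] + g * cm,
       sd = (1 - g) * sigma[genotypes])
}

#' Log-likelihood of the contamination model
#'
#' Sum over samples and SNP probes of the normal log-density with mean
#' `(1 - gamma_n) * mu_k + gamma_n * c_j` and standard deviation
#' `(1 - gamma_n) * sigma_k`, where `k` is the genotype of sample n at
#' probe j. Missing beta-values are skipped. With `gamma = 0` this
#' reduces to a plain three-component normal genotype likelihood.
#'
#' @param beta_snp SNP-probe beta matrix (probe x sample).
#' @param gamma per-sample contamination degrees in `[0, 0.99]`.
#' @param cj per-probe foreign-DNA methylation levels in `[0, 1]`.
#' @param mu,sigma genotype cluster means (increasing) and sds (> 0),
#'   length 3 each.
#' @param genotypes integer matrix (sample x probe) with entries 1
#'   (AA), 2 (AB), 3 (BB).
#' @return scalar log-likelihood.
#' @export
contamination_loglik <- function(beta_snp, gamma, cj, mu, sigma, genotypes) {
  B <- t(as.matrix(beta_snp))
  stopifnot(length(gamma) == nrow(B), length(cj) == ncol(B),
            length(mu) == 3L, length(sigma) == 3L,
            identical(dim(genotypes), dim(B)))
  if (any(gamma < 0 | gamma > GAMMA_MAX))
    stop("gamma must lie in [0, 0.99]", call. = FALSE)
  if (any(cj < 0 | cj > 1)) stop("c must lie in [0, 1]", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  ms <- contamination_mean_sd(gamma, cj, mu, sigma, genotypes)
  ll <- stats::dnorm(B, ms$mean, ms$sd, log = TRUE)
  sum(ll[!is.na(B)])
}

#' Fit the contamination model by Metropolis-within-Gibbs sampling
#'
#' Random-walk Metropolis updates (reflected at the parameter bounds)
#' for the contamination degrees `gamma_n`, the foreign methylation
#' levels `c_j` and the genotype cluster parameters `mu_k`, `sigma_k`,
#' interleaved with discrete Gibbs draws of the latent genotypes
#' `k[n, j]` proportional to the component likelihoods. Priors are
#' uniform on `[0, 0.99]` for `gamma`, uniform on `[0, 1]` for `c`, flat
#' order-constrained on `mu`, and half-normal(0.1) on `sigma`. Proposal
#' scales adapt during burn-in toward ~30% acceptance. The whole cohort
#' is fitted jointly; estimates are posterior means over the retained
#' draws. The run is fully reproducible from `seed`.
#'
#' @param beta_snp SNP-probe beta matrix (probe x sample).
#' @param init optional `GenotypePosteriors` used to initialize the
#'   latent genotypes (hard calls) and cluster parameters.
#' @param n_iter total Metropolis iterations (default 10000).
#' @param burn_in iterations discarded before estimation (default 5000).
#' @param thin keep every `thin`-th post-burn-in draw in the stored
#'   chain (default 10).
#' @param seed integer seed.
#' @return A `ContaminationFit`: list with `gamma` (posterior means),
#'   `gamma_ci` (2.5/97.5 posterior percentiles), `c`, `mu`, `sigma`,
#'   `genotypes` (posterior modal assignments), `chain` (thinned gamma
#'   draws), `acceptance_rate` per parameter block, `loglik_trace`.
#' @export
fit_contamination <- function(beta_snp, init = NULL, n_iter = 10000L,
                              burn_in = 5000L, thin = 10L, seed = 1L) {
  B <- t(as.matrix(beta_snp))
  N <- nrow(B); J <- ncol(B)
  if (N < 10L) stop("need at least 10 samples", call. = FALSE)
  if (sum(colSums(!is.na(B)) > 0L) < 20L)
    stop("need at least 20 SNP probes with data", call. = FALSE)
  miss <- is.na(B)
  set.seed(seed)

  # --- initialization ---
  if (!is.null(init)) {
    geno_post <- init[dimnames(B)[[1]] %||% seq_len(N), , 1:3, drop = FALSE]
    K <- apply(geno_post, c(1, 2), function(p) if (anyNA(p)) 2L else which.max(p))
  } else {
    K <- matrix(cut(B, c(-Inf, 0.25, 0.75, Inf), labels = FALSE), N, J)
    K[is.na(K)] <- 2L
  }
  mu <- vapply(1:3, function(k) {
    v <- B[K == k & !miss]
    if (length(v) >= 5L) mean(v) else c(0.05, 0.5, 0.95)[k]
  }, 0)
  mu <- sort(pmin(pmax(mu, 0.01), 0.99))
  sigma <- vapply(1:3, function(k) {
    v <- B[K == k & !miss]
    if (length(v) >= 5L) max(stats::sd(v), 0.01) else 0.05
  }, 0)
  gamma <- rep(0.02, N)
  cj <- rep(0.5, J)

  ll_matrix <- function() {
    ms <- contamination_mean_sd(gamma, cj, mu, sigma, K)
    ll <- stats::dnorm(B, ms$mean, ms$sd, log = TRUE)
    ll[miss] <- 0
    ll
  }
  ll_mat <- ll_matrix()

  prop_sd <- c(gamma = 0.03, c = 0.05, mu = 0.01, sigma = 0.01)
  acc <- rej <- c(gamma = 0, c = 0, mu = 0, sigma = 0)
  adapt_every <- 100L

  n_keep <- floor((n_iter - burn_in) / thin)
  chain_gamma <- matrix(NA_real_, n_keep, N)
  sum_gamma <- numeric(N); sum_c <- numeric(J)
  sum_mu <- sum_sigma <- numeric(3)
  geno_counts <- array(0L, c(N, J, 3L))
  n_post <- 0L
  loglik_trace <- numeric(0)
  kept <- 0L

  for (it in seq_len(n_iter)) {
    # gamma block: samples are conditionally independent
    gamma_p <- reflect(gamma + stats::rnorm(N, 0, prop_sd["gamma"]), 0, GAMMA_MAX)
    ms <- contamination_mean_sd(gamma_p, cj, mu, sigma, K)
    ll_p <- stats::dnorm(B, ms$mean, ms$sd, log = TRUE); ll_p[miss] <- 0
    take <- log(stats::runif(N)) < rowSums(ll_p) - rowSums(ll_mat)
    gamma[take] <- gamma_p[take]
    ll_mat[take, ] <- ll_p[take, ]
    acc["gamma"] <- acc["gamma"] + sum(take); rej["gamma"] <- rej["gamma"] + sum(!take)

    # c block: probes are conditionally independent
    c_p <- reflect(cj + stats::rnorm(J, 0, prop_sd["c"]), 0, 1)
    ms <- contamination_mean_sd(gamma, c_p, mu, sigma, K)
    ll_p <- stats::dnorm(B, ms$mean, ms$sd, log = TRUE); ll_p[miss] <- 0
    take <- log(stats::runif(J)) < colSums(ll_p) - colSums(ll_mat)
    cj[take] <- c_p[take]
    ll_mat[, take] <- ll_p[, take]
    acc["c"] <- acc["c"] + sum(take); rej["c"] <- rej["c"] + sum(!take)

    # mu / sigma blocks, one genotype component at a time
    gmat <- matrix(gamma, N, J)
    cmat <- matrix(cj, N, J, byrow = TRUE)
    for (k in 1:3) {
      sel <- K == k & !miss
      if (!any(sel)) next
      mu_p <- reflect(mu[k] + stats::rnorm(1, 0, prop_sd["mu"]), 0, 1)
      ordered_ok <- all(sort(replace(mu, k, mu_p)) == replace(mu, k, mu_p))
      if (ordered_ok) {
        new_ll <- stats::dnorm(B[sel], (1 - gmat[sel]) * mu_p + gmat[sel] * cmat[sel],
                               (1 - gmat[sel]) * sigma[k], log = TRUE)
        if (log(stats::runif(1)) < sum(new_ll) - sum(ll_mat[sel])) {
          mu[k] <- mu_p; ll_mat[sel] <- new_ll
          acc["mu"] <- acc["mu"] + 1
        } else rej["mu"] <- rej["mu"] + 1
      } else rej["mu"] <- rej["mu"] + 1

      sigma_p <- reflect(sigma[k] + stats::rnorm(1, 0, prop_sd["sigma"]),
                         SIGMA_MIN, 1)
      new_ll <- stats::dnorm(B[sel], (1 - gmat[sel]) * mu[k] + gmat[sel] * cmat[sel],
                             (1 - gmat[sel]) * sigma_p, log = TRUE)
      log_prior_diff <- (sigma[k]^2 - sigma_p^2) / (2 * 0.1^2)  # half-normal(0.1)
      if (log(stats::runif(1)) < sum(new_ll) - sum(ll_mat[sel]) + log_prior_diff) {
        sigma[k] <- sigma_p; ll_mat[sel] <- new_ll
        acc["sigma"] <- acc["sigma"] + 1
      } else rej["sigma"] <- rej["sigma"] + 1
    }

    # genotype Gibbs block via Gumbel-max over the three components
    ll_k <- array(NA_real_, c(N, J, 3L))
    for (k in 1:3)
      ll_k[, , k] <- stats::dnorm(B, (1 - gmat) * mu[k] + gmat * cmat,
                                  (1 - gmat) * sigma[k], log = TRUE)
    gumbel <- -log(-log(stats::runif(N * J * 3L)))
    scored <- ll_k + array(gumbel, c(N, J, 3L))
    K_new <- max.col(matrix(scored, N * J, 3L))
    K <- matrix(K_new, N, J)
    ll_mat <- matrix(ll_k[cbind(rep(seq_len(N), J),
                                rep(seq_len(J), each = N),
                                as.vector(K))], N, J)
    ll_mat[miss] <- 0

    if (!all(is.finite(ll_mat[!miss])))
      stop("contamination sampler produced non-finite likelihood", call. = FALSE)

    # adapt proposal scales toward ~0.3 acceptance during burn-in
    if (it <= burn_in && it %% adapt_every == 0L) {
      rate <- acc / pmax(acc + rej, 1)
      prop_sd <- pmin(pmax(prop_sd * exp(rate - 0.3), 1e-4), 0.5)
      acc[] <- 0; rej[] <- 0
    }

    if (it %% 50L == 0L) loglik_trace <- c(loglik_trace, sum(ll_mat))

    if (it > burn_in) {
      n_post <- n_post + 1L
      sum_gamma <- sum_gamma + gamma
      sum_c <- sum_c + cj
      sum_mu <- sum_mu + mu
      sum_sigma <- sum_sigma + sigma
      geno_counts[cbind(rep(seq_len(N), J), rep(seq_len(J), each = N),
                        as.vector(K))] <-
        geno_counts[cbind(rep(seq_len(N), J), rep(seq_len(J), each = N),
                          as.vector(K))] + 1L
      if ((it - burn_in) %% thin == 0L && kept < n_keep) {
        kept <- kept + 1L
        chain_gamma[kept, ] <- gamma
      }
    }
  }

  rate <- acc / pmax(acc + rej, 1)
  if (any(rate < 0.05 | rate > 0.95))
    warning("acceptance rate outside [0.05, 0.95] for block(s): ",
            paste(names(rate)[rate < 0.05 | rate > 0.95], collapse = ", "))

  sample_ids <- dimnames(B)[[1]]
  gamma_hat <- sum_gamma / n_post
  names(gamma_hat) <- sample_ids
  ci <- apply(chain_gamma[seq_len(kept), , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  geno_mode <- max.col(matrix(geno_counts, N * J, 3L))

  structure(list(
    gamma = gamma_hat,
    gamma_ci = t(ci),
    c = sum_c / n_post,
    mu = sum_mu / n_post,
    sigma = sum_sigma / n_post,
    genotypes = matrix(geno_mode, N, J, dimnames = dimnames(B)),
    chain = chain_gamma[seq_len(kept), , drop = FALSE],
    acceptance_rate = rate,
    loglik_trace = loglik_trace,
    n_iter = n_iter, burn_in = burn_in, seed = seed
  ), class = "ContaminationFit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ContaminationFit <- function(x, ...) {
  cat("ContaminationFit:", length(x$gamma), "samples,",
      x$n_iter, "iterations (", x$burn_in, "burn-in )\n")
  cat("  gamma: mean", round(mean(x$gamma), 4),
      "range", paste(round(range(x$gamma), 4), collapse = "-"), "\n")
  cat("  acceptance:", paste(sprintf("%s=%.2f", names(x$acceptance_rate),
                                     x$acceptance_rate), collapse = " "), "\n")
  invisible(x)
}

#' Contamination report table
#'
#' @param fit a `ContaminationFit`.
#' @return data.frame with `sample_id`, `gamma_hat`, `gamma_ci_low`,
#'   `gamma_ci_high`.
#' @export
contamination_report <- function(fit) {
  data.frame(
    sample_id = names(fit$gamma) %||% seq_along(fit$gamma),
    gamma_hat = unname(fit$gamma),
    gamma_ci_low = unname(fit$gamma_ci[, 1]),
    gamma_ci_high = unname(fit$gamma_ci[, 2]),
    stringsAsFactors = FALSE
  )
}
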