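# Genetic fingerprinting from SNP-probe beta-values.
#
# Beta-values of the "rs" probes cluster at ~0, ~0.5 and ~1 according to
# the underlying genotype (AA/AB/BB). A four-component mixture --- three
# Beta distributions plus a uniform outlier component --- is fitted by EM
# to the beta-values pooled across all SNP probes and samples. Posterior
# genotype probabilities then drive a soft pairwise identity check and a
# per-sample outlier score.

GENOTYPE_LEVELS <- c("AA", "AB", "BB", "outlier")
BETA_EPS <- 1e-6

clamp_beta <- function(x) pmin(pmax(x, BETA_EPS), 1 - BETA_EPS)

# moment-matched Beta shapes for mean m, variance v
beta_moments <- function(m, v) {
  m <- min(max(m, 0.01), 0.99)
  v <- min(max(v, 1e-6), m * (1 - m) * 0.95)
  nu <- m * (1 - m) / v - 1
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

mixture_densities <- function(x, shape1, shape2) {
  d <- cbind(
    stats::dbeta(x, shape1[1], shape2[1]),
    stats::dbeta(x, shape1[2], shape2[2]),
    stats::dbeta(x, shape1[3], shape2[3]),
    1  # uniform outlier density on [0,1]
  )
  colnames(d) <- GENOTYPE_LEVELS
  d
}

weighted_beta_fit <- function(S1, S2, W, shape1, shape2) {
  # generalized M-step on the weighted Beta log-likelihood, expressed
  # through its sufficient statistics S1 = sum(w log x),
  # S2 = sum(w log(1-x)), W = sum(w), so each evaluation is O(1);
  # optim never returns a worse point than its start, preserving the EM
  # monotonicity guarantee
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b) || a > 1e6 || b > 1e6) return(1e12)
    -(W * (lgamma(a + b) - lgamma(a) - lgamma(b)) + (a - 1) * S1 + (b - 1) * S2)
  }
  fit <- stats::optim(log(c(shape1, shape2)), negll, method = "Nelder-Mead",
                      control = list(maxit = 200L))
  exp(fit$par)
}

#' Fit the four-component SNP genotype mixture by EM
#'
#' Pools beta-values of all SNP probes across samples and fits three Beta
#' components (genotypes AA, AB, BB) plus a uniform outlier component on
#' `[0, 1]` whose density is fixed at 1 (only its weight is learned).
#' Components are initialized by moment-matching within the beta ranges
#' `[0, 0.25]`, `(0.25, 0.75]` and `(0.75, 1]` and relabeled by ascending
#' mean after fitting, so `mean(AA) < mean(AB) < mean(BB)`.
#'
#' @param beta_snp numeric matrix of SNP-probe beta-values (probe x
#'   sample) or a numeric vector; values in `[0, 1]`, `NA` allowed.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol stop when the log-likelihood gain drops below this
#'   (default 1e-6).
#' @return A `SnpMixtureModel`: list with `weights` (4 mixing
#'   proportions), `shape1`/`shape2` (Beta shapes per genotype),
#'   `means` (component means), `loglik_trace` (non-decreasing),
#'   `converged`.
#' @export
fit_snp_mixture <- function(beta_snp, max_iter = 500L, tol = 1e-6) {
  x <- as.vector(beta_snp)
  x <- x[!is.na(x)]
  if (length(x) < 50L)
    stop("need at least 50 non-missing pooled beta-values", call. = FALSE)
  if (any(x < 0 | x > 1))
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  x <- clamp_beta(x)

  init_from_bins <- function() {
    bins <- list(x[x <= 0.25], x[x > 0.25 & x <= 0.75], x[x > 0.75])
    shapes <- matrix(NA_real_, 3, 2)
    centers <- c(0.05, 0.5, 0.95)
    for (k in 1:3) {
      b <- bins[[k]]
      if (length(b) >= 5L) shapes[k, ] <- beta_moments(mean(b), stats::var(b))
      else shapes[k, ] <- beta_moments(centers[k], 0.0025)
    }
    counts <- pmax(vapply(bins, length, 0L), 1L)
    w <- c(counts / sum(counts) * 0.99, 0.01)
    list(shape1 = shapes[, 1], shape2 = shapes[, 2], weights = w)
  }
  fallback_init <- function() {
    shapes <- t(vapply(c(0.05, 0.5, 0.95), beta_moments, numeric(2),
                       v = 0.0025))
    list(shape1 = shapes[, 1], shape2 = shapes[, 2],
         weights = c(0.27, 0.27, 0.26, 0.2))
  }

  lx <- log(x); l1x <- log1p(-x)
  run_em <- function(init) {
    shape1 <- init$shape1; shape2 <- init$shape2; w <- init$weights
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- mixture_densities(x, shape1, shape2)
      wd <- sweep(dens, 2, w, `*`)
      rowsum_wd <- rowSums(wd)
      if (any(!is.finite(rowsum_wd)) || any(rowsum_wd <= 0)) return(NULL)
      ll <- sum(log(rowsum_wd))
      trace <- c(trace, ll)
      resp <- wd / rowsum_wd
      w_new <- colMeans(resp)
      if (any(w_new[1:3] < 1e-10)) return(NULL)
      for (k in 1:3) {
        rk <- resp[, k]
        sh <- weighted_beta_fit(sum(rk * lx), sum(rk * l1x), sum(rk),
                                shape1[k], shape2[k])
        shape1[k] <- sh[1]; shape2[k] <- sh[2]
      }
      w <- w_new
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(weights = w, shape1 = shape1, shape2 = shape2, loglik_trace = trace,
         converged = it < max_iter)
  }

  # EM from two starts: data-driven bin moments with a small outlier
  # weight, and canonical trimodal clusters with a generous outlier
  # weight. The second start avoids local optima on heavily contaminated
  # cohorts where in-between beta-values would otherwise inflate the
  # genotype components. The fit with the higher final log-likelihood
  # wins.
  fits <- list(run_em(init_from_bins()), run_em(fallback_init()))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    stop("mixture fit failed: EM diverged or a genotype component emptied",
         call. = FALSE)
  fit <- fits[[which.max(vapply(fits, function(f) utils::tail(f$loglik_trace, 1L), 0))]]

  means <- fit$shape1 / (fit$shape1 + fit$shape2)
  ord <- order(means)
  fit$shape1 <- fit$shape1[ord]
  fit$shape2 <- fit$shape2[ord]
  fit$weights <- c(fit$weights[1:3][ord], fit$weights[4])
  names(fit$weights) <- GENOTYPE_LEVELS
  fit$means <- sort(means)
  names(fit$means) <- GENOTYPE_LEVELS[1:3]
  class(fit) <- "SnpMixtureModel"
  fit
}

#' @export
print.SnpMixtureModel <- function(x, ...) {
  cat("SnpMixtureModel (3 Beta genotype components + uniform outliers)\n")
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = " "), "\n")
  cat("  means:  ", paste(sprintf("%s=%.3f", names(x$means), x$means),
                          collapse = " "), "\n")
  cat("  log-likelihood:", utils::tail(x$loglik_trace, 1L),
      "after", length(x$loglik_trace), "EM iterations\n")
  invisible(x)
}

#' Soft genotype calls from a fitted mixture
#'
#' Posterior probability of each of the four components (AA, AB, BB,
#' outlier) for every sample x SNP-probe beta-value, by Bayes' rule over
#' the fitted component densities. Each posterior slice sums to 1;
#' missing beta-values yield missing slices.
#'
#' @param model a `SnpMixtureModel`.
#' @param beta_snp SNP-probe beta matrix (probe x sample).
#' @return A `GenotypePosteriors`: 3-d array (sample x SNP probe x 4).
#' @export
call_genotypes <- function(model, beta_snp) {
  beta_snp <- as.matrix(beta_snp)
  if (any(beta_snp < 0 | beta_snp > 1, na.rm = TRUE))
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  x <- clamp_beta(as.vector(t(beta_snp)))  # sample-major
  dens <- mixture_densities(x, model$shape1, model$shape2)
  wd <- sweep(dens, 2, model$weights, `*`)
  posts <- wd / rowSums(wd)
  posts[is.na(x), ] <- NA_real_
  out <- array(posts,
               dim = c(ncol(beta_snp), nrow(beta_snp), 4L),
               dimnames = list(colnames(beta_snp), rownames(beta_snp),
                               GENOTYPE_LEVELS))
  class(out) <- c("GenotypePosteriors", class(out))
  out
}

#' Per-sample outlier score O
#'
#' The average, over a sample's non-missing SNP probes, of the log2 odds
#' that the beta-value belongs to the outlier component. High values mean
#' the sample deviates from the ideal trimodal genotype pattern ---
#' typical of contamination or poor technical quality. Samples above
#' -4 log2 odds are conventionally considered suspect.
#'
#' @param posteriors a `GenotypePosteriors` array.
#' @param clip posteriors are clipped to `[clip, 1 - clip]` before taking
#'   odds, bounding the score for degenerate 0/1 posteriors.
#' @return named numeric vector of outlier scores per sample (`NA` when
#'   all of a sample's probes are missing).
#' @export
snp_outliers <- function(posteriors, clip = 1e-8) {
  p <- posteriors[, , "outlier", drop = FALSE]
  dim(p) <- dim(posteriors)[1:2]
  p <- pmin(pmax(p, clip), 1 - clip)
  o <- rowMeans(log2(p / (1 - p)), na.rm = TRUE)
  o[!is.finite(o)] <- NA_real_
  names(o) <- dimnames(posteriors)[[1]]
  o
}

#' Pairwise fingerprint agreement and metadata conflicts
#'
#' Soft identity check: for a pair of samples, agreement is the expected
#' number of SNP probes at which both carry the same genotype, divided by
#' the effective number of probes after soft exclusion of outliers ---
#' numerator `sum_j sum_k q[a,j,k] * q[b,j,k]` over the three genotype
#' components, denominator `sum_j w[a,j] * w[b,j]` with
#' `w = 1 - p(outlier)`. A probe partially classified as outlier is
#' thereby only partially excluded. Conflicts are pairs whose agreement
#' contradicts the donor metadata: same donor but agreement below the
#' threshold (`unexpected_disagreement`), or different donors with
#' agreement at or above it (`unexpected_agreement`).
#'
#' @param posteriors a `GenotypePosteriors` array.
#' @param donor_ids character vector of donor ids, one per sample (in
#'   posterior array order).
#' @param conflict_threshold agreement cutoff separating same-donor from
#'   different-donor pairs (default 0.90).
#' @param pairs optional data.frame (`sample_a`, `sample_b`) restricting
#'   which pairs are reported; default all unordered pairs.
#' @return An `AgreementResult`: list with `pairs` (data.frame
#'   `sample_a`, `sample_b`, `donor_a`, `donor_b`, `agreement`,
#'   `n_effective`) and `conflicts` (subset with `conflict_type`).
#' @export
check_snp_agreement <- function(posteriors, donor_ids,
                                conflict_threshold = 0.90, pairs = NULL) {
  samples <- dimnames(posteriors)[[1]]
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(donor_ids) != n)
    stop("donor_ids must match the number of samples", call. = FALSE)

  zero_na <- function(m) { m[is.na(m)] <- 0; m }
  W <- zero_na(1 - posteriors[, , "outlier"])
  num <- matrix(0, n, n)
  for (k in 1:3) {
    Q <- zero_na(posteriors[, , k])
    num <- num + tcrossprod(Q)
  }
  den <- tcrossprod(W)

  if (is.null(pairs)) {
    idx <- which(upper.tri(den), arr.ind = TRUE)
    pairs <- data.frame(sample_a = samples[idx[, 1]],
                        sample_b = samples[idx[, 2]],
                        stringsAsFactors = FALSE)
  } else {
    idx <- cbind(match(pairs$sample_a, samples), match(pairs$sample_b, samples))
    if (anyNA(idx)) stop("unknown sample id in pairs", call. = FALSE)
  }
  agreement <- num[idx] / den[idx]
  res <- data.frame(
    sample_a = pairs$sample_a, sample_b = pairs$sample_b,
    donor_a = donor_ids[idx[, 1]], donor_b = donor_ids[idx[, 2]],
    agreement = agreement, n_effective = den[idx],
    stringsAsFactors = FALSE
  )
  same <- res$donor_a == res$donor_b
  type <- rep(NA_character_, nrow(res))
  type[same & !is.na(res$agreement) & res$agreement < conflict_threshold] <-
    "unexpected_disagreement"
  type[!same & !is.na(res$agreement) & res$agreement >= conflict_threshold] <-
    "unexpected_agreement"
  conflicts <- res[!is.na(type), , drop = FALSE]
  conflicts$conflict_type <- type[!is.na(type)]
  rownames(conflicts) <- NULL

  structure(list(pairs = res, conflicts = conflicts,
                 conflict_threshold = conflict_threshold),
            class = "AgreementResult")
}

#' @export
print.AgreementResult <- function(x, ...) {
  cat("AgreementResult:", nrow(x$pairs), "pairwise comparisons,",
      nrow(x$conflicts), "conflict(s) at threshold",
      x$conflict_threshold, "\n")
  invisible(x)
}
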