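#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Expectation-maximisation for a k-component univariate Gaussian mixture,
#' run from several k-means-seeded starting points; the best final
#' log-likelihood wins. Component variances are floored at
#' `1e-6 * var(values)` to prevent degeneracy. Components are returned
#' sorted by mean.
#'
#' @param values Numeric vector, length at least `10 * k`.
#' @param k Number of components.
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Number of seeded restarts (default 10).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return Object of class `"gmm1d"`: list with `k`, `weights`, `means`,
#'   `variances`, `log_likelihood`, `n`, `bic`, `loglik_trace` (of the
#'   winning restart) and `converged`.
#' @export
fit_gmm_1d <- function(values, k, seed = 1L, n_restarts = 10L,
                       max_iter = 500L, tol = 1e-8) {
  values <- as.numeric(values)
  k <- as.integer(k)
  n <- length(values)
  if (n < 10L * k) stop("need at least 10*k observations")
  v_all <- var(values)
  if (v_all == 0) {
    if (k == 1L)
      return(new_gmm1d(1, values[1L], 1e-12, n,
                       log_likelihood = Inf, trace = Inf, converged = TRUE))
    stop("degenerate (constant) values: only k = 1 is fittable")
  }
  if (k == 1L) {
    mu <- mean(values); s2 <- mean((values - mu)^2)
    ll <- sum(dnorm(values, mu, sqrt(s2), log = TRUE))
    return(new_gmm1d(1, mu, s2, n, ll, trace = ll, converged = TRUE))
  }
  floor_var <- 1e-6 * v_all
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed * 1000L + r)
    km <- suppressWarnings(kmeans(values, centers = k, nstart = 1L,
                                  iter.max = 20L))
    w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    w <- pmax(w, 1 / n); w <- w / sum(w)
    mu <- as.numeric(km$centers)
    s2 <- pmax(vapply(seq_len(k), function(j) {
      xs <- values[km$cluster == j]
      if (length(xs) > 1L) var(xs) else v_all / k
    }, numeric(1)), floor_var)
    fit <- em_gmm_1d(values, w, mu, s2, floor_var, max_iter, tol)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  ord <- order(best$means)
  new_gmm1d(best$weights[ord], best$means[ord], best$variances[ord], n,
            best$log_likelihood, best$trace, best$converged)
}

em_gmm_1d <- function(x, w, mu, s2, floor_var, max_iter, tol) {
  n <- length(x); k <- length(w)
  ll_old <- -Inf; trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * dnorm(x, mu[j], sqrt(s2[j])), numeric(n))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    post <- dens / tot
    nk <- colSums(post)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(post * x) / nk
    s2 <- pmax(colSums(post * (outer(x, mu, "-")^2)) / nk, floor_var)
  }
  list(weights = w, means = mu, variances = s2, log_likelihood = ll_old,
       trace = trace, converged = converged)
}

new_gmm1d <- function(w, mu, s2, n, log_likelihood, trace, converged) {
  k <- length(mu)
  npar <- 3L * k - 1L
  structure(list(k = k, weights = as.numeric(w) / sum(w),
                 means = as.numeric(mu), variances = as.numeric(s2),
                 log_likelihood = log_likelihood, n = n,
                 bic = -2 * log_likelihood + npar * log(n),
                 loglik_trace = trace, converged = converged),
            class = "gmm1d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat(sprintf("1-D Gaussian mixture, k = %d (logLik %.2f, BIC %.2f)\n",
              x$k, x$log_likelihood, x$bic))
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 4),
                   sd = round(sqrt(x$variances), 4)))
  invisible(x)
}

#' Posterior component probabilities of a fitted 1-D mixture
#' @param model A `"gmm1d"` fit.
#' @param values Numeric vector to score.
#' @return Matrix (length(values) x k) of posterior probabilities.
#' @export
posterior_gmm1d <- function(model, values) {
  dens <- vapply(seq_len(model$k), function(j)
    model$weights[j] * dnorm(values, model$means[j], sqrt(model$variances[j])),
    numeric(length(values)))
  dens <- matrix(dens, nrow = length(values))
  tot <- rowSums(dens)
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  dens / tot
}

map_assign_gmm1d <- function(model, values) {
  max.col(posterior_gmm1d(model, values), ties.method = "first")
}

#' Select the mixture order by BIC
#'
#' Fits [fit_gmm_1d()] for each candidate `k` and returns the minimum-BIC
#' model; ties go to the smaller `k`. Candidate orders whose fit fails
#' (e.g. too few observations) are skipped.
#'
#' @param values Numeric vector.
#' @param k_range Candidate component counts (default 1:6).
#' @param seed Integer seed.
#' @return The winning `"gmm1d"` fit.
#' @export
select_components <- function(values, k_range = 1:6, seed = 1L) {
  if (!length(k_range)) stop("k_range must be non-empty")
  fits <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    f <- tryCatch(fit_gmm_1d(values, k, seed = seed), error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop("no candidate order could be fitted")
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  fits[[which.min(bics)]]             # which.min takes the first (smallest k) tie
}

#' Amplitude filter: drop genes in the background-intensity components
#'
#' First step of the adaptive two-step filter. The per-gene mean log2
#' expression is decomposed into a Gaussian mixture; genes MAP-assigned to
#' the `n_keep` (default 3) components with the highest means are retained,
#' removing the low-intensity background component(s). With a single-component
#' fit nothing is removed.
#'
#' @param x Expression matrix.
#' @param k_range Candidate mixture orders.
#' @param n_keep Maximum number of top-amplitude components retained
#'   (effective number is `min(n_keep, k - 1)`).
#' @param seed Integer seed.
#' @return List with `retained` (gene ids), `removed`, `model`, `statistic`.
#' @export
amplitude_filter <- function(x, k_range = 1:6, n_keep = 3L, seed = 1L) {
  validate_expression_matrix(x)
  stat <- rowMeans(x)
  model <- select_components(stat, k_range = k_range, seed = seed)
  if (model$k <= 1L) {
    warning("single-component amplitude fit: no genes removed")
    return(list(retained = rownames(x), removed = character(0),
                model = model, statistic = stat))
  }
  keep_k <- min(n_keep, model$k - 1L)
  keep_components <- order(model$means, decreasing = TRUE)[seq_len(keep_k)]
  assign <- map_assign_gmm1d(model, stat)
  keep <- assign %in% keep_components
  list(retained = rownames(x)[keep], removed = rownames(x)[!keep],
       model = model, statistic = stat)
}

#' Variance filter: drop the lowest-variance component
#'
#' Second step of the adaptive filter. The log per-gene sample variance is
#' decomposed into a Gaussian mixture and genes MAP-assigned to the component
#' with the lowest mean (the low-variance, uninformative genes) are removed.
#' Zero-variance genes are removed outright. With a single-component fit
#' nothing is removed.
#'
#' @inheritParams amplitude_filter
#' @return List with `retained`, `removed`, `model`, `statistic`.
#' @export
variance_filter <- function(x, k_range = 1:6, seed = 1L) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L) stop("variance filter needs >= 2 samples")
  v <- apply(x, 1L, var)
  zero <- v <= 0
  stat <- log(v[!zero])
  model <- select_components(stat, k_range = k_range, seed = seed)
  if (model$k <= 1L) {
    warning("single-component variance fit: no genes removed")
    return(list(retained = rownames(x)[!zero], removed = rownames(x)[zero],
                model = model, statistic = stat))
  }
  low <- which.min(model$means)
  assign <- map_assign_gmm1d(model, stat)
  keep_ids <- rownames(x)[!zero][assign != low]
  list(retained = keep_ids, removed = setdiff(rownames(x), keep_ids),
       model = model, statistic = stat)
}
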