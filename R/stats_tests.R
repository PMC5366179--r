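#' Per-group means, variances and sizes for every gene
#'
#' @param x Expression matrix (genes x samples).
#' @param groups Per-sample group labels.
#' @return List with `n` (named sizes), `means` and `vars`
#'   (genes x groups matrices) and `levels`.
#' @keywords internal
group_stats <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(x)) stop("groups must have one label per sample")
  lev <- levels(groups)
  n <- as.numeric(table(groups))
  sums <- t(rowsum(t(x), groups))            # genes x groups
  means <- sweep(sums, 2L, n, "/")
  sq <- t(rowsum(t(x)^2, groups))
  vars <- sweep(sq - sweep(means^2, 2L, n, "*"), 2L, pmax(n - 1, 1), "/")
  vars[vars < 0] <- 0
  list(n = setNames(n, lev), means = means, vars = vars, levels = lev)
}

#' Normality and homoscedasticity checks for one gene
#'
#' Normality holds if the Shapiro-Wilk p-value is at least `alpha` in every
#' group (groups of fewer than 3 observations cannot be assessed and count as
#' non-normal); variance homogeneity is tested with the Brown-Forsythe
#' (median-centred Levene) statistic.
#'
#' @param values Numeric vector (one gene across samples).
#' @param groups Per-sample group labels.
#' @param alpha Significance level for both checks.
#' @return List with logical `normal` and `homoscedastic`.
#' @export
assumption_checks <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  split_v <- split(values, groups)
  normal <- all(vapply(split_v, function(v) {
    if (length(v) < 3L || length(unique(v)) == 1L) return(FALSE)
    shapiro.test(v)$p.value >= alpha
  }, logical(1)))
  list(normal = normal,
       homoscedastic = brown_forsythe_test(values, groups)$p.value >= alpha)
}

#' Brown-Forsythe test of variance homogeneity
#'
#' Median-centred Levene test: a one-way ANOVA on the absolute deviations
#' from the group medians.
#'
#' @inheritParams assumption_checks
#' @return List with `statistic`, `df`, `p.value`.
#' @export
brown_forsythe_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  med <- tapply(values, groups, median)
  z <- abs(values - med[groups])
  k <- nlevels(groups); n <- length(z)
  zbar <- tapply(z, groups, mean); ni <- tabulate(groups)
  ssb <- sum(ni * (zbar - mean(z))^2)
  ssw <- sum((z - zbar[groups])^2)
  if (ssw == 0) return(list(statistic = NA_real_, df = c(k - 1, n - k),
                            p.value = if (ssb == 0) 1 else 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, df = c(k - 1, n - k),
       p.value = pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Choose the parametric or non-parametric testing branch
#'
#' Applies [assumption_checks()] gene-wise and routes the whole analysis:
#' parametric (ANOVA + Dunnett) if at least `frac_threshold` of genes pass
#' both checks, otherwise non-parametric (Kruskal-Wallis + Games-Howell).
#'
#' @param x Expression matrix.
#' @param groups Per-sample group labels.
#' @param alpha Significance level for the checks.
#' @param frac_threshold Minimum fraction of assumption-satisfying genes for
#'   the parametric route (default 0.5).
#' @param max_genes Checks are run on at most this many genes (evenly
#'   subsampled, deterministic) to bound cost.
#' @return List with `branch` ("parametric"/"nonparametric"),
#'   `fraction_passing`, `n_checked`.
#' @export
choose_test_branch <- function(x, groups, alpha = 0.05, frac_threshold = 0.5,
                               max_genes = 1000L) {
  validate_expression_matrix(x)
  idx <- if (nrow(x) > max_genes)
    unique(round(seq(1L, nrow(x), length.out = max_genes))) else seq_len(nrow(x))
  pass <- vapply(idx, function(i) {
    ch <- assumption_checks(x[i, ], groups, alpha)
    ch$normal && ch$homoscedastic
  }, logical(1))
  frac <- mean(pass)
  list(branch = if (frac >= frac_threshold) "parametric" else "nonparametric",
       fraction_passing = frac, n_checked = length(idx))
}

#' One-way ANOVA gate
#'
#' Classic one-way F test per gene; genes with p below `alpha` pass the gate
#' into post-hoc testing. Genes with zero within-group variance and equal
#' group means get p = 1 by convention.
#'
#' @param x Expression matrix.
#' @param groups Per-sample group labels (>= 2 levels).
#' @param alpha Significance level.
#' @return List with `p` (named per-gene), `retained` (gene ids) and
#'   `statistic` (F values).
#' @export
anova_gate <- function(x, groups, alpha = 0.05) {
  validate_expression_matrix(x)
  gs <- group_stats(x, groups)
  k <- length(gs$levels)
  if (k < 2L) stop("need >= 2 groups")
  n <- sum(gs$n); N <- ncol(x)
  grand <- rowMeans(x)
  ssb <- rowSums(sweep((gs$means - grand)^2, 2L, gs$n, "*"))
  ssw <- rowSums(sweep(gs$vars, 2L, gs$n - 1, "*"))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  p[ssw == 0 & ssb <= .Machine$double.eps * N] <- 1
  p[ssw == 0 & ssb > .Machine$double.eps * N] <- 0
  names(p) <- rownames(x)
  list(p = p, retained = rownames(x)[p < alpha], statistic = f)
}

#' Kruskal-Wallis gate
#'
#' Tie-corrected Kruskal-Wallis test per gene (chi-square reference with
#' k - 1 df); genes with p below `alpha` pass. All-equal genes get p = 1.
#'
#' @inheritParams anova_gate
#' @return List with `p` and `retained`.
#' @export
kruskal_wallis_gate <- function(x, groups, alpha = 0.05) {
  validate_expression_matrix(x)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  p <- apply(x, 1L, function(v) {
    if (length(unique(v)) == 1L) return(1)
    kruskal.test(v, groups)$p.value
  })
  p[is.na(p)] <- 1
  names(p) <- rownames(x)
  list(p = p, retained = rownames(x)[p < alpha])
}

#' Dunnett many-to-one comparisons for one gene
#'
#' Two-sided comparisons of each treatment group against the control:
#' \eqn{t_i = (\bar x_i - \bar x_0)/(s_p \sqrt{1/n_i + 1/n_0})} with the
#' pooled SD over all groups and N - k degrees of freedom. Family-wise
#' adjusted p-values come from the multivariate-t distribution of the
#' comparison vector (correlation \eqn{\rho_{ij} = \sqrt{n_i n_j /
#' ((n_i+n_0)(n_j+n_0))}}), evaluated by seeded quasi-Monte-Carlo
#' integration with 1e5 points.
#'
#' @param values Numeric vector (one gene).
#' @param groups Per-sample group labels including the control.
#' @param control Label of the control group.
#' @param mc_seed Seed for the integration (fixed for reproducibility).
#' @return Data frame with one row per treatment group: `group`, `t`,
#'   `p_unadjusted`, `p_adjusted`, `direction` (+1/-1 sign of the mean
#'   difference vs control).
#' @export
dunnett_vs_control <- function(values, groups, control, mc_seed = 1L) {
  groups <- droplevels(as.factor(groups))
  if (!control %in% levels(groups)) stop("control group '", control, "' not present")
  lev <- levels(groups)
  trt <- setdiff(lev, control)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  N <- length(values); k <- length(lev)
  df <- N - k
  sp2 <- sum((n - 1) * v) / df
  se <- sqrt(sp2 * (1 / n[trt] + 1 / n[control]))
  tstat <- (m[trt] - m[control]) / se
  corr <- dunnett_corr(n[trt], n[[control]])
  p_adj <- vapply(abs(tstat), function(tt) {
    if (!is.finite(tt)) return(NA_real_)
    set.seed(mc_seed)
    1 - mvtnorm::pmvt(lower = rep(-tt, length(trt)),
                      upper = rep(tt, length(trt)), df = as.integer(df),
                      corr = corr,
                      algorithm = mvtnorm::GenzBretz(maxpts = 1e5,
                                                     abseps = 1e-4))[1]
  }, numeric(1))
  p_adj <- pmin(pmax(p_adj, 0), 1)
  data.frame(group = trt, t = as.numeric(tstat),
             p_unadjusted = 2 * pt(-abs(tstat), df),
             p_adjusted = p_adj,
             direction = sign(m[trt] - m[control]),
             row.names = NULL, stringsAsFactors = FALSE)
}

dunnett_corr <- function(n_trt, n0) {
  k <- length(n_trt)
  lam <- sqrt(n_trt / (n_trt + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  corr
}

#' Dunnett comparisons for every gene of a matrix
#'
#' @param x Expression matrix.
#' @param groups Per-sample group labels.
#' @param control Control group label.
#' @param mc_seed Integration seed.
#' @return List with `p_adjusted` and `direction` (genes x treatment
#'   matrices) and `groups` (treatment labels).
#' @export
dunnett_vs_control_matrix <- function(x, groups, control, mc_seed = 1L) {
  validate_expression_matrix(x)
  res <- apply(x, 1L, dunnett_vs_control, groups = groups, control = control,
               mc_seed = mc_seed, simplify = FALSE)
  trt <- res[[1L]]$group
  p <- t(vapply(res, `[[`, numeric(length(trt)), "p_adjusted"))
  d <- t(vapply(res, `[[`, numeric(length(trt)), "direction"))
  dimnames(p) <- dimnames(d) <- list(rownames(x), trt)
  list(p_adjusted = p, direction = d, groups = trt)
}

#' Games-Howell pairwise comparisons for one gene
#'
#' For each unordered pair of groups, the Welch-type statistic
#' \eqn{t = |\bar x_i - \bar x_j| / \sqrt{s_i^2/n_i + s_j^2/n_j}} with
#' Welch-Satterthwaite degrees of freedom is referred to the studentized
#' range distribution with `k` groups: \eqn{p = P(Q_{k,\nu} \ge t\sqrt 2)}.
#' Robust to unequal variances and unequal group sizes.
#'
#' @param values Numeric vector (one gene).
#' @param groups Per-sample group labels (each group n >= 2).
#' @return Data frame with `group1`, `group2`, `t`, `df`, `p`, `direction`.
#' @export
games_howell_pairwise <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  k <- length(lev)
  if (k < 2L) stop("need >= 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2L)) stop("every group needs n >= 2")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  pairs <- utils::combn(lev, 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se2 <- v[[i]] / n[[i]] + v[[j]] / n[[j]]
    dm <- m[[i]] - m[[j]]
    if (se2 == 0) {
      p <- if (dm == 0) 1 else 0
      return(c(t = if (dm == 0) 0 else Inf, df = Inf, p = p,
               direction = sign(dm)))
    }
    tt <- abs(dm) / sqrt(se2)
    df <- se2^2 / ((v[[i]] / n[[i]])^2 / (n[[i]] - 1) +
                     (v[[j]] / n[[j]])^2 / (n[[j]] - 1))
    p <- ptukey(tt * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    c(t = tt, df = df, p = p, direction = sign(dm))
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             t = res["t", ], df = res["df", ], p = res["p", ],
             direction = res["direction", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Games-Howell pairwise significance for every gene
#'
#' Vectorised across genes: per class pair, Welch statistics and
#' Welch-Satterthwaite degrees of freedom are computed from per-group means
#' and variances, and referred to the studentized range distribution for `k`
#' groups. The result is the gene x class-pair substrate that CE-DEG and
#' biomarker selection consume.
#'
#' @param x Expression matrix.
#' @param groups Per-sample group labels.
#' @return Object of class `"pairwise_significance"`: list with `p` and
#'   `direction` (genes x pairs matrices; columns named "A|B"), `pairs`
#'   (2 x npairs character matrix) and `classes`.
#' @export
pairwise_significance <- function(x, groups) {
  validate_expression_matrix(x)
  gs <- group_stats(x, groups)
  lev <- gs$levels; k <- length(lev)
  if (k < 2L) stop("need >= 2 groups")
  if (any(gs$n < 2L)) stop("every group needs n >= 2")
  pairs <- utils::combn(lev, 2L)
  npair <- ncol(pairs)
  p <- d <- matrix(NA_real_, nrow(x), npair,
                   dimnames = list(rownames(x),
                                   paste(pairs[1L, ], pairs[2L, ], sep = "|")))
  for (c_idx in seq_len(npair)) {
    i <- pairs[1L, c_idx]; j <- pairs[2L, c_idx]
    vi <- gs$vars[, i] / gs$n[[i]]; vj <- gs$vars[, j] / gs$n[[j]]
    se2 <- vi + vj
    dm <- gs$means[, i] - gs$means[, j]
    tt <- abs(dm) / sqrt(se2)
    df <- se2^2 / (vi^2 / (gs$n[[i]] - 1) + vj^2 / (gs$n[[j]] - 1))
    pv <- ptukey(tt * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    pv[se2 == 0 & dm == 0] <- 1
    pv[se2 == 0 & dm != 0] <- 0
    p[, c_idx] <- pv
    d[, c_idx] <- sign(dm)
  }
  structure(list(p = p, direction = d, pairs = pairs, classes = lev),
            class = "pairwise_significance")
}

#' Null family-wise error simulation for the Games-Howell family
#'
#' Simulates `n_reps` experiments with all group means equal (Gaussian, the
#' given per-group SDs and sizes), runs the full Games-Howell pairwise family
#' on each, and reports the fraction of experiments with at least one
#' adjusted p-value below `alpha` — the empirical family-wise type-I error.
#' Vectorised across replicates.
#'
#' @param n Integer vector of group sizes.
#' @param sds Per-group standard deviations (unequal variances allowed).
#' @param n_reps Number of simulated experiments.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return List with `fwer`, `n_reps` and `se` (binomial Monte-Carlo SE at
#'   the nominal level).
#' @export
gh_null_fwer <- function(n, sds = rep(1, length(n)), n_reps = 10000L,
                         alpha = 0.05, seed = 1L) {
  k <- length(n)
  stopifnot(k >= 2L, length(sds) == k, all(n >= 2L))
  set.seed(seed)
  means <- vars <- matrix(NA_real_, n_reps, k)
  for (j in seq_len(k)) {
    xj <- matrix(rnorm(n[j] * n_reps, 0, sds[j]), n[j], n_reps)
    means[, j] <- colMeans(xj)
    vars[, j] <- colSums((xj - rep(means[, j], each = n[j]))^2) / (n[j] - 1)
  }
  pairs <- utils::combn(k, 2L)
  any_sig <- rep(FALSE, n_reps)
  for (c_idx in seq_len(ncol(pairs))) {
    i <- pairs[1L, c_idx]; j <- pairs[2L, c_idx]
    vi <- vars[, i] / n[i]; vj <- vars[, j] / n[j]
    se2 <- vi + vj
    tt <- abs(means[, i] - means[, j]) / sqrt(se2)
    df <- se2^2 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
    p <- ptukey(tt * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    any_sig <- any_sig | (p < alpha)
  }
  list(fwer = mean(any_sig), n_reps = n_reps,
       se = sqrt(alpha * (1 - alpha) / n_reps))
}
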