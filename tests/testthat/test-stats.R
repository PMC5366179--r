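test_that("assumption checks calibrate on Gaussian data and catch violations", {
  set.seed(51)
  groups <- rep(c("A", "B", "C"), each = 30)
  # Gaussian equal-variance: both flags true at roughly (1-alpha)^(k+1)
  pass <- replicate(300, {
    ch <- assumption_checks(rnorm(90), groups, alpha = 0.05)
    ch$normal && ch$homoscedastic
  })
  expected <- (1 - 0.05)^4          # 3 Shapiro tests + 1 Brown-Forsythe
  expect_equal(mean(pass), expected, tolerance = 3 * sqrt(expected * (1 - expected) / 300) / expected)

  # heavy-tailed group flagged non-normal at large n
  set.seed(52)
  ht <- c(rt(500, df = 3), rnorm(500))
  ch <- assumption_checks(ht, rep(c("A", "B"), each = 500))
  expect_false(ch$normal)

  # group below n = 3 counts as non-normal
  v <- c(rnorm(30), 1, 2)
  ch2 <- assumption_checks(v, c(rep("A", 30), "B", "B"))
  expect_false(ch2$normal)
})

test_that("branch routing follows the assumption checks", {
  set.seed(53)
  x <- matrix(rnorm(200 * 90), 200, 90,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:90)))
  groups <- rep(c("A", "B", "C"), each = 30)
  expect_equal(choose_test_branch(x, groups)$branch, "parametric")
  xt <- matrix(rt(200 * 90, df = 3), 200, 90, dimnames = dimnames(x))
  expect_equal(choose_test_branch(xt, groups)$branch, "nonparametric")
})

test_that("ANOVA gate: F equals t^2 with two groups; null calibration; power", {
  set.seed(54)
  x <- matrix(rnorm(100 * 40), 100, 40,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:40)))
  groups <- rep(c("A", "B"), each = 20)
  res <- anova_gate(x, groups)
  for (i in c(1, 50, 100)) {
    tt <- t.test(x[i, groups == "A"], x[i, groups == "B"], var.equal = TRUE)
    expect_equal(unname(res$p[i]), tt$p.value, tolerance = 1e-10)
    expect_equal(unname(res$statistic[i]), unname(tt$statistic)^2,
                 tolerance = 1e-10)
  }

  # null retention rate ~ alpha
  set.seed(55)
  g <- 4000
  xn <- matrix(rnorm(g * 60), g, 60,
               dimnames = list(sprintf("g%04d", 1:g), sprintf("s%02d", 1:60)))
  gr3 <- rep(c("A", "B", "C"), each = 20)
  frac <- length(anova_gate(xn, gr3)$retained) / g
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / g))

  # power on shifted genes matches the closed-form noncentral F
  set.seed(56)
  shift <- 0.8; n_rep <- 800
  xs <- matrix(rnorm(n_rep * 60), n_rep, 60,
               dimnames = list(sprintf("g%04d", 1:n_rep), sprintf("s%02d", 1:60)))
  xs[, gr3 == "C"] <- xs[, gr3 == "C"] + shift
  emp_power <- length(anova_gate(xs, gr3)$retained) / n_rep
  grand <- shift / 3
  ncp <- 20 * ((0 - grand)^2 + (0 - grand)^2 + (shift - grand)^2)
  theor <- pf(qf(0.95, 2, 57), 2, 57, ncp = ncp, lower.tail = FALSE)
  expect_equal(emp_power, theor,
               tolerance = 3 * sqrt(theor * (1 - theor) / n_rep) / theor)

  # degenerate: zero within-variance, equal means
  xz <- matrix(5, 2, 40, dimnames = list(c("g1", "g2"), colnames(x)))
  expect_equal(unname(anova_gate(xz, groups)$p), c(1, 1))
})

test_that("Dunnett reduces to the pooled t-test with one treatment group", {
  set.seed(57)
  v <- rnorm(40)
  groups <- rep(c("T1", "CTR"), each = 20)
  res <- dunnett_vs_control(v, groups, control = "CTR")
  tt <- t.test(v[groups == "T1"], v[groups == "CTR"], var.equal = TRUE)
  expect_equal(res$p_adjusted, tt$p.value, tolerance = 1e-3)
  expect_equal(res$p_unadjusted, tt$p.value, tolerance = 1e-10)
})

test_that("Dunnett adjusted p is monotone and matches multcomp", {
  set.seed(58)
  groups <- rep(c("CTR", "T1", "T2", "T3"), times = c(15, 10, 12, 14))
  v <- rnorm(length(groups)) + 0.8 * (groups == "T2")
  res <- dunnett_vs_control(v, groups, control = "CTR")
  expect_true(all(res$p_adjusted >= res$p_unadjusted - 1e-9))
  expect_true(all(res$p_adjusted >= 0 & res$p_adjusted <= 1))

  skip_if_not_installed("multcomp")
  df <- data.frame(v = v, g = factor(groups, levels = c("CTR", "T1", "T2", "T3")))
  glht_fit <- multcomp::glht(aov(v ~ g, data = df),
                             linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(glht_fit)$test$pvalues
  expect_equal(res$p_adjusted, as.numeric(ref), tolerance = 5e-3)
  expect_error(dunnett_vs_control(v, groups, control = "nope"), "not present")
})

test_that("Dunnett controls the family-wise error on null families", {
  set.seed(59)
  g <- 400
  groups <- rep(c("CTR", "T1", "T2", "T3", "T4", "T5"), each = 12)
  x <- matrix(rnorm(g * length(groups)), g, length(groups),
              dimnames = list(sprintf("g%04d", 1:g), sprintf("s%02d",
                                                             seq_along(groups))))
  dn <- dunnett_vs_control_matrix(x, groups, control = "CTR")
  fwer <- mean(apply(dn$p_adjusted < 0.05, 1, any))
  expect_lt(abs(fwer - 0.05), 3 * sqrt(0.05 * 0.95 / g) + 0.01)
})

test_that("Kruskal-Wallis gate: two-group equivalence, null rate, rank invariance", {
  set.seed(60)
  x <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:30)))
  groups <- rep(c("A", "B"), each = 15)
  kw <- kruskal_wallis_gate(x, groups)
  # KW with 2 groups equals the two-sided Mann-Whitney normal approximation
  for (i in c(3, 27)) {
    r <- rank(x[i, ])
    w <- sum(r[groups == "A"])
    mu <- 15 * 31 / 2; sig <- sqrt(15 * 15 * 31 / 12)
    p_mw <- 2 * pnorm(-abs((w - mu) / sig))
    expect_equal(unname(kw$p[i]), p_mw, tolerance = 1e-6)
  }
  # monotone-transform invariance
  kw2 <- kruskal_wallis_gate(exp(x), groups)
  expect_equal(kw$p, kw2$p, tolerance = 1e-12)

  set.seed(61)
  g <- 3000
  xn <- matrix(rnorm(g * 45), g, 45,
               dimnames = list(sprintf("g%04d", 1:g), sprintf("s%02d", 1:45)))
  frac <- length(kruskal_wallis_gate(xn, rep(c("A", "B", "C"), each = 15))$retained) / g
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / g) + 0.01)
})

test_that("Games-Howell with two groups equals the Welch t-test", {
  set.seed(62)
  v <- c(rnorm(12, 0, 1), rnorm(20, 0.5, 2.5))
  groups <- rep(c("A", "B"), times = c(12, 20))
  gh <- games_howell_pairwise(v, groups)
  wt <- t.test(v[groups == "A"], v[groups == "B"])
  expect_equal(gh$p, wt$p.value, tolerance = 1e-6)
  expect_equal(gh$df, unname(wt$parameter), tolerance = 1e-9)
})

test_that("Games-Howell agrees with a permutation max-|t| oracle", {
  set.seed(63)
  v <- c(rnorm(5, 0, 1), rnorm(5, 0.8, 1.6), rnorm(5, 0.2, 0.7))
  groups <- rep(c("A", "B", "C"), each = 5)
  gh <- games_howell_pairwise(v, groups)

  welch_t <- function(vals, g) {
    prs <- combn(unique(g), 2)
    apply(prs, 2, function(pr) {
      a <- vals[g == pr[1]]; b <- vals[g == pr[2]]
      abs(mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
    })
  }
  obs <- welch_t(v, groups)
  n_perm <- 4000
  maxmat <- replicate(n_perm, max(welch_t(v, sample(groups))))
  p_perm <- vapply(obs, function(t0) mean(maxmat >= t0), numeric(1))
  # small-sample distributional slack plus MC error
  expect_lt(max(abs(gh$p - p_perm)), 0.15)
})

test_that("matrix-level pairwise significance matches the per-gene function", {
  set.seed(64)
  d <- make_group_matrix(matrix(rnorm(20 * 4, 8), 20, 4,
                                dimnames = list(NULL, c("A", "B", "C", "D"))),
                         n_per_group = c(10, 14, 8, 12))
  pw <- pairwise_significance(d$x, d$groups)
  expect_equal(dim(pw$p), c(20L, 6L))
  for (i in c(1, 13)) {
    single <- games_howell_pairwise(d$x[i, ], d$groups)
    expect_equal(unname(pw$p[i, ]), single$p, tolerance = 1e-10)
    expect_equal(unname(pw$direction[i, ]), single$direction)
  }
  expect_true(all(pw$p >= 0 & pw$p <= 1))
  # zero-variance pair conventions
  xz <- rbind(g1 = rep(1, 20), g2 = c(rep(1, 10), rep(2, 10)))
  colnames(xz) <- sprintf("s%02d", 1:20)
  gz <- rep(c("A", "B"), each = 10)
  pz <- pairwise_significance(xz, gz)
  expect_equal(unname(pz$p[, 1]), c(1, 0))
})
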