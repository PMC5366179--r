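test_that("case-control DEG sets recover planted shifts with direction", {
  set.seed(71)
  classes <- c("ALL", "AML", "CTR")
  means <- matrix(8, 60, 3, dimnames = list(sprintf("g%03d", 1:60), classes))
  means["g001", "ALL"] <- 9.5          # up in ALL only
  means["g002", "AML"] <- 6.5          # down in AML only
  d <- make_group_matrix(means, n_per_group = c(25, 25, 25), noise_sd = 0.5)
  degs <- case_control_degs(d$x, d$groups, control = "CTR")
  expect_true("g001" %in% degs$ALL$up)
  expect_false("g001" %in% degs$AML$genes)
  expect_true("g002" %in% degs$AML$down)
  s <- summary(degs)
  expect_equal(s$up + s$down, s$total)
  expect_error(case_control_degs(d$x, d$groups, control = "XXX"),
               "not present")
})

test_that("case-control null set sizes are near the alpha level", {
  set.seed(72)
  g <- 300
  x <- matrix(rnorm(g * 75), g, 75,
              dimnames = list(sprintf("g%04d", 1:g), sprintf("s%02d", 1:75)))
  groups <- rep(c("A", "B", "CTR"), each = 25)
  degs <- case_control_degs(x, groups, control = "CTR")
  # ANOVA gate already trims to ~alpha*G; Dunnett inside keeps fewer
  expect_lte(length(degs$A$genes) / g, 0.05 + 3 * sqrt(0.05 * 0.95 / g))
})

test_that("CE-DEG and biomarker definitions follow the pairwise rules", {
  classes <- c("A", "B", "C")
  # pairs: A|B, A|C, B|C
  p <- rbind(
    all_sig  = c(0.001, 0.001, 0.001),  # significant for every pair
    only_a   = c(0.001, 0.001, 0.900),  # pairs involving A only
    a_plus_bc = c(0.001, 0.001, 0.010), # CE-DEG for A but B|C also significant
    nothing  = c(0.500, 0.700, 0.900))
  pw <- make_pairwise(p, classes)
  ce <- ce_deg_sets(pw, alpha = 0.05)
  expect_setequal(ce$A, c("all_sig", "only_a", "a_plus_bc"))
  # a_plus_bc is also a CE-DEG for B and C: both its B and C pairs are
  # significant (A|B, B|C and A|C, B|C respectively)
  expect_setequal(ce$B, c("all_sig", "a_plus_bc"))
  expect_setequal(ce$C, c("all_sig", "a_plus_bc"))
  sel <- select_biomarkers(pw, alpha = 0.05)
  expect_setequal(sel$biomarkers$A, "only_a")   # a_plus_bc excluded by B|C
  expect_equal(length(sel$biomarkers$B), 0L)
  # invariants: biomarker subset of CE-DEG; sets disjoint
  for (cl in classes)
    expect_true(all(sel$biomarkers[[cl]] %in% sel$ce_degs[[cl]]))
  all_bio <- unlist(sel$biomarkers)
  expect_equal(anyDuplicated(all_bio), 0L)
})

test_that("planted biomarkers are recovered and two-class genes never selected", {
  sens <- fdr <- two_hits <- numeric(5)
  for (s in 1:5) {
    cfg <- simulation_config(
      n_genes = 400, class_sizes = c(A = 30, B = 30, C = 30,
                                     D = 30, E = 30, F = 30),
      n_batches = 1, batch_sd_add = 0, batch_scale_shape = 0,
      n_ce_degs = 10, n_biomarkers_per_class = 4,
      effect_size = 1.0, noise_sd = 0.5, seed = s)
    d <- simulate_dataset(cfg)
    gate <- kruskal_wallis_gate(d$matrix, d$annotation$subtype)
    pw <- pairwise_significance(d$matrix[gate$retained, , drop = FALSE],
                                d$annotation$subtype)
    sel <- select_biomarkers(pw)
    truth_bio <- d$truth$gene_id[!is.na(d$truth$biomarker_class)]
    two_class <- d$truth$gene_id[is.na(d$truth$biomarker_class) &
                                   d$truth$ce_deg_classes != ""]
    found <- unlist(sel$biomarkers)
    sens[s] <- mean(truth_bio %in% found)
    fdr[s] <- if (length(found)) mean(!found %in% truth_bio) else 0
    two_hits[s] <- sum(two_class %in% found)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.1)
  expect_equal(sum(two_hits), 0)
})

test_that("planted CE-DEG genes are found for their two classes", {
  cfg <- simulation_config(
    n_genes = 300, class_sizes = c(A = 30, B = 30, C = 30, D = 30),
    n_batches = 1, batch_sd_add = 0, batch_scale_shape = 0,
    n_ce_degs = 12, n_biomarkers_per_class = 0,
    effect_size = 1.0, noise_sd = 0.5, seed = 7)
  d <- simulate_dataset(cfg)
  pw <- pairwise_significance(d$matrix, d$annotation$subtype)
  ce <- ce_deg_sets(pw)
  two <- d$truth[d$truth$ce_deg_classes != "", ]
  hits <- mapply(function(g, cls) {
    cl <- strsplit(cls, ",")[[1]]
    all(vapply(cl, function(c_) g %in% ce[[c_]], logical(1)))
  }, two$gene_id, two$ce_deg_classes)
  expect_gte(mean(hits), 0.9)
})

test_that("Dice coefficient identities and Jaccard relation hold", {
  expect_equal(dice_coefficient(c("a", "b"), c("a", "b")), 1)
  expect_equal(dice_coefficient(c("a", "b"), c("c", "d")), 0)
  expect_equal(dice_coefficient(character(0), character(0)), 0)
  set.seed(73)
  for (r in 1:20) {
    u <- sprintf("g%03d", 1:200)
    a <- sample(u, sample(5:150, 1))
    b <- sample(u, sample(5:150, 1))
    dsc <- dice_coefficient(a, b)
    # direct element count
    expect_equal(dsc, 2 * length(intersect(a, b)) / (length(a) + length(b)))
    jac <- length(intersect(a, b)) / length(union(a, b))
    expect_equal(dsc, 2 * jac / (1 + jac), tolerance = 1e-12)
    expect_equal(dsc, dice_coefficient(b, a))
  }
})

test_that("Dice bootstrap interval behaves as an interval should", {
  u <- sprintf("g%04d", 1:500)
  a <- u[1:200]
  expect_equal(unlist(dice_confidence_interval(a, a, u, n_boot = 200,
                                               seed = 1)[c("lower", "upper")]),
               c(lower = 1, upper = 1))
  set.seed(74)
  contains <- replicate(40, {
    a <- sample(u, 150); b <- sample(u, 180)
    ci <- dice_confidence_interval(a, b, u, n_boot = 300, seed = sample.int(1e6, 1))
    ci$lower <= ci$estimate && ci$estimate <= ci$upper
  })
  expect_gte(mean(contains), 0.99)
  # width shrinks with universe size at fixed overlap fraction
  widths <- vapply(c(200, 2000), function(nu) {
    uu <- sprintf("x%05d", seq_len(nu))
    a <- uu[seq_len(nu * 0.4)]
    b <- uu[seq(nu * 0.2, nu * 0.6)]
    ci <- dice_confidence_interval(a, b, uu, n_boot = 400, seed = 5)
    ci$upper - ci$lower
  }, numeric(1))
  expect_lt(widths[2], widths[1])
  expect_error(dice_confidence_interval("a", "a", character(0)), "universe")
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  u <- sprintf("g%02d", 1:8)
  query <- u[1:4]
  term <- u[c(1, 2, 3, 5)]      # 2x2 table: 3,1 / 1,3
  res <- fisher_enrichment(query, u, list(T1 = term))
  # two-sided hypergeometric: sum of tables at least as extreme
  probs <- dhyper(0:4, 4, 4, 4)
  p_manual <- sum(probs[probs <= dhyper(3, 4, 4, 4) + 1e-12])
  expect_equal(res$p, p_manual, tolerance = 1e-10)

  # perfect split: p near 0, odds ratio infinite
  u2 <- sprintf("h%03d", 1:40)
  res2 <- fisher_enrichment(u2[1:20], u2, list(T = u2[1:20]))
  expect_lt(res2$p, 1e-8)
  expect_true(is.infinite(res2$odds_ratio))
  expect_warning(fisher_enrichment(u2[1:5], u2, list(T = u2[1:10],
                                                     none = "zzz")), "none")
})

test_that("Fisher p-values are uniform under random queries", {
  set.seed(75)
  u <- sprintf("g%04d", 1:400)
  terms <- lapply(1:150, function(i) sample(u, 40))
  names(terms) <- sprintf("T%03d", 1:150)
  query <- sample(u, 100)
  res <- fisher_enrichment(query, u, terms)
  # exact-test null: p is discrete and stochastically >= uniform, so the
  # rejection rate never exceeds the level (within MC error), at any level
  for (lev in c(0.05, 0.10, 0.25)) {
    se3 <- 3 * sqrt(lev * (1 - lev) / length(res$p))
    expect_lte(mean(res$p < lev), lev + se3)
  }
  expect_gt(mean(res$p), 0.35)
})

test_that("dice_matrix reports all pairs with intervals", {
  u <- sprintf("g%03d", 1:300)
  sets <- list(A = u[1:100], B = u[50:150], C = u[200:300])
  dm <- dice_matrix(sets, u, n_boot = 200, seed = 2)
  expect_equal(nrow(dm), 3L)
  expect_true(all(dm$lower <= dm$dsc + 1e-9 & dm$dsc <= dm$upper + 1e-9))
})
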