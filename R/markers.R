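#' Case-control DEG sets (each class vs the control group)
#'
#' First comparative analysis: genes are gated by one-way ANOVA across all
#' main classes, then each class is compared with the control group by
#' Dunnett many-to-one comparisons; a gene belongs to a class's DEG set when
#' its family-wise adjusted p-value is below `alpha`, with the direction
#' taken from the sign of the mean difference against the control.
#'
#' @param x Expression matrix (genes x samples).
#' @param main_class Per-sample main-class labels including the control.
#' @param control Control class label (default "CTR").
#' @param alpha Significance level.
#' @param mc_seed Seed for the Dunnett integration.
#' @return Object of class `"deg_sets"`: list with per-class elements
#'   (each a list `genes`, `direction` named +1/-1, `up`, `down`) plus
#'   attributes; `summary(x)` gives the per-class total/up/down count table.
#' @export
case_control_degs <- function(x, main_class, control = "CTR", alpha = 0.05,
                              mc_seed = 1L) {
  validate_expression_matrix(x)
  main_class <- droplevels(as.factor(main_class))
  if (!control %in% levels(main_class))
    stop("control class '", control, "' not present")
  gate <- anova_gate(x, main_class, alpha)
  xg <- x[gate$retained, , drop = FALSE]
  if (nrow(xg) == 0L) {
    classes <- setdiff(levels(main_class), control)
    empty <- lapply(classes, function(cl)
      list(genes = character(0), direction = numeric(0),
           up = character(0), down = character(0)))
    names(empty) <- classes
    return(structure(empty, class = "deg_sets", control = control,
                     alpha = alpha, n_gated = 0L))
  }
  dn <- dunnett_vs_control_matrix(xg, main_class, control, mc_seed = mc_seed)
  sets <- lapply(dn$groups, function(cl) {
    sel <- dn$p_adjusted[, cl] < alpha
    g <- rownames(xg)[sel]
    dir <- setNames(dn$direction[sel, cl], g)
    list(genes = g, direction = dir,
         up = g[dir > 0], down = g[dir < 0])
  })
  names(sets) <- dn$groups
  structure(sets, class = "deg_sets", control = control, alpha = alpha,
            n_gated = nrow(xg))
}

#' @export
summary.deg_sets <- function(object, ...) {
  data.frame(class = names(object),
             total = vapply(object, function(s) length(s$genes), integer(1)),
             up = vapply(object, function(s) length(s$up), integer(1)),
             down = vapply(object, function(s) length(s$down), integer(1)),
             up_pct = vapply(object, function(s)
               if (length(s$genes)) round(100 * length(s$up) / length(s$genes), 2)
               else NA_real_, numeric(1)),
             down_pct = vapply(object, function(s)
               if (length(s$genes)) round(100 * length(s$down) / length(s$genes), 2)
               else NA_real_, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Class-enhanced DEG (CE-DEG) sets
#'
#' A gene is a CE-DEG for class `c` when its adjusted pairwise p-value is
#' below `alpha` for *every* pair (c, c'): it differentiates the class from
#' all other classes in pairwise comparisons. A gene may be a CE-DEG for
#' several classes.
#'
#' @param pw A [pairwise_significance()] object.
#' @param alpha Significance level.
#' @return Named list of gene-id vectors, one per class.
#' @export
ce_deg_sets <- function(pw, alpha = 0.05) {
  stopifnot(inherits(pw, "pairwise_significance"))
  sig <- pw$p < alpha
  if (anyNA(sig)) stop("missing pairwise p-values")
  sets <- lapply(pw$classes, function(cl) {
    cols <- pw$pairs[1L, ] == cl | pw$pairs[2L, ] == cl
    rownames(pw$p)[rowSums(sig[, cols, drop = FALSE]) == sum(cols)]
  })
  names(sets) <- pw$classes
  sets
}

#' Single-class biomarker selection
#'
#' A biomarker for class `c` is a CE-DEG for `c` that additionally shows no
#' significant difference between any pair of the remaining classes; the
#' resulting sets are disjoint across classes by construction.
#'
#' @inheritParams ce_deg_sets
#' @return List with `biomarkers` and `ce_degs` (named lists of gene-id
#'   vectors per class).
#' @export
select_biomarkers <- function(pw, alpha = 0.05) {
  stopifnot(inherits(pw, "pairwise_significance"))
  ce <- ce_deg_sets(pw, alpha)
  sig <- pw$p < alpha
  bio <- lapply(pw$classes, function(cl) {
    others <- pw$pairs[1L, ] != cl & pw$pairs[2L, ] != cl
    quiet <- rowSums(sig[, others, drop = FALSE]) == 0L
    intersect(ce[[cl]], rownames(pw$p)[quiet])
  })
  names(bio) <- pw$classes
  list(biomarkers = bio, ce_degs = ce)
}

#' Dice similarity coefficient of two gene sets
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)}; 0 when both sets are empty.
#'
#' @param a,b Character vectors (gene sets).
#' @return Numeric in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Bootstrap confidence interval for the Dice coefficient
#'
#' Nonparametric gene-level bootstrap: universe genes are resampled with
#' replacement and the Dice coefficient is recomputed on the induced multiset
#' memberships; percentile bounds are returned.
#'
#' @param a,b Gene sets (subsets of `universe`).
#' @param universe All genes the sets were drawn from.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`.
#' @export
dice_confidence_interval <- function(a, b, universe, n_boot = 2000L,
                                     seed = 1L, conf = 0.95) {
  if (!length(universe)) stop("empty universe")
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("sets must be subsets of the universe")
  in_a <- universe %in% a
  in_b <- universe %in% b
  set.seed(seed)
  nu <- length(universe)
  stat <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(nu, nu, replace = TRUE)
    na <- sum(in_a[idx]); nb <- sum(in_b[idx])
    ni <- sum(in_a[idx] & in_b[idx])
    stat[r] <- if (na + nb == 0) 0 else 2 * ni / (na + nb)
  }
  qs <- quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(estimate = dice_coefficient(a, b), lower = qs[1L], upper = qs[2L])
}

#' Dice similarity matrix with confidence intervals
#'
#' All pairwise Dice coefficients among a list of gene sets, with bootstrap
#' confidence intervals.
#'
#' @param sets Named list of gene sets.
#' @param universe Universe of genes.
#' @param n_boot,seed,conf Passed to [dice_confidence_interval()].
#' @return Data frame with `set1`, `set2`, `dsc`, `lower`, `upper`.
#' @export
dice_matrix <- function(sets, universe, n_boot = 2000L, seed = 1L,
                        conf = 0.95) {
  if (length(sets) < 2L) stop("need >= 2 sets")
  prs <- utils::combn(names(sets), 2L)
  res <- apply(prs, 2L, function(pr) {
    ci <- dice_confidence_interval(sets[[pr[1L]]], sets[[pr[2L]]], universe,
                                   n_boot = n_boot, seed = seed, conf = conf)
    c(ci$estimate, ci$lower, ci$upper)
  })
  data.frame(set1 = prs[1L, ], set2 = prs[2L, ], dsc = res[1L, ],
             lower = res[2L, ], upper = res[3L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher-exact term overrepresentation
#'
#' Two-sided Fisher exact test of each user-supplied term set against a
#' query gene set over a gene universe (the classic 2x2 overrepresentation
#' layout). Terms that do not intersect the universe are skipped with a
#' warning.
#'
#' @param query Gene set of interest (subset of `universe`).
#' @param universe All genes under consideration.
#' @param terms Named list of gene sets (e.g. ontology terms).
#' @return Data frame sorted by p-value: `term`, `n_overlap`, `n_term`,
#'   `n_query`, `p`, `odds_ratio` (Inf flagged when the table is degenerate).
#' @export
fisher_enrichment <- function(query, universe, terms) {
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  query <- unique(query); universe <- unique(universe)
  rows <- lapply(names(terms), function(tn) {
    term <- intersect(unique(terms[[tn]]), universe)
    if (!length(term)) {
      warning("term '", tn, "' does not intersect the universe; skipped")
      return(NULL)
    }
    a <- length(intersect(query, term))
    b <- length(setdiff(query, term))
    c_ <- length(setdiff(term, query))
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, c_, b, d), 2L))
    data.frame(term = tn, n_overlap = a, n_term = length(term),
               n_query = length(query), p = ft$p.value,
               odds_ratio = unname(ft$estimate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term intersects the universe")
  out[order(out$p), , drop = FALSE]
}
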