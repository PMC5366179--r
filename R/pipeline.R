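#' Run the full multi-class biomarker-discovery pipeline
#'
#' Orchestrates the stages on an already-summarised log2 matrix: optional
#' empirical-Bayes batch adjustment (with before/after verification counts),
#' two-step adaptive mixture filtering (amplitude, then variance), and the
#' three comparative analyses — (1) main classes vs the control group via
#' ANOVA gate + Dunnett comparisons, (2) all-pairs comparison of the main
#' classes via Kruskal-Wallis gate + Games-Howell post-hoc tests with CE-DEG
#' and biomarker selection, and (3) the same all-pairs analysis across all
#' subtypes. Gene counts after every reduction step are recorded.
#'
#' @param x Expression matrix (genes x samples, log2 scale).
#' @param annotation Sample annotation (`sample_id`, `subtype`, `batch`).
#' @param config An [analysis_config()].
#' @param adjust_batch Run batch adjustment (default TRUE when >1 batch).
#' @param run_cv Also run the repeated cross-validation study on the subtype
#'   labels with the CE-DEG feature selector (default FALSE; costly).
#' @return Object of class `"pipeline_report"`: list with `matrix` (final
#'   filtered, adjusted matrix), `gene_counts` (named, per stage),
#'   `batch_check` (significant-gene fractions before/after adjustment),
#'   `case_control` (deg_sets + summary + Dice matrix), `main_pairs`
#'   (CE-DEGs + biomarkers for the main classes), `subtype_pairs` (same for
#'   subtypes), optional `cv`, `timings` (seconds per stage) and `config`.
#' @export
run_pipeline <- function(x, annotation, config = analysis_config(),
                         adjust_batch = TRUE, run_cv = FALSE) {
  validate_expression_matrix(x)
  annotation <- align_annotation(x, annotation)
  annotation <- merge_to_main_classes(
    annotation,
    class_map = infer_class_map(annotation$subtype))
  alpha <- config$alpha
  stage <- function(name) message("stage: ", name)
  timings <- c(); gene_counts <- c(input = nrow(x))
  tic <- function() proc.time()[["elapsed"]]

  batch_check <- NULL
  if (adjust_batch && length(unique(annotation$batch)) > 1L) {
    stage("batch adjustment")
    t0 <- tic()
    before <- kw_batch_test(x, annotation$batch, alpha)
    x <- combat_adjust(x, annotation$batch, class = annotation$subtype)
    after <- kw_batch_test(x, annotation$batch, alpha)
    batch_check <- c(before = before$fraction_significant,
                     after = after$fraction_significant)
    timings["batch"] <- tic() - t0
  }

  stage("adaptive filtering")
  t0 <- tic()
  amp <- amplitude_filter(x, k_range = config$filter$k_range,
                          n_keep = config$filter$n_keep, seed = config$seed)
  x <- x[amp$retained, , drop = FALSE]
  gene_counts["amplitude_filter"] <- nrow(x)
  vf <- variance_filter(x, k_range = config$filter$k_range,
                        seed = config$seed)
  x <- x[vf$retained, , drop = FALSE]
  gene_counts["variance_filter"] <- nrow(x)
  timings["filter"] <- tic() - t0

  control <- config$test$control
  stage("analysis 1: main classes vs control")
  t0 <- tic()
  cc <- case_control_degs(x, annotation$main_class, control = control,
                          alpha = alpha, mc_seed = config$seed)
  deg_sets_list <- lapply(cc, `[[`, "genes")
  cc_dice <- if (sum(lengths(deg_sets_list) > 0) >= 2L)
    dice_matrix(deg_sets_list[lengths(deg_sets_list) > 0], rownames(x),
                seed = config$seed) else NULL
  gene_counts["case_control_gated"] <- attr(cc, "n_gated")
  timings["case_control"] <- tic() - t0

  stage("analysis 2: main-class pairwise comparisons")
  t0 <- tic()
  main_pairs <- pairwise_analysis(x, annotation$main_class, alpha,
                                  branch = config$test$branch)
  timings["main_pairs"] <- tic() - t0

  stage("analysis 3: subtype pairwise comparisons")
  t0 <- tic()
  subtype_pairs <- pairwise_analysis(x, annotation$subtype, alpha,
                                     branch = config$test$branch)
  timings["subtype_pairs"] <- tic() - t0

  cv <- NULL
  if (run_cv) {
    stage("cross-validation study")
    t0 <- tic()
    cv <- repeated_stratified_cv(x, annotation$subtype,
                                 feature_selector = cedeg_feature_selector(alpha),
                                 k = config$cv$k, reps = config$cv$reps,
                                 seed = config$seed)
    timings["cv"] <- tic() - t0
  }

  structure(list(matrix = x, gene_counts = gene_counts,
                 batch_check = batch_check,
                 case_control = list(degs = cc, summary = summary(cc),
                                     dice = cc_dice),
                 main_pairs = main_pairs, subtype_pairs = subtype_pairs,
                 cv = cv, timings = timings, config = config),
            class = "pipeline_report")
}

# one all-pairs comparative analysis: assumption routing, gate, post-hoc,
# CE-DEG + biomarker selection
pairwise_analysis <- function(x, groups, alpha, branch = "auto") {
  if (branch == "auto")
    branch <- choose_test_branch(x, groups, alpha)$branch
  gate <- if (branch == "parametric") anova_gate(x, groups, alpha)
          else kruskal_wallis_gate(x, groups, alpha)
  xg <- x[gate$retained, , drop = FALSE]
  if (nrow(xg) == 0L) {
    empty <- setNames(rep(list(character(0)), length(unique(groups))),
                      sort(unique(as.character(groups))))
    return(list(branch = branch, n_gated = 0L,
                ce_degs = empty, biomarkers = empty, pairwise = NULL))
  }
  pw <- pairwise_significance(xg, groups)
  sel <- select_biomarkers(pw, alpha)
  list(branch = branch, n_gated = nrow(xg), ce_degs = sel$ce_degs,
       biomarkers = sel$biomarkers, pairwise = pw)
}

# subtype labels outside the built-in 18-class map get an identity mapping,
# so synthetic class names work out of the box
infer_class_map <- function(subtypes) {
  known <- main_class_map()
  u <- unique(subtypes)
  if (all(u %in% names(known))) return(known)
  setNames(u, u)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Multi-class biomarker discovery pipeline\n")
  cat("gene counts per stage:\n")
  print(x$gene_counts)
  if (!is.null(x$batch_check))
    cat(sprintf("batch-significant gene fraction: %.3f before, %.3f after adjustment\n",
                x$batch_check[["before"]], x$batch_check[["after"]]))
  cat("\ncase-control DEG summary:\n")
  print(x$case_control$summary)
  nb <- vapply(x$main_pairs$biomarkers, length, integer(1))
  cat(sprintf("\nmain-class analysis (%s branch): %d CE-DEG-bearing classes, %d biomarkers\n",
              x$main_pairs$branch,
              sum(lengths(x$main_pairs$ce_degs) > 0), sum(nb)))
  nb2 <- vapply(x$subtype_pairs$biomarkers, length, integer(1))
  cat(sprintf("subtype analysis (%s branch): %d biomarkers\n",
              x$subtype_pairs$branch, sum(nb2)))
  if (!is.null(x$cv)) {
    m <- confusion_metrics(x$cv)
    cat(sprintf("cross-validation weighted sensitivity: %.3f (%.3f, %.3f)\n",
                m$weighted, m$ci[1L], m$ci[2L]))
  }
  cat("\nstage timings (s):\n"); print(round(x$timings, 2))
  invisible(x)
}
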