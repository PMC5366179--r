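#' Published class sizes of the MILE Stage-I cohort
#'
#' Sample counts per diagnostic class in Stage I of the Microarray
#' Innovations in Leukaemia (MILE) study: 16 leukaemia subclasses,
#' myelodysplastic syndromes (MDS) and a non-leukaemia/healthy control
#' group, 2096 bone marrow samples in total. These counts are the study
#' conditions the synthetic-data generator emulates and the input to the
#' subclass-merging arithmetic.
#'
#' @return Named integer vector of length 18 (samples per subtype).
#' @seealso [main_class_map()], [merge_to_main_classes()]
#' @export
#' @examples
#' sum(mile_class_sizes()) # 2096
mile_class_sizes <- function() {
  c("B-ALL_t(8;14)"      = 13L,
    "Pro-B-ALL_t(11q23)" = 70L,
    "Pre-B-ALL_t(9;22)+" = 122L,
    "T-ALL"              = 174L,
    "ALL_t(12;21)"       = 58L,
    "ALL_t(1;19)"        = 36L,
    "ALL_HK"             = 40L,
    "Pre-B-ALL_t(9;22)-" = 237L,
    "AML_t(8;21)"        = 40L,
    "AML_t(15;17)"       = 37L,
    "AML_t(16;16)"       = 28L,
    "AML_t(11q23)"       = 38L,
    "AML_NK"             = 351L,
    "AML_CAK"            = 48L,
    "CLL"                = 448L,
    "CML"                = 76L,
    "MDS"                = 206L,
    "CTR"                = 74L)
}

#' Deterministic subtype-to-main-class mapping
#'
#' The eight acute lymphoblastic subclasses merge into ALL, the six acute
#' myeloid subclasses into AML; CLL, CML, MDS and the control group map to
#' themselves, giving six main classes.
#'
#' @return Named character vector: names are the 18 subtype labels, values
#'   the corresponding main class.
#' @export
main_class_map <- function() {
  subtypes <- names(mile_class_sizes())
  main <- c(rep("ALL", 8L), rep("AML", 6L), "CLL", "CML", "MDS", "CTR")
  setNames(main, subtypes)
}

#' Published per-class DEG counts (leukaemia vs control)
#'
#' Numbers of differentially expressed genes per main leukaemia class
#' against the control group, split by direction, as reported in the MILE
#' reanalysis (total / up- / down-regulated). Used for direction-balance
#' arithmetic; the counts themselves are cohort-specific.
#'
#' @return Data frame with columns `class`, `total`, `up`, `down`.
#' @export
mile_deg_counts <- function() {
  data.frame(
    class = c("ALL", "AML", "CLL", "CML", "MDS"),
    total = c(6186L, 5628L, 6577L, 3791L, 1317L),
    up    = c(3110L, 2857L, 3297L, 1509L, 500L),
    down  = c(3076L, 2771L, 3280L, 2282L, 817L),
    stringsAsFactors = FALSE)
}

#' Published cross-validation summaries for the two MILE pipelines
#'
#' Per-subtype sample totals and printed cross-validation sensitivities for
#' the original MILE feature selection (union of top-100 pairwise t-test
#' genes) and the CE-DEG pipeline, together with the correctly-classified
#' diagonal counts that are recoverable from the printed prediction tables.
#' Shipped as plain text under `inst/extdata/mile_cv_tables.tsv`.
#'
#' @return Data frame with columns `class` (C1..C18), `total`,
#'   `sens_original`, `sens_novel`, `diag_original`, `diag_novel` (diagonal
#'   counts, `NA` where not recoverable from the printed table).
#' @export
mile_cv_tables <- function() {
  path <- system.file("extdata", "mile_cv_tables.tsv", package = "cedeg",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Weighted average cross-validation sensitivity
#'
#' Sensitivities weighted by class sample totals:
#' \eqn{\sum_c n_c s_c / \sum_c n_c}.
#'
#' @param sensitivity Per-class sensitivities in `[0, 1]`.
#' @param totals Per-class sample counts (same length).
#' @return Single numeric value.
#' @export
weighted_sensitivity <- function(sensitivity, totals) {
  stopifnot(length(sensitivity) == length(totals), all(totals > 0))
  sum(sensitivity * totals) / sum(totals)
}
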