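#' PCA diagnostic for batch structure
#'
#' Projects mean-centred samples on the top principal directions; colouring
#' the scores by preparation batch is the standard visual check for batch
#' effects before and after adjustment.
#'
#' @param x Expression matrix (genes x samples).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `variance_explained`
#'   (fractions, non-increasing) and `sdev`.
#' @export
pca_diagnostic <- function(x, n_components = 2L) {
  validate_expression_matrix(x)
  n_components <- as.integer(n_components)
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(genes, samples)")
  if (all(apply(x, 1L, var) == 0)) stop("constant matrix: no variance to decompose")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       variance_explained = ve[seq_len(n_components)],
       sdev = pc$sdev[seq_len(n_components)])
}

#' Empirical-Bayes batch adjustment
#'
#' Parametric empirical-Bayes location/scale batch correction (the ComBat
#' model): gene-wise least-squares fit with batch indicators and biological
#' covariates, standardisation by the non-batch fit and pooled SD, per-batch
#' per-gene location/scale estimates shrunk toward batch-level moment-matched
#' hyperpriors (normal on location, inverse-gamma on scale), then removal of
#' the shrunk batch effects and restoration of the non-batch fit. Biological
#' class is passed as a covariate so class-mean differences are preserved in
#' expectation.
#'
#' @param x Expression matrix (genes x samples, log2 scale).
#' @param batch Per-sample batch labels (length = ncol(x)).
#' @param class Optional per-sample biological class labels to protect.
#' @return Adjusted matrix of the same dimensions.
#' @export
combat_adjust <- function(x, batch, class = NULL) {
  validate_expression_matrix(x)
  batch <- as.factor(batch)
  if (length(batch) != ncol(x)) stop("batch must have one label per sample")
  if (nlevels(batch) < 2L) {
    warning("single batch: nothing to adjust, returning input")
    return(x)
  }
  small <- table(batch)
  if (any(small < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(small)[small < 2L], collapse = ", "))
  mod <- NULL
  if (!is.null(class)) {
    class <- as.factor(class)
    if (length(class) != ncol(x)) stop("class must have one label per sample")
    mod <- model.matrix(~class)
    full <- cbind(model.matrix(~batch), mod[, -1L, drop = FALSE])
    if (qr(full)$rank < ncol(full)) {
      conf <- vapply(levels(class), function(cl)
        length(unique(batch[class == cl])) == 1L, logical(1))
      stop("batch and class are confounded (rank-deficient design); ",
           "class level(s) observed in a single batch: ",
           paste(levels(class)[conf], collapse = ", "))
    }
  }
  out <- sva::ComBat(dat = x, batch = batch, mod = mod, par.prior = TRUE,
                     prior.plots = FALSE)
  dimnames(out) <- dimnames(x)
  out
}

#' Per-gene Kruskal-Wallis test against batch
#'
#' Tie-corrected Kruskal-Wallis test of each gene's values across batches;
#' after successful batch adjustment the significant fraction should fall to
#' about the significance level.
#'
#' @param x Expression matrix.
#' @param batch Per-sample batch labels.
#' @param alpha Significance level for the summary count.
#' @return List with `p` (per-gene p-values; 1 for constant genes),
#'   `n_significant` and `fraction_significant`.
#' @export
kw_batch_test <- function(x, batch, alpha = 0.05) {
  validate_expression_matrix(x)
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) stop("need >= 2 batches")
  p <- apply(x, 1L, function(v) {
    if (length(unique(v)) == 1L) return(1)
    kruskal.test(v, batch)$p.value
  })
  p[is.na(p)] <- 1
  list(p = p, n_significant = sum(p < alpha),
       fraction_significant = mean(p < alpha))
}

#' Two-way ANOVA screen for batch and subtype effects
#'
#' Per-gene two-way ANOVA with interaction on the (unbalanced) batch x
#' subtype design using Type-II sums of squares, reporting how many genes are
#' significant for the batch main effect, the subtype main effect, and their
#' interaction. Running it before and after batch adjustment shows batch
#' significance collapsing while subtype signal is retained.
#'
#' @param x Expression matrix.
#' @param batch Per-sample batch labels.
#' @param subtype Per-sample class labels.
#' @param alpha Significance level.
#' @return List with `counts` (named: batch, subtype, interaction), `p`
#'   (genes x 3 matrix) and `df` of the design.
#' @export
twoway_anova_screen <- function(x, batch, subtype, alpha = 0.05) {
  validate_expression_matrix(x)
  batch <- droplevels(as.factor(batch)); subtype <- droplevels(as.factor(subtype))
  if (nlevels(batch) < 2L || nlevels(subtype) < 2L)
    stop("both factors need >= 2 levels")
  n <- ncol(x)
  y <- t(x)                                    # samples x genes
  rss <- function(design) {
    q <- qr(design)
    list(rss = colSums(qr.resid(q, y)^2), rank = q$rank)
  }
  m_b  <- rss(model.matrix(~batch))
  m_s  <- rss(model.matrix(~subtype))
  m_bs <- rss(model.matrix(~batch + subtype))
  m_f  <- rss(model.matrix(~batch * subtype))
  df_res <- n - m_f$rank
  if (df_res <= 0) stop("no residual degrees of freedom for the full model")
  mse <- m_f$rss / df_res
  # Type II: each main effect adjusted for the other; interaction adjusted
  # for both main effects.
  df_batch <- m_bs$rank - m_s$rank
  df_sub   <- m_bs$rank - m_b$rank
  df_int   <- m_f$rank - m_bs$rank
  F_batch <- ((m_s$rss - m_bs$rss) / df_batch) / mse
  F_sub   <- ((m_b$rss - m_bs$rss) / df_sub) / mse
  F_int   <- ((m_bs$rss - m_f$rss) / df_int) / mse
  p <- cbind(batch = pf(F_batch, df_batch, df_res, lower.tail = FALSE),
             subtype = pf(F_sub, df_sub, df_res, lower.tail = FALSE),
             interaction = pf(F_int, df_int, df_res, lower.tail = FALSE))
  p[!is.finite(p)] <- 1
  rownames(p) <- rownames(x)
  list(counts = colSums(p < alpha), p = p,
       df = c(batch = df_batch, subtype = df_sub, interaction = df_int,
              residual = df_res))
}
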