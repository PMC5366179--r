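#' Down-scaled multi-class sample-size profile
#'
#' The 18-class cohort profile scaled to desk size while preserving the
#' imbalance: each class receives `max(min_n, round(scale * n))` samples.
#'
#' @param scale Scaling factor applied to the published class sizes.
#' @param min_n Minimum samples per class after scaling.
#' @param sizes Named vector of full-cohort class sizes
#'   (default [mile_class_sizes()]).
#' @return Named integer vector of class sizes.
#' @export
scaled_class_profile <- function(scale = 1 / 7, min_n = 10L,
                                 sizes = mile_class_sizes()) {
  pmax(as.integer(min_n), as.integer(round(sizes * scale)))
}

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: an unbalanced
#' multi-class cohort processed in several batches, per-gene baselines drawn
#' from a four-component Gaussian mixture (one low-intensity background
#' component plus three signal components), additive and multiplicative
#' per-gene batch effects matching the empirical-Bayes batch-model
#' assumptions, planted class-enhanced genes and single-class biomarkers,
#' and optionally heavy-tailed noise in chosen classes.
#'
#' @param n_genes Number of genes.
#' @param class_sizes Named vector of samples per class; default the
#'   down-scaled 18-class profile of [scaled_class_profile()].
#' @param n_batches Number of preparation batches; samples are assigned to
#'   batches at random (so batch and class are not confounded).
#' @param baseline_mixture List with `weights`, `means`, `sds` of the
#'   baseline mixture on the log2 scale; component 1 is the background.
#' @param effect_size Log2 shift applied to planted differential genes.
#' @param n_ce_degs Number of planted multi-class CE-DEG genes (each
#'   separates two randomly chosen classes, with opposite shifts).
#' @param n_biomarkers_per_class Planted single-class biomarker genes per
#'   class.
#' @param batch_sd_add SD of the additive per-gene batch shifts.
#' @param batch_scale_shape SD (log scale) of the multiplicative per-gene
#'   batch factors applied to the noise term.
#' @param noise_sd Residual SD for signal genes; background genes use
#'   `0.3 * noise_sd`, giving them both low mean and low variance.
#' @param frac_batch_affected Fraction of genes receiving batch effects.
#' @param heavy_tail_classes Character vector of classes whose residuals are
#'   scaled t(3 df) instead of Gaussian (variance still `noise_sd^2`).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              class_sizes = scaled_class_profile(),
                              n_batches = 4L,
                              baseline_mixture = list(
                                weights = c(0.35, 0.30, 0.20, 0.15),
                                means   = c(3.5, 6.5, 8.5, 10.5),
                                sds     = c(0.4, 0.7, 0.7, 0.7)),
                              effect_size = 1.0,
                              n_ce_degs = 40L,
                              n_biomarkers_per_class = 5L,
                              batch_sd_add = 0.5,
                              batch_scale_shape = 0.1,
                              noise_sd = 0.5,
                              frac_batch_affected = 1.0,
                              heavy_tail_classes = character(),
                              seed = 1L) {
  w <- baseline_mixture$weights
  if (abs(sum(w) - 1) > 1e-9) stop("baseline mixture weights must sum to 1")
  if (length(w) != length(baseline_mixture$means) ||
      length(w) != length(baseline_mixture$sds))
    stop("baseline mixture weights/means/sds lengths differ")
  if (n_genes < 1L || n_batches < 1L) stop("counts must be positive")
  if (sum(class_sizes) <= 0L) stop("class_sizes must sum to a positive total")
  if (is.null(names(class_sizes)))
    names(class_sizes) <- sprintf("class%02d", seq_along(class_sizes))
  if (!all(heavy_tail_classes %in% names(class_sizes)))
    stop("heavy_tail_classes not all present in class_sizes")
  structure(list(n_genes = as.integer(n_genes), class_sizes = class_sizes,
                 n_batches = as.integer(n_batches),
                 baseline_mixture = baseline_mixture,
                 effect_size = effect_size, n_ce_degs = as.integer(n_ce_degs),
                 n_biomarkers_per_class = as.integer(n_biomarkers_per_class),
                 batch_sd_add = batch_sd_add,
                 batch_scale_shape = batch_scale_shape, noise_sd = noise_sd,
                 frac_batch_affected = frac_batch_affected,
                 heavy_tail_classes = heavy_tail_classes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-class multi-batch expression dataset with ground truth
#'
#' Generates \eqn{x_{gs} = \mu_g + \beta_{g,k(s)} + \gamma_{g,b(s)} +
#' \delta_{g,b(s)} \epsilon_{gs}} on the log2 scale: per-gene baselines
#' \eqn{\mu_g} from the configured mixture, planted class effects
#' \eqn{\beta}, additive batch shifts \eqn{\gamma \sim N(0,
#' \mathrm{batch\_sd\_add}^2)}, multiplicative batch factors \eqn{\delta}
#' (log-normal) on the residuals. Planted biomarker genes are shifted by
#' \eqn{\pm} `effect_size` in exactly one class; planted CE-DEG genes in two
#' classes with opposite signs. Background genes (mixture component 1) carry
#' no class effects and reduced residual SD.
#'
#' @param config A [simulation_config()].
#' @return List with elements `matrix` (genes x samples), `annotation`
#'   (`sample_id`, `subtype`, `batch`) and `truth` (per-gene `gene_id`,
#'   `is_background`, `ce_deg_classes` (comma-separated, "" if none),
#'   `biomarker_class` (`NA` if none), `batch_affected`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cs <- config$class_sizes
  classes <- names(cs)
  n_s <- sum(cs)
  n_g <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n_g))
  sample_ids <- sprintf("S%04d", seq_len(n_s))
  subtype <- rep(classes, times = cs)
  batch <- sample(sprintf("batch%02d", seq_len(config$n_batches)),
                  n_s, replace = TRUE)
  # ensure every batch has at least 2 samples (EB adjustment precondition)
  for (b in sprintf("batch%02d", seq_len(config$n_batches))) {
    while (sum(batch == b) < 2L) batch[sample(n_s, 1L)] <- b
  }

  bm <- config$baseline_mixture
  comp <- sample(seq_along(bm$weights), n_g, replace = TRUE, prob = bm$weights)
  mu <- rnorm(n_g, bm$means[comp], bm$sds[comp])
  is_background <- comp == 1L

  # plant class effects on non-background genes
  beta <- matrix(0, n_g, length(classes), dimnames = list(gene_ids, classes))
  ce_classes <- vector("list", n_g)
  biomarker_class <- rep(NA_character_, n_g)
  signal_pool <- which(!is_background)
  n_bio <- config$n_biomarkers_per_class * length(classes)
  n_plant <- n_bio + config$n_ce_degs
  if (config$effect_size != 0 && n_plant > 0) {
    if (n_plant > length(signal_pool))
      stop("not enough non-background genes to plant the requested effects")
    planted <- sample(signal_pool, n_plant)
    bio_idx <- planted[seq_len(n_bio)]
    ce_idx <- planted[seq_len(config$n_ce_degs) + n_bio]
    if (n_bio > 0) {
      bio_cls <- rep(classes, each = config$n_biomarkers_per_class)
      sgn <- sample(c(-1, 1), n_bio, replace = TRUE)
      for (i in seq_len(n_bio)) {
        beta[bio_idx[i], bio_cls[i]] <- sgn[i] * config$effect_size
        biomarker_class[bio_idx[i]] <- bio_cls[i]
        ce_classes[[bio_idx[i]]] <- bio_cls[i]
      }
    }
    for (i in seq_along(ce_idx)) {
      two <- sample(classes, 2L)
      beta[ce_idx[i], two] <- c(1, -1) * config$effect_size
      ce_classes[[ce_idx[i]]] <- sort(two)
    }
  }

  # batch effects
  batch_levels <- sort(unique(batch))
  batch_affected <- runif(n_g) < config$frac_batch_affected
  gamma <- matrix(0, n_g, length(batch_levels),
                  dimnames = list(gene_ids, batch_levels))
  delta <- matrix(1, n_g, length(batch_levels),
                  dimnames = list(gene_ids, batch_levels))
  if (config$batch_sd_add > 0)
    gamma[batch_affected, ] <- rnorm(sum(batch_affected) * length(batch_levels),
                                     0, config$batch_sd_add)
  if (config$batch_scale_shape > 0)
    delta[batch_affected, ] <- exp(rnorm(sum(batch_affected) * length(batch_levels),
                                         0, config$batch_scale_shape))

  # residuals: Gaussian, or scaled t(3) in heavy-tailed classes
  sd_g <- ifelse(is_background, 0.3 * config$noise_sd, config$noise_sd)
  eps <- matrix(rnorm(n_g * n_s), n_g, n_s) * sd_g
  if (length(config$heavy_tail_classes)) {
    ht <- subtype %in% config$heavy_tail_classes
    eps[, ht] <- matrix(rt(n_g * sum(ht), df = 3), n_g, sum(ht)) /
      sqrt(3) * sd_g
  }

  bcol <- match(batch, batch_levels)
  kcol <- match(subtype, classes)
  x <- mu + beta[, kcol, drop = FALSE] + gamma[, bcol, drop = FALSE] +
    delta[, bcol, drop = FALSE] * eps
  dimnames(x) <- list(gene_ids, sample_ids)

  truth <- data.frame(
    gene_id = gene_ids,
    is_background = is_background,
    ce_deg_classes = vapply(ce_classes, function(z)
      paste(z, collapse = ","), character(1)),
    biomarker_class = biomarker_class,
    batch_affected = batch_affected,
    stringsAsFactors = FALSE)
  annotation <- data.frame(sample_id = sample_ids, subtype = subtype,
                           batch = batch, stringsAsFactors = FALSE)
  list(matrix = x, annotation = annotation, truth = truth)
}

#' Expand a gene-level matrix to a probe-level fixture
#'
#' Each gene becomes `probes_per_gene` probe rows: probe value = gene value +
#' a per-probe affinity (drawn once, centred to sum to zero within the gene)
#' + independent noise. Used to exercise median-polish summarisation.
#'
#' @param summary Gene-level expression matrix (log2 scale).
#' @param probes_per_gene Probes per gene, at least 2.
#' @param affinity_sd SD of per-probe affinities.
#' @param noise_sd SD of probe-level measurement noise (default 0.1).
#' @param seed Integer seed.
#' @return List with `values` (probe x sample matrix, probe ids
#'   `<gene>_p<k>`) and `genes` (gene id per probe row).
#' @export
simulate_probe_matrix <- function(summary, probes_per_gene = 11L,
                                  affinity_sd = 1.0, noise_sd = 0.1,
                                  seed = 1L) {
  if (probes_per_gene < 2L) stop("probes_per_gene must be >= 2")
  validate_expression_matrix(summary)
  set.seed(seed)
  n_g <- nrow(summary); n_s <- ncol(summary); p <- as.integer(probes_per_gene)
  aff <- matrix(rnorm(n_g * p, 0, affinity_sd), n_g, p)
  aff <- aff - rowMeans(aff)                       # affinities sum to 0 per gene
  genes <- rep(rownames(summary), each = p)
  vals <- summary[genes, , drop = FALSE] + as.vector(t(aff)) +
    matrix(rnorm(n_g * p * n_s, 0, noise_sd), n_g * p, n_s)
  rownames(vals) <- paste0(genes, "_p", rep(seq_len(p), times = n_g))
  list(values = vals, genes = genes)
}
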