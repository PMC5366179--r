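# shared fixture builders for the test suite

# tiny expression matrix with group structure: genes x samples, Gaussian
# noise around per-group means given as a genes x groups matrix
make_group_matrix <- function(group_means, n_per_group, noise_sd = 0.5,
                              seed = 1) {
  set.seed(seed)
  k <- ncol(group_means)
  groups <- rep(colnames(group_means), times = n_per_group)
  x <- group_means[, rep(seq_len(k), times = n_per_group), drop = FALSE] +
    matrix(rnorm(nrow(group_means) * length(groups), 0, noise_sd),
           nrow(group_means), length(groups))
  rownames(x) <- if (is.null(rownames(group_means)))
    sprintf("g%03d", seq_len(nrow(group_means))) else rownames(group_means)
  colnames(x) <- sprintf("s%03d", seq_along(groups))
  list(x = x, groups = groups)
}

# annotation table expanding per-class sizes into one row per sample
make_annotation <- function(class_sizes, n_batches = 1, seed = 1) {
  set.seed(seed)
  n <- sum(class_sizes)
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             subtype = rep(names(class_sizes), times = class_sizes),
             batch = sample(sprintf("b%02d", seq_len(n_batches)), n,
                            replace = TRUE),
             stringsAsFactors = FALSE)
}

# hand-built pairwise_significance object from an explicit p matrix
make_pairwise <- function(p, classes) {
  pairs <- combn(classes, 2)
  stopifnot(ncol(p) == ncol(pairs))
  colnames(p) <- paste(pairs[1, ], pairs[2, ], sep = "|")
  structure(list(p = p, direction = sign(p - 0.5), pairs = pairs,
                 classes = classes),
            class = "pairwise_significance")
}

# independent step-by-step median polish oracle (explicit sweep loop,
# written without reference to stats::medpolish)
medpolish_oracle <- function(mat, max_iter = 20, tol = 1e-6) {
  overall <- 0
  row_eff <- rep(0, nrow(mat))
  col_eff <- rep(0, ncol(mat))
  r <- mat
  last <- 0
  for (it in seq_len(max_iter)) {
    rm_ <- apply(r, 1, median)
    r <- r - rm_
    row_eff <- row_eff + rm_
    cm_ <- median(col_eff)
    overall <- overall + cm_
    col_eff <- col_eff - cm_
    cm2 <- apply(r, 2, median)
    r <- sweep(r, 2, cm2)
    col_eff <- col_eff + cm2
    rm2 <- median(row_eff)
    overall <- overall + rm2
    row_eff <- row_eff - rm2
    s <- sum(abs(r))
    if (s == 0 || abs(s - last) < tol * s) break
    last <- s
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r)
}
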