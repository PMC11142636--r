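#' Revaluation score
#'
#' Change in preference for the pre-revaluation-optimal start state, before
#' versus after revaluation: `clip(p_pre - p_post, 0, 1)`. 0 means no change
#' in preference, 1 a complete reversal.
#'
#' @param p_pre,p_post Preferences in \[0, 1\] (vectors are fine).
#' @return Scores in \[0, 1\].
#' @export
revaluation_score <- function(p_pre, p_post) {
  if (any(p_pre < 0 | p_pre > 1) || any(p_post < 0 | p_post > 1)) {
    stop("preferences must lie in [0, 1]", call. = FALSE)
  }
  clip01(p_pre - p_post)
}

#' Pairwise cosine similarity of logged representation vectors
#'
#' Symmetric matrix of cosine similarities between the rows of a
#' representation log (e.g. the per-step context vectors of a prediction
#' run). Zero rows get similarity 0 with everything (including themselves),
#' with a warning.
#'
#' @param reps Numeric matrix, one representation per row (>= 2 rows), or a
#'   data frame of numeric columns.
#' @return An `n x n` symmetric matrix; unit diagonal for nonzero rows.
#' @export
context_similarity_matrix <- function(reps) {
  reps <- as.matrix(reps)
  if (nrow(reps) < 2L) stop("need at least 2 representation vectors", call. = FALSE)
  nrm <- sqrt(rowSums(reps^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("zero representation vectors present; their similarity is 0 by convention")
    nrm[zero] <- 1
  }
  u <- reps / nrm
  m <- tcrossprod(u)
  m[zero, ] <- 0
  m[, zero] <- 0
  # clamp numerical overshoot
  pmin(pmax(m, -1), 1)
}

#' Decode a latent task label from representation vectors
#'
#' Fits an L2-regularized logistic regression (ridge penalty at a fixed
#' strength) on training-phase representations and reports accuracy on the
#' held-out test representations. Used to ask whether the context layer
#' encodes the active graph.
#'
#' @param train_reps,test_reps Numeric matrices, one representation per
#'   row.
#' @param train_labels,test_labels Two-class label vectors.
#' @param lambda Ridge penalty (fixed, no cross-validation).
#' @return Test accuracy in \[0, 1\].
#' @export
decode_context_labels <- function(train_reps, train_labels,
                                  test_reps, test_labels, lambda = 0.01) {
  train_reps <- as.matrix(train_reps)
  test_reps <- as.matrix(test_reps)
  y <- factor(train_labels)
  if (nlevels(y) != 2L) {
    stop("training labels must contain exactly two classes", call. = FALSE)
  }
  fit <- glmnet::glmnet(train_reps, y,
    family = "binomial", alpha = 0,
    lambda = lambda, standardize = FALSE
  )
  pred <- predict(fit, test_reps, type = "class")[, 1L]
  mean(pred == as.character(factor(test_labels, levels = levels(y))))
}

#' Decode the active graph from a prediction run's context log
#'
#' Sequence-level decoding protocol for a [run_next_state_experiment()]
#' result: each sequence is represented by the mean of its logged context
#' vectors over steps `>= min_step` (the active graph is unidentifiable
#' before the first within-sequence transition, so the first step is
#' excluded by default); a ridge logistic regression is fit on training
#' sequences and scored on the final test sequences.
#'
#' @param run A `study2_run`.
#' @param lambda Ridge penalty passed to [decode_context_labels()].
#' @param min_step First within-sequence step whose context enters the
#'   sequence feature.
#' @return Test decoding accuracy in \[0, 1\].
#' @export
decode_graph <- function(run, lambda = 0.01, min_step = 2) {
  stopifnot(inherits(run, "study2_run"))
  lg <- run$log
  keep <- lg$step >= min_step
  x <- rowsum(run$contexts[keep, , drop = FALSE], lg$sequence[keep]) /
    as.vector(table(lg$sequence[keep]))
  y <- tapply(lg$graph[keep], lg$sequence[keep], function(g) g[1])
  ph <- tapply(lg$phase[keep], lg$sequence[keep], function(p) p[1])
  tr <- ph == "train"
  decode_context_labels(x[tr, , drop = FALSE], y[tr],
    x[!tr, , drop = FALSE], y[!tr],
    lambda = lambda
  )
}

#' Classical multidimensional scaling of representations
#'
#' Torgerson (classical) MDS of the pairwise Euclidean distances between
#' representation rows. Coordinates are only identified up to rotation and
#' reflection, so downstream comparisons should use the embedded distance
#' matrix.
#'
#' @param reps Numeric matrix, one item per row (>= 3 items).
#' @param n_dims Embedding dimension.
#' @return A tibble of coordinates (`dim1`, `dim2`, ...), one row per item.
#' @export
mds_embed <- function(reps, n_dims = 2) {
  reps <- as.matrix(reps)
  if (nrow(reps) < 3L) stop("need at least 3 items to embed", call. = FALSE)
  d <- stats::dist(reps)
  if (max(d) == 0) {
    warning("all representations identical; returning zero coordinates")
    coords <- matrix(0, nrow(reps), n_dims)
  } else {
    coords <- stats::cmdscale(d, k = n_dims)
    if (ncol(coords) < n_dims) { # rank-deficient input
      coords <- cbind(coords, matrix(0, nrow(coords), n_dims - ncol(coords)))
    }
  }
  colnames(coords) <- paste0("dim", seq_len(n_dims))
  tibble::as_tibble(coords)
}

#' Idealized representational-similarity templates
#'
#' Builds the two hypothesis matrices that model representations are
#' compared against, over all stimulus-by-context conditions (ordered as in
#' a `study3_run`'s `conditions` tibble: context 1 then context 2, each
#' row-major over the feature grid).
#'
#' * `task_specific`: within a context, similarity falls linearly with the
#'   difference along that context's *relevant* feature
#'   (`1 - |delta| / (n_levels - 1)`) and ignores the irrelevant one;
#'   across contexts similarity is 0.
#' * `task_general`: similarity falls with the mean absolute difference
#'   across *both* features, identically in and across contexts.
#'
#' @param n_levels Feature levels per dimension.
#' @param kind `"task_specific"` or `"task_general"`.
#' @return A symmetric matrix with unit diagonal, of class `rsa_template`,
#'   with the condition tibble attached as `attr(, "conditions")`.
#' @export
rsa_template <- function(n_levels = 5, kind = c("task_specific", "task_general")) {
  kind <- match.arg(kind)
  grid <- tidyr::expand_grid(
    context = 1:2, f1 = seq_len(n_levels),
    f2 = seq_len(n_levels)
  )
  n <- nrow(grid)
  rng <- n_levels - 1
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (kind == "task_general") {
        d <- (abs(grid$f1[i] - grid$f1[j]) + abs(grid$f2[i] - grid$f2[j])) / 2
        m[i, j] <- 1 - d / rng
      } else if (grid$context[i] == grid$context[j]) {
        rel <- if (grid$context[i] == 1L) "f1" else "f2"
        m[i, j] <- 1 - abs(grid[[rel]][i] - grid[[rel]][j]) / rng
      } # else 0 across contexts
    }
  }
  diag(m) <- 1
  structure(m, class = c("rsa_template", "matrix"), conditions = grid, kind = kind)
}

#' Correlate model representations with an RSA template
#'
#' Builds the model's pairwise similarity matrix over conditions and
#' Pearson-correlates its off-diagonal entries with the template's
#' (Spearman available as an option). The model similarity is the Pearson
#' correlation between condition vectors by default -- the usual RSA choice,
#' since it discounts the activation offset every condition shares -- with
#' raw cosine available as an alternative. The rows of `reps` must be in
#' the template's condition order.
#'
#' @param reps Conditions-by-units representation matrix (e.g. the `reps`
#'   of a `study3_run`).
#' @param template An [rsa_template()] (or any symmetric matrix).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param similarity `"correlation"` (default) or `"cosine"`: how the model
#'   similarity matrix is built.
#' @return Correlation in \[-1, 1\].
#' @export
rsa_template_correlation <- function(reps, template, method = "pearson",
                                     similarity = c("correlation", "cosine")) {
  similarity <- match.arg(similarity)
  reps <- as.matrix(reps)
  template <- unclass(template)
  if (nrow(reps) != nrow(template)) {
    stop("reps and template disagree on the number of conditions", call. = FALSE)
  }
  sim <- if (similarity == "correlation") {
    suppressWarnings(stats::cor(t(reps)))
  } else {
    context_similarity_matrix(reps)
  }
  if (any(!is.finite(sim))) {
    stop("constant representation vectors: correlation undefined", call. = FALSE)
  }
  off <- upper.tri(sim)
  a <- sim[off]
  b <- template[off]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant similarity matrix: correlation undefined", call. = FALSE)
  }
  stats::cor(a, b, method = method)
}

#' Two-sample comparison of metric scores
#'
#' Standard two-sided two-sample test between two groups of per-instance
#' scores: Welch's unpaired t-test or the Mann-Whitney (Wilcoxon rank-sum)
#' U test.
#'
#' @param scores_a,scores_b Numeric vectors (each >= 2 observations).
#' @param test `"t_unpaired"` or `"mann_whitney"`.
#' @return A one-row tibble: `test`, `statistic` (t, or U for
#'   Mann-Whitney), `p_value`.
#' @export
group_compare <- function(scores_a, scores_b,
                          test = c("t_unpaired", "mann_whitney")) {
  test <- match.arg(test)
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (test == "t_unpaired") {
    ht <- stats::t.test(scores_a, scores_b)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(scores_a, scores_b, exact = FALSE))
  }
  tibble::tibble(
    test = test, statistic = unname(ht$statistic),
    p_value = ht$p.value
  )
}

#' Variance of hidden representations along each feature dimension
#'
#' For each context, averages the probed hidden representations over the
#' levels of each feature dimension and reports the total variance of those
#' level means -- how strongly the layer's geometry spreads along that
#' feature. After blocked training the task-irrelevant dimension is
#' expected to be compressed (lower variance) relative to the relevant one.
#'
#' @param reps Conditions-by-units matrix (rows ordered as `conditions`).
#' @param conditions Tibble with `context`, `f1`, `f2` describing the rows.
#' @return A tibble with one row per (context, feature): `context`,
#'   `feature`, `relevant`, `variance`.
#' @export
representation_feature_variance <- function(reps, conditions) {
  reps <- as.matrix(reps)
  stopifnot(nrow(reps) == nrow(conditions))
  purrr::map_dfr(1:2, function(k) {
    idx <- conditions$context == k
    purrr::map_dfr(c("f1", "f2"), function(feat) {
      lev <- conditions[[feat]][idx]
      means <- rowsum(reps[idx, , drop = FALSE], lev) / as.vector(table(lev))
      tibble::tibble(
        context = k, feature = feat,
        relevant = (k == 1L) == (feat == "f1"),
        variance = sum(apply(means, 2L, stats::var))
      )
    })
  })
}
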