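test_that("revaluation scores measure clipped preference change", {
  expect_equal(revaluation_score(0.7, 0.7), 0)
  expect_equal(revaluation_score(1, 0), 1)
  expect_equal(revaluation_score(0.3, 0.8), 0) # improvement clips to zero
  expect_equal(revaluation_score(c(0.9, 0.5), c(0.2, 0.5)), c(0.7, 0))
  expect_error(revaluation_score(1.2, 0.5), "0, 1")
  # antisymmetry under swapping pre/post, up to clipping
  p <- 0.8
  q <- 0.25
  expect_equal(revaluation_score(p, q), p - q)
  expect_equal(revaluation_score(q, p), 0)
})

test_that("context similarity matrices behave on degenerate inputs", {
  x <- rbind(c(1, 0), c(1, 0), c(2, 0))
  expect_equal(context_similarity_matrix(x), matrix(1, 3, 3))
  y <- diag(3)
  expect_equal(context_similarity_matrix(y), diag(3))
  z <- rbind(c(1, 0), c(0, 0))
  expect_warning(m <- context_similarity_matrix(z), "zero")
  expect_equal(m[2, ], c(0, 0))
  expect_error(context_similarity_matrix(matrix(1, 1, 2)), "at least 2")
})

test_that("label decoding separates separable codes and not chance codes", {
  set.seed(61)
  a <- matrix(rnorm(200, mean = 2), 50)
  b <- matrix(rnorm(200, mean = -2), 50)
  acc <- decode_context_labels(rbind(a, b), rep(1:2, each = 50),
    rbind(a[1:10, ], b[1:10, ]), rep(1:2, each = 10)
  )
  expect_equal(acc, 1)

  same <- matrix(rnorm(400), 100)
  acc2 <- decode_context_labels(same, rep(1:2, 50),
    matrix(rnorm(80), 20), rep(1:2, 10)
  )
  expect_gt(acc2, 0.2)
  expect_lt(acc2, 0.8)
  expect_error(
    decode_context_labels(a, rep(1, 50), b, rep(2, 10)),
    "two classes"
  )
})

test_that("decoding and RSA are invariant to a common rotation of the code", {
  set.seed(63)
  labs <- rep(1:2, 25)
  reps <- matrix(rnorm(50 * 6), 50) + outer(ifelse(labs == 1, 2, -2), rep(1, 6))
  q <- qr.Q(qr(matrix(rnorm(36), 6))) # a random orthogonal matrix
  rotated <- reps %*% q
  tmpl <- rsa_template(5, "task_specific")
  # RSA on cosine similarity: angles between rows are rotation-invariant
  expect_equal(
    rsa_template_correlation(reps, tmpl, similarity = "cosine"),
    rsa_template_correlation(rotated, tmpl, similarity = "cosine"),
    tolerance = 1e-10
  )
  acc1 <- decode_context_labels(reps[1:40, ], labs[1:40], reps[41:50, ], labs[41:50])
  acc2 <- decode_context_labels(rotated[1:40, ], labs[1:40], rotated[41:50, ], labs[41:50])
  expect_equal(acc1, acc2)
})

test_that("classical MDS reproduces exact low-dimensional geometry", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  emb <- mds_embed(pts, 2)
  expect_equal(
    as.matrix(dist(emb)), as.matrix(dist(pts)),
    tolerance = 1e-8, ignore_attr = TRUE
  )

  # collinear points leave the second dimension empty
  line <- cbind(1:5, 2 * (1:5))
  emb2 <- mds_embed(line, 2)
  expect_lt(var(emb2$dim2), 1e-10)

  # random reps: embedded distances match an independent spectral oracle
  set.seed(67)
  reps <- matrix(rnorm(60), 10)
  emb3 <- as.matrix(mds_embed(reps, 2))
  d2 <- as.matrix(dist(reps))^2
  j <- diag(10) - 1 / 10
  b <- -0.5 * j %*% d2 %*% j
  ev <- eigen(b, symmetric = TRUE)
  oracle <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  expect_equal(as.matrix(dist(emb3)), as.matrix(dist(oracle)), tolerance = 1e-8)

  expect_warning(mds_embed(matrix(1, 4, 3)), "identical")
  expect_error(mds_embed(matrix(1, 2, 3)), "at least 3")
})

test_that("RSA templates encode their constructive definitions", {
  for (kind in c("task_specific", "task_general")) {
    tm <- rsa_template(5, kind)
    expect_equal(dim(tm), c(50L, 50L))
    expect_equal(unclass(tm), t(unclass(tm)), ignore_attr = TRUE)
    expect_equal(diag(tm), rep(1, 50))
  }
  conds <- attr(rsa_template(5, "task_specific"), "conditions")
  ts <- unclass(rsa_template(5, "task_specific"))
  tg <- unclass(rsa_template(5, "task_general"))
  i <- which(conds$context == 1 & conds$f1 == 1 & conds$f2 == 1)
  j <- which(conds$context == 1 & conds$f1 == 1 & conds$f2 == 5) # irrelevant moves
  k <- which(conds$context == 1 & conds$f1 == 5 & conds$f2 == 1) # relevant moves
  m <- which(conds$context == 2 & conds$f1 == 1 & conds$f2 == 1) # context moves
  # task-specific: depends only on the relevant feature within a context
  expect_equal(ts[i, j], 1)
  expect_equal(ts[i, k], 0)
  expect_equal(ts[i, m], 0)
  # task-general: both features count equally, context is ignored
  expect_equal(tg[i, j], 0.5)
  expect_equal(tg[i, k], 0.5)
  expect_equal(tg[i, m], 1)
})

test_that("template correlations hit their fixed points", {
  tmpl <- rsa_template(3, "task_general")
  conds <- attr(tmpl, "conditions")
  # representations whose cosine-similarity matrix *is* the template: a
  # symmetric PSD matrix factorizes as V sqrt(L), whose row cosines equal it
  ev <- eigen(unclass(tmpl), symmetric = TRUE)
  reps <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  r <- rsa_template_correlation(reps, tmpl, similarity = "cosine")
  expect_equal(r, 1, tolerance = 1e-8)

  # random reps are uncorrelated with the template on average
  rs <- replicate(200, {
    rsa_template_correlation(matrix(rnorm(18 * 5), 18), tmpl)
  })
  expect_lt(abs(mean(rs)), 0.1)

  expect_error(
    rsa_template_correlation(outer(1:18, rep(1, 5)), tmpl),
    "constant|undefined"
  )
})

test_that("group comparisons match closed forms and a brute-force U count", {
  a <- c(1, 2, 3)
  b <- c(10, 11, 12)
  res <- group_compare(a, b, "mann_whitney")
  expect_equal(res$statistic, 0) # complete separation
  expect_lt(res$p_value, 0.1)

  # U equals the number of (a_i > b_j) pairs plus half-ties
  x <- c(3, 5, 8)
  y <- c(2, 5, 9)
  u_brute <- 0
  for (xi in x) {
    for (yj in y) {
      u_brute <- u_brute + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  res2 <- group_compare(x, y, "mann_whitney")
  expect_equal(res2$statistic, u_brute)

  set.seed(73)
  g <- rnorm(20)
  res3 <- group_compare(g, g, "mann_whitney")
  expect_equal(res3$statistic, 20 * 20 / 2)
  expect_gt(res3$p_value, 0.9)

  tt <- group_compare(rnorm(10), rnorm(10) + 5, "t_unpaired")
  expect_lt(tt$p_value, 1e-4)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("feature-variance summaries detect compressed dimensions", {
  conds <- tidyr::expand_grid(context = 1:2, f1 = 1:5, f2 = 1:5)
  # synthetic code: in context 1 only f1 is represented, in context 2 only f2
  reps <- cbind(
    ifelse(conds$context == 1, conds$f1, 0),
    ifelse(conds$context == 2, conds$f2, 0)
  )
  fv <- representation_feature_variance(reps, conds)
  expect_equal(nrow(fv), 4)
  rel <- fv$variance[fv$relevant]
  irr <- fv$variance[!fv$relevant]
  expect_true(all(rel > irr))
})

test_that("sequence-level graph decoding works on a labelled toy run", {
  # synthetic study2_run: contexts are two distinct constants per graph
  lg <- tibble::tibble(
    sequence = rep(1:40, each = 4),
    phase = rep(c("train", "test"), c(120, 40)),
    graph = rep(rep(1:2, 20), each = 4),
    step = rep(1:4, 40),
    stimulus_id = 1L, next_id = 2L,
    prediction = 2L, correct = TRUE
  )
  ctx <- matrix(0, 160, 3)
  ctx[lg$graph == 1, 1] <- 1
  ctx[lg$graph == 2, 2] <- 1
  run <- structure(list(log = lg, contexts = ctx), class = "study2_run")
  expect_equal(decode_graph(run), 1)
})
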