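test_that("append is append-only and validates dimensions", {
  st <- memory_store(3, 2, 1)
  expect_equal(memory_n(st), 0L)

  memory_append(st, c(1, 0, 0), c(0.5, 0.5), 2)
  expect_equal(memory_n(st), 1L)
  expect_equal(st$S[1, ], c(1, 0, 0))
  expect_equal(st$C[1, ], c(0.5, 0.5))
  expect_equal(st$O[1, ], 2)

  # existing rows bit-identical after later appends (incl. buffer growth)
  before <- list(s = st$S[1, ], c = st$C[1, ], o = st$O[1, ])
  for (i in 1:300) memory_append(st, c(0, 1, 0), c(1, 0), i)
  expect_equal(memory_n(st), 301L)
  expect_identical(st$S[1, ], before$s)
  expect_identical(st$C[1, ], before$c)
  expect_identical(st$O[1, ], before$o)

  # duplicates are retained, not merged
  st2 <- memory_store(2, 2, 1)
  memory_append(st2, c(1, 0), c(0, 1), 1)
  memory_append(st2, c(1, 0), c(0, 1), 1)
  expect_equal(memory_n(st2), 2L)
  expect_equal(st2$S[1, ], st2$S[2, ])

  expect_error(memory_append(st2, c(1, 0, 0), c(0, 1), 1), "stimulus")
  expect_error(memory_append(st2, c(1, 0), c(0, 1, 0), 1), "context")
  expect_error(memory_append(st2, c(1, 0), c(0, 1), c(1, 2)), "outcome")
})

test_that("retrieval weights form a simplex and match hand cases", {
  # single exactly matching row -> weight 1
  st <- toy_store(
    matrix(c(1, 0), 1),
    matrix(c(0, 1), 1),
    matrix(5, 1)
  )
  w <- memory_weights(st, c(1, 0), c(0, 1))
  expect_equal(w, 1)

  # two rows with identical scores -> 0.5 each
  st2 <- toy_store(
    rbind(c(1, 0), c(0, 1)),
    rbind(c(1, 0), c(0, 1)),
    matrix(1:2, 2)
  )
  w2 <- memory_weights(st2, c(1, 1), c(1, 1))
  expect_equal(w2, c(0.5, 0.5))
})

test_that("weights match a brute-force cosine + softmax oracle", {
  set.seed(42)
  S <- matrix(rnorm(9), 3)
  C <- matrix(rnorm(9), 3)
  O <- matrix(rnorm(3), 3)
  st <- toy_store(S, C, O)
  qs <- rnorm(3)
  qc <- rnorm(3)
  cfg <- retrieval_config(tau = 0.1)
  w <- memory_weights(st, qs, qc, cfg)
  w_or <- oracle_retrieval_weights(S, C, qs, qc, tau = 0.1)
  expect_equal(w, w_or, tolerance = 1e-8)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))

  # mixing weights enter the score linearly
  cfg2 <- retrieval_config(tau = 0.2, stimulus_weight = 0.4, context_weight = 1.7)
  expect_equal(
    memory_weights(st, qs, qc, cfg2),
    oracle_retrieval_weights(S, C, qs, qc, tau = 0.2, sw = 0.4, cw = 1.7),
    tolerance = 1e-8
  )
})

test_that("zero queries contribute zero similarity instead of erroring", {
  set.seed(1)
  st <- toy_store(matrix(rnorm(6), 2), matrix(rnorm(6), 2), matrix(rnorm(2), 2))
  w <- memory_weights(st, c(0, 0, 0), rnorm(3))
  expect_equal(sum(w), 1)
  # zero on both sides: all scores equal -> uniform
  expect_equal(memory_weights(st, rep(0, 3), rep(0, 3)), c(0.5, 0.5))
  expect_error(
    memory_weights(memory_store(3, 3, 1), rnorm(3), rnorm(3)),
    "no memories"
  )
})

test_that("reading with weights is the stored rows' convex combination", {
  set.seed(7)
  S <- matrix(rnorm(12), 4)
  C <- matrix(rnorm(12), 4)
  O <- matrix(rnorm(8), 4)
  st <- toy_store(S, C, O)

  # one-hot weights return the row exactly
  r1 <- memory_read(st, c(0, 0, 1, 0))
  expect_equal(r1$stimulus, S[3, ])
  expect_equal(r1$context, C[3, ])
  expect_equal(r1$outcome, O[3, ])

  # uniform weights over 2 rows = elementwise mean
  st2 <- toy_store(S[1:2, ], C[1:2, ], O[1:2, , drop = FALSE])
  r2 <- memory_read(st2, c(0.5, 0.5))
  expect_equal(r2$stimulus, colMeans(S[1:2, ]))

  # random simplex weights match the loop oracle
  w <- runif(4)
  w <- w / sum(w)
  r3 <- memory_read(st, w)
  expect_equal(r3$stimulus, oracle_weighted_average(S, w), tolerance = 1e-12)
  expect_equal(r3$context, oracle_weighted_average(C, w), tolerance = 1e-12)
  expect_equal(r3$outcome, oracle_weighted_average(O, w), tolerance = 1e-12)

  # convex-combination bound, componentwise
  for (j in seq_len(ncol(S))) {
    expect_gte(r3$stimulus[j], min(S[, j]))
    expect_lte(r3$stimulus[j], max(S[, j]))
  }

  expect_error(memory_read(st, c(1, 0)), "length")
  expect_error(memory_read(st, c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("tau -> 0 retrieval converges to the nearest-neighbour row", {
  set.seed(11)
  S <- matrix(rnorm(15), 5)
  C <- matrix(rnorm(15), 5)
  O <- matrix(rnorm(5), 5)
  st <- toy_store(S, C, O)
  qs <- rnorm(3)
  qc <- rnorm(3)
  sc <- sapply(seq_len(5), function(i) {
    oracle_cosine(qs, S[i, ]) + oracle_cosine(qc, C[i, ])
  })
  best <- which.max(sc)
  rec <- memory_recall(st, qs, qc, retrieval_config(tau = 1e-6))
  expect_equal(rec$stimulus, S[best, ], tolerance = 1e-8)
  expect_equal(rec$outcome, O[best, ], tolerance = 1e-8)
})

test_that("retrieval is invariant to row permutation", {
  set.seed(13)
  S <- matrix(rnorm(12), 4)
  C <- matrix(rnorm(12), 4)
  O <- matrix(rnorm(4), 4)
  p <- sample(4)
  qs <- rnorm(3)
  qc <- rnorm(3)
  r1 <- memory_recall(toy_store(S, C, O), qs, qc)
  r2 <- memory_recall(toy_store(S[p, ], C[p, ], O[p, , drop = FALSE]), qs, qc)
  expect_equal(r1$stimulus, r2$stimulus, tolerance = 1e-12)
  expect_equal(r1$outcome, r2$outcome, tolerance = 1e-12)
})

test_that("retrieval gradient w.r.t. the query context passes a finite-difference check", {
  set.seed(17)
  for (rep in 1:3) {
    S <- matrix(rnorm(12), 4)
    C <- matrix(rnorm(12), 4)
    O <- matrix(rnorm(8), 4)
    st <- toy_store(S, C, O)
    qs <- rnorm(3)
    qc <- rnorm(3)
    up <- rnorm(2)
    cfg <- retrieval_config(tau = 0.3)
    g <- memory_context_grad(st, qs, qc, up, cfg)
    f <- function(x) {
      sum(up * memory_read(st, memory_weights(st, qs, x, cfg))$outcome)
    }
    expect_lt(rel_err(g, fd_gradient(f, qc)), 1e-4)
  }
})

test_that("the engines' fused recall matches the module operations exactly", {
  set.seed(19)
  S <- matrix(rnorm(18), 6)
  C <- matrix(rnorm(24), 6)
  O <- matrix(rnorm(12), 6)
  st <- toy_store(S, C, O)
  qs <- rnorm(3)
  qc <- rnorm(4)
  up <- rnorm(2)
  cfg <- retrieval_config(tau = 0.17, stimulus_weight = 0.6)
  fused <- egoframe:::recall_with_grad(st, qs, qc, cfg)
  w <- memory_weights(st, qs, qc, cfg)
  slow <- memory_read(st, w)
  expect_equal(fused$weights, w, tolerance = 1e-12)
  expect_equal(fused$stimulus, slow$stimulus, tolerance = 1e-12)
  expect_equal(fused$context, slow$context, tolerance = 1e-12)
  expect_equal(fused$outcome, slow$outcome, tolerance = 1e-12)
  expect_equal(
    fused$context_grad(up),
    memory_context_grad(st, qs, qc, up, cfg),
    tolerance = 1e-12
  )
})

test_that("empty-store recall returns a flagged zero retrieval", {
  st <- memory_store(2, 3, 1)
  rec <- memory_recall(st, c(1, 0), c(0, 0, 1))
  expect_true(rec$empty)
  expect_equal(rec$stimulus, c(0, 0))
  expect_equal(rec$context, c(0, 0, 0))
  expect_equal(rec$outcome, 0)
})

test_that("a store round-trips through its delimited dump", {
  set.seed(23)
  st <- toy_store(matrix(rnorm(6), 2), matrix(rnorm(4), 2), matrix(rnorm(2), 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  memory_export(st, path)
  st2 <- memory_import(path)
  expect_equal(memory_n(st2), 2L)
  expect_equal(st2$S[1:2, ], st$S[1:2, ], tolerance = 1e-12)
  expect_equal(st2$C[1:2, ], st$C[1:2, ], tolerance = 1e-12)
  expect_equal(st2$O[1:2, , drop = FALSE], st$O[1:2, , drop = FALSE],
    tolerance = 1e-12
  )
  tb <- tibble::as_tibble(st)
  expect_named(tb, c("s_1", "s_2", "s_3", "c_1", "c_2", "o_1"))
})

test_that("the linear weight transform clips negatives and normalizes", {
  st <- toy_store(
    rbind(c(1, 0), c(-1, 0), c(0, 1)),
    rbind(c(1, 0), c(1, 0), c(1, 0)),
    matrix(1:3, 3)
  )
  cfg <- retrieval_config(
    tau = 1, stimulus_weight = 1, context_weight = 0,
    transform = "linear"
  )
  w <- memory_weights(st, c(1, 0), c(0, 1), cfg)
  expect_equal(w, c(1, 0, 0)) # scores 1, -1, 0 -> clipped to 1, 0, 0
})
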