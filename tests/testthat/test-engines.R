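test_that("observation mode writes one predecessor-only memory per stimulus", {
  sp <- study1_spec("reward_revaluation", n_passes = 2)
  trials <- make_study1_trials(sp, 3)
  learn <- trials[trials$phase == "learning", ]
  # the write order (store first, integrate the stimulus afterwards) means a
  # stored context can only contain predecessors; with retrieved-context
  # blending switched off this is exact and exhaustively checkable
  model <- study1_model(init_sd = 0, gamma = 0)
  out <- run_observation(learn, model)
  expect_equal(memory_n(out$model$store), nrow(learn))
  st <- out$model$store
  for (i in seq_len(memory_n(st))) {
    s_id <- which.max(st$S[i, ])
    expect_equal(st$C[i, s_id], 0)
  }
  # the default (reinstating) model still writes exactly one row per step
  out2 <- run_observation(learn, study1_model())
  expect_equal(memory_n(out2$model$store), nrow(learn))
})

test_that("with no retrieved-context blending the stored context is the bare integrator", {
  sp <- study1_spec("reward_revaluation", n_passes = 1)
  trials <- make_study1_trials(sp, 3)
  learn <- trials[trials$phase == "learning", ]
  model <- study1_model(gamma = 0, rho = 0.5, beta = 1, init_sd = 0, normalize = FALSE)
  out <- run_observation(learn, model)
  st <- out$model$store
  # hand-unrolled integrator: context stored with the 3rd state of a pass
  # is 0.5 * e(first) + 1 * e(second)
  for (tr in c("A", "B")) {
    rows <- which(learn$trajectory == tr)
    states <- learn$stimulus_id[rows]
    expected <- 0.5 * onehot(states[1], 6) + onehot(states[2], 6)
    expect_equal(st$C[rows[3], ], expected, tolerance = 1e-12)
    # and the state-3 context carries only the first state
    expect_equal(st$C[rows[2], ], onehot(states[1], 6), tolerance = 1e-12)
  }
})

test_that("sharp-retrieval rollouts replay the observed trajectory and its reward", {
  sp <- study1_spec("reward_revaluation", r_a = 1, r_b = 10, n_passes = 5)
  trials <- make_study1_trials(sp, 3)
  learn <- trials[trials$phase == "learning", ]
  model <- study1_model(tau = 1e-6, init_sd = 0, gamma = 0.5)
  model <- run_observation(learn, model)$model

  v1 <- estimate_value(model, 1L)
  expect_equal(v1$trace$retrieved_state, c(1L, 3L, 5L))
  expect_equal(v1$V, 1) # trajectory A's terminal reward
  v2 <- estimate_value(model, 2L)
  expect_equal(v2$trace$retrieved_state, c(2L, 4L, 6L))
  expect_equal(v2$V, 10)

  # after reward revaluation the same rollout finds the swapped reward
  reval <- trials[trials$phase == "revaluation", ]
  model2 <- run_observation(reval, model)$model
  v1b <- estimate_value(model2, 1L)
  expect_gt(v1b$V, 5) # now dominated by the new 10 reward

  expect_equal(estimate_value(model, 1L, n_queries = 0)$V, 0)
  expect_error(estimate_value(model, 1L, n_queries = -1), "n_queries")
  expect_error(
    estimate_value(study1_model(), 1L),
    "no memories"
  )
})

test_that("preferences are a logistic function of the value difference", {
  expect_equal(decide_preference(3, 3), 0.5)
  expect_gt(decide_preference(100, 0), 0.999)
  expect_lt(decide_preference(0, 100), 0.001)
  # closed form at kappa = 1
  expect_equal(decide_preference(2, 0, kappa = 1), 1 / (1 + exp(-2)))
  v <- estimate_value # accepts value_estimate objects too
  sp <- study1_spec("reward_revaluation", n_passes = 2)
  m <- run_observation(
    make_study1_trials(sp, 1)[1:6, ],
    study1_model(init_sd = 0)
  )$model
  expect_equal(
    decide_preference(estimate_value(m, 1L), estimate_value(m, 1L)), 0.5
  )
})

test_that("the prediction engine starts uninformed and learns a single graph quickly", {
  sp <- study2_spec("blocked", n_train = 30, n_test = 5, block_length = 30)
  seqs <- make_study2_sequences(sp, 21)
  r <- run_next_state_experiment(seqs, study2_config(), 22)
  # with one graph only, accuracy over the last third is high
  lg <- r$log
  late <- lg$sequence > 20 & lg$phase == "train"
  expect_gt(mean(lg$correct[late]), 0.8)
  # logs align with the stream
  expect_equal(nrow(r$contexts), nrow(lg))
  expect_equal(dim(r$contexts)[2], study2_config()$d_c)
})

test_that("engine runs are bit-identical under a fixed seed", {
  sp <- study2_spec("interleaved", n_train = 12, n_test = 4)
  seqs <- make_study2_sequences(sp, 31)
  r1 <- run_next_state_experiment(seqs, study2_config(), 32)
  r2 <- run_next_state_experiment(seqs, study2_config(), 32)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$contexts, r2$contexts)
  expect_identical(r1$params, r2$params)

  tr <- make_study3_trials(study3_spec("blocked", n_train = 40, n_test = 10), 33)
  s1 <- run_category_experiment(tr, study3_config(), 34)
  s2 <- run_category_experiment(tr, study3_config(), 34)
  expect_identical(s1$log, s2$log)
  expect_identical(s1$reps, s2$reps)
})

test_that("an untrained recurrent baseline predicts at chance", {
  sp <- study2_spec("interleaved", n_train = 50, n_test = 10)
  seqs <- make_study2_sequences(sp, 41)
  # first sequences, before any learning has accumulated: about 1 in 10
  r <- run_rnn_baseline(seqs, study2_config(), 42)
  early <- r$log$sequence <= 10
  expect_lt(mean(r$log$correct[early]), 0.35)
})

test_that("the category engine solves an easy separable regime", {
  # single context throughout: no task conflict, boundary-distant stimuli
  # should be classified correctly by the end
  sp <- study3_spec("blocked", n_train = 300, n_test = 50, block_length = 300)
  tr <- make_study3_trials(sp, 51)
  r <- run_category_experiment(tr, study3_config(), 52)
  lg <- r$log
  far <- abs(lg$f1 - 3) >= 2 & lg$phase == "test"
  expect_gt(mean(lg$correct[far]), 0.8)
  expect_equal(dim(r$reps), c(50L, study3_config()$d_h))
  expect_equal(nrow(r$conditions), 50L)
})
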