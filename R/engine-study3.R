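#' Configuration for the category-learning agent
#'
#' The full architecture: MGU context module (fed by the stimulus encoding,
#' the context cue, and optionally the previously retrieved context),
#' episodic retrieval over (stimulus + cue, context) keys with two-way
#' accept/reject outcomes, and the semantic pathway's context-dependent
#' hidden layer. The two pathway outputs are combined (elementwise mean by
#' default) and scored with a softmax cross-entropy on the reward sign.
#'
#' @param d_c Context dimension.
#' @param d_h Semantic hidden-layer dimension.
#' @param eta MGU learning rate.
#' @param eta_sem Semantic-pathway learning rate.
#' @param tau Retrieval softmax temperature.
#' @param stimulus_weight,context_weight Retrieval similarity mixing
#'   weights.
#' @param combination Pathway combination rule, see [combine_predictions()];
#'   `"wmean"` is a weighted mixture with semantic weight `sem_vote`.
#' @param sem_vote Semantic-pathway weight of the `"wmean"` mixture.
#' @param init_sd Weight-initialization scale.
#' @param use_retrieved_input Include the previously retrieved context in
#'   the MGU input.
#' @param gamma Blend weight for folding the retrieved context back into
#'   the context state after each query (reinstatement), as in the other
#'   engines.
#' @param cue_gain Gain on the context-cue portion of the MGU input
#'   (salience of the cue relative to the stimulus features).
#' @param sem_context_sd Initialization scale of the semantic pathway's
#'   context-to-hidden weights (see [semantic_init()]).
#' @param key_cue_gain Gain on the cue portion of the episodic memory key
#'   (the cue's retrieval salience, independent of its salience in the
#'   context update).
#' @param clip_norm Gradient-norm clip on the context gradient.
#' @param normalize Unit-normalize the context state each step.
#' @return A list of class `study3_config`.
#' @export
study3_config <- function(d_c = 16, d_h = 16, eta = 0.3, eta_sem = 0.1,
                          tau = 0.1, stimulus_weight = 0.6, context_weight = 1,
                          combination = "mean", sem_vote = 0.75,
                          init_sd = 0.3,
                          use_retrieved_input = TRUE, gamma = 0.5,
                          cue_gain = 0.5, key_cue_gain = 1,
                          sem_context_sd = 2.5,
                          clip_norm = 1, normalize = TRUE) {
  structure(
    list(
      d_c = as.integer(d_c), d_h = as.integer(d_h),
      eta = eta, eta_sem = eta_sem, combination = combination,
      sem_vote = sem_vote,
      init_sd = init_sd, gamma = gamma, cue_gain = cue_gain,
      key_cue_gain = key_cue_gain,
      sem_context_sd = sem_context_sd, clip_norm = clip_norm,
      normalize = isTRUE(normalize),
      use_retrieved_input = isTRUE(use_retrieved_input),
      retrieval = retrieval_config(
        tau = tau, stimulus_weight = stimulus_weight,
        context_weight = context_weight
      )
    ),
    class = "study3_config"
  )
}

#' Run the context-cued category-learning experiment
#'
#' Online loop over a trial stream from [make_study3_trials()]. Per trial
#' the agent updates its context through the MGU from the stimulus and the
#' context cue; runs the semantic forward pass; queries episodic memory;
#' combines the two pathway outputs; responds (argmax accept/reject);
#' observes the reward sign; and backpropagates the cross-entropy error
#' through both pathways -- semantic weights directly, episodic retrieval
#' into the context, both truncated at the previous context state.
#'
#' After the run, a representation probe evaluates the semantic hidden
#' layer for every stimulus-by-context condition, pairing each stimulus
#' with the mean test-phase context vector of each context.
#'
#' @param trials A tibble from [make_study3_trials()].
#' @param config A [study3_config()].
#' @param seed Integer seed.
#' @return A list of class `study3_run`: `log` (per-trial tibble with
#'   `prediction`, `correct`), `reps` (conditions-by-hidden matrix of probed
#'   hidden representations), `conditions` (tibble describing each row of
#'   `reps`: `context`, `f1`, `f2`), `params`, `semantic`, `store`.
#' @export
run_category_experiment <- function(trials, config = study3_config(),
                                    seed = NULL) {
  stopifnot(inherits(config, "study3_config"))
  with_local_seed(seed, {
    n_levels <- max(trials$f1, trials$f2)
    d_stim <- 2L * n_levels
    d_cue <- 2L
    d_c <- config$d_c
    d_in <- d_stim + d_cue + if (config$use_retrieved_input) d_c else 0L
    params <- mgu_init(d_in, d_c, eta = config$eta, init_sd = config$init_sd)
    semp <- semantic_init(d_stim, d_c, config$d_h,
      d_o = 2L,
      eta = config$eta_sem, init_sd = 1,
      context_sd = config$sem_context_sd
    )
    d_key <- d_stim + d_cue
    store <- memory_store(d_key, d_c, 2L, capacity = 256L)
    ctx <- fresh_context(d_c, 0.1)
    retr_ctx <- numeric(d_c)
    n <- nrow(trials)
    pred <- integer(n)
    contexts <- matrix(0, n, d_c)
    for (i in seq_len(n)) {
      stim <- study3_encode_stimulus(trials$f1[i], trials$f2[i], n_levels)
      cue1 <- one_hot(trials$context[i], 2L)
      key <- c(stim, config$key_cue_gain * cue1)
      inp0 <- c(stim, config$cue_gain * cue1)
      input <- if (config$use_retrieved_input) c(inp0, retr_ctx) else inp0
      stepres <- mgu_step(params, ctx, input)
      ctx <- stepres$context
      sem <- semantic_forward(semp, stim, ctx)
      rec <- recall_with_grad(store, key, ctx, config$retrieval,
        with_stimulus = FALSE
      )
      # both pathways vote on a probability scale: the semantic logits pass
      # through a softmax, the retrieved outcome is already a distribution
      sem_p <- softmax(sem$output)
      epi_p <- if (rec$empty) rep(0.5, 2L) else rec$outcome
      comb <- if (config$combination == "wmean") {
        (1 - config$sem_vote) * epi_p + config$sem_vote * sem_p
      } else {
        combine_predictions(epi_p, sem_p, config$combination)
      }
      comb <- comb / sum(comb)
      pred[i] <- argmax_rand(comb)
      y <- if (trials$reward[i] > 0) 1L else 2L
      g_comb <- numeric(2L) # d(-log comb[y]) / d comb
      g_comb[y] <- -1 / (comb[y] + 1e-3)
      gs <- switch(config$combination,
        mean = list(sem = g_comb / 2, epi = g_comb / 2),
        wmean = list(
          sem = config$sem_vote * g_comb,
          epi = (1 - config$sem_vote) * g_comb
        ),
        sum = list(sem = g_comb, epi = g_comb),
        semantic_only = list(sem = g_comb, epi = numeric(2L)),
        episodic_only = list(sem = numeric(2L), epi = g_comb)
      )
      # through the semantic softmax
      g_sem_logits <- sem_p * (gs$sem - sum(sem_p * gs$sem))
      semback <- semantic_backward(semp, sem$cache, g_sem_logits)
      gctx <- semback$grad_context
      if (!rec$empty && any(gs$epi != 0)) {
        gctx <- gctx + rec$context_grad(gs$epi)
      }
      semp <- semantic_update(semp, semback)
      gctx <- clip_grad(gctx, config$clip_norm)
      params <- mgu_update(params, mgu_backward(params, stepres$cache, gctx))
      retr_ctx <- rec$context
      if (!rec$empty && config$gamma > 0) {
        ctx <- (1 - config$gamma) * ctx + config$gamma * rec$context
      }
      if (config$normalize) ctx <- unit_norm(ctx)
      contexts[i, ] <- ctx
      memory_append(store, key, ctx, one_hot(y, 2L))
    }
    # representation probe: each stimulus paired with each context's mean
    # training-phase context vector (the representation regime the
    # schedule actually produced)
    tr_idx <- which(trials$phase == "train")
    if (!length(tr_idx)) tr_idx <- seq_len(n)
    cbar <- lapply(1:2, function(k) {
      rows <- tr_idx[trials$context[tr_idx] == k]
      if (!length(rows)) rows <- tr_idx
      colMeans(contexts[rows, , drop = FALSE])
    })
    grid <- tidyr::expand_grid(
      context = 1:2, f1 = seq_len(n_levels),
      f2 = seq_len(n_levels)
    )
    reps <- t(vapply(seq_len(nrow(grid)), function(r) {
      semantic_forward(
        semp,
        study3_encode_stimulus(grid$f1[r], grid$f2[r], n_levels),
        cbar[[grid$context[r]]]
      )$hidden
    }, numeric(config$d_h)))
    structure(
      list(
        log = dplyr::mutate(trials,
          prediction = pred,
          correct = (pred == 1L) == (trials$reward > 0)
        ),
        reps = reps, conditions = grid,
        params = params, semantic = semp, store = store
      ),
      class = "study3_run"
    )
  })
}
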