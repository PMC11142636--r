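#' Configuration for the next-state prediction agent
#'
#' Hyperparameters of the memory-augmented prediction agent: a Minimal
#' Gated Unit context module feeding episodic retrieval over (stimulus,
#' context) keys. The MGU input is the one-hot stimulus, optionally
#' concatenated with the context retrieved on the previous step (so
#' reinstated memories can steer the context).
#'
#' @param d_c Context dimension.
#' @param eta MGU learning rate (deliberately high: online learning from
#'   hundreds of trials).
#' @param tau Retrieval softmax temperature.
#' @param stimulus_weight,context_weight Retrieval similarity mixing
#'   weights.
#' @param init_sd Weight-initialization scale (see [mgu_init()]) and the
#'   scale of the initial context noise.
#' @param use_retrieved_input Include the previously retrieved context in
#'   the MGU input (default `TRUE`).
#' @param stimulus_gain Gain on the stimulus portion of the MGU input.
#'   Values below 1 make the context dynamics lean on reinstated
#'   (retrieved) context rather than on building stimulus-specific codes.
#' @param gamma Blend weight for folding the retrieved context directly
#'   back into the context state after each query (as in the
#'   linear-integrator agent); 0 disables and leaves reinstatement entirely
#'   to the learned input pathway.
#' @param eps Floor inside the cross-entropy log (bounds the error
#'   gradient, since the retrieved outcome can assign a remembered-next-state
#'   probability of exactly zero).
#' @param clip_norm Maximum Euclidean norm of the context gradient before
#'   it enters the MGU backward pass (standard recurrent-network gradient
#'   clipping); `Inf` disables.
#' @param loss `"ce"` (cross-entropy on the retrieved next-state
#'   distribution) or `"mse"` (squared error).
#' @param normalize Rescale the context state to unit Euclidean norm at the
#'   end of every step (retrieval is cosine-based, so this fixes the
#'   state's scale without changing what is retrieved).
#' @return A list of class `study2_config`.
#' @export
study2_config <- function(d_c = 16, eta = 0.5, tau = 0.25,
                          stimulus_weight = 0.3, context_weight = 1,
                          init_sd = 0.3, use_retrieved_input = TRUE,
                          stimulus_gain = 1, gamma = 0.5,
                          eps = 1e-3, clip_norm = 1, loss = c("ce", "mse"),
                          normalize = TRUE) {
  loss <- match.arg(loss)
  structure(
    list(
      d_c = as.integer(d_c), eta = eta, init_sd = init_sd,
      use_retrieved_input = isTRUE(use_retrieved_input),
      stimulus_gain = stimulus_gain, gamma = gamma, eps = eps,
      clip_norm = clip_norm, loss = loss, normalize = isTRUE(normalize),
      retrieval = retrieval_config(
        tau = tau, stimulus_weight = stimulus_weight,
        context_weight = context_weight
      )
    ),
    class = "study2_config"
  )
}

clip_grad <- function(g, max_norm) {
  n <- sqrt(sum(g^2))
  if (is.finite(max_norm) && n > max_norm) g * (max_norm / n) else g
}

# random tie-breaking argmax
argmax_rand <- function(x) {
  m <- which(x == max(x))
  if (length(m) == 1L) m else m[sample.int(length(m), 1L)]
}

#' Run the memory-augmented next-state prediction experiment
#'
#' Online loop over a sequence stream from [make_study2_sequences()]. Per
#' transition the agent: updates its context through the MGU; queries
#' episodic memory with the one-hot stimulus and the updated context;
#' predicts the next state as the argmax of the retrieved outcome; observes
#' the true next state; backpropagates the cross-entropy error through the
#' (differentiable) retrieval into the MGU weights, truncated at the
#' previous context; and appends (stimulus, context, true next state) to
#' memory. The context persists across sequences, so block structure is
#' something the agent has to discover.
#'
#' @param sequences A tibble from [make_study2_sequences()].
#' @param config A [study2_config()].
#' @param seed Integer seed (weight init, context noise, tie-breaking).
#' @return A list of class `study2_run`: `log` (per-transition tibble with
#'   `sequence`, `phase`, `graph`, `step`, `stimulus_id`, `next_id`,
#'   `prediction`, `correct`), `contexts` (matrix, one row per transition:
#'   the context used for the query), `params` (final MGU weights), and
#'   `store`.
#' @export
run_next_state_experiment <- function(sequences, config = study2_config(),
                                      seed = NULL) {
  stopifnot(inherits(config, "study2_config"))
  with_local_seed(seed, {
    n_states <- max(sequences$stimulus_id, sequences$next_id)
    d_c <- config$d_c
    d_in <- n_states + if (config$use_retrieved_input) d_c else 0L
    params <- mgu_init(d_in, d_c, eta = config$eta, init_sd = config$init_sd)
    store <- memory_store(n_states, d_c, n_states, capacity = 256L)
    ctx <- fresh_context(d_c, 0.1)
    retr_ctx <- numeric(d_c)
    n <- nrow(sequences)
    contexts <- matrix(0, n, d_c)
    pred <- integer(n)
    stim_ids <- sequences$stimulus_id
    next_ids <- sequences$next_id
    for (i in seq_len(n)) {
      s <- one_hot(stim_ids[i], n_states)
      sg <- config$stimulus_gain * s
      input <- if (config$use_retrieved_input) c(sg, retr_ctx) else sg
      stepres <- mgu_step(params, ctx, input)
      ctx <- stepres$context
      rec <- recall_with_grad(store, s, ctx, config$retrieval,
        with_stimulus = FALSE
      )
      y <- next_ids[i]
      if (rec$empty) {
        pred[i] <- sample.int(n_states, 1L) # uninformed guess
        retr_ctx <- numeric(d_c)
      } else {
        pred[i] <- argmax_rand(rec$outcome)
        g_o <- if (config$loss == "ce") {
          g <- numeric(n_states)
          g[y] <- -1 / (rec$outcome[y] + config$eps)
          g
        } else {
          2 * (rec$outcome - one_hot(y, n_states))
        }
        gctx <- clip_grad(rec$context_grad(g_o), config$clip_norm)
        params <- mgu_update(params, mgu_backward(params, stepres$cache, gctx))
        retr_ctx <- rec$context
        if (config$gamma > 0) {
          ctx <- (1 - config$gamma) * ctx + config$gamma * rec$context
        }
      }
      if (config$normalize) ctx <- unit_norm(ctx)
      contexts[i, ] <- ctx # end-of-step context: what is stored and logged
      memory_append(store, s, ctx, one_hot(y, n_states))
    }
    structure(
      list(
        log = dplyr::mutate(sequences,
          prediction = pred,
          correct = pred == next_ids
        ),
        contexts = contexts, params = params, store = store
      ),
      class = "study2_run"
    )
  })
}

#' Run the plain recurrent baseline on the prediction task
#'
#' A gated recurrent network with no episodic memory: the next state is
#' read out from the Minimal Gated Unit context through a learned linear
#' softmax layer. Unlike the memory-augmented engine, the baseline is
#' trained by backpropagation through time within each sequence (truncated
#' at sequence boundaries), one gradient update per sequence -- the
#' standard way such a recurrent predictor is trained -- and with the
#' conventional, slow learning rate given by `baseline_eta`. This is the
#' comparison network that exhibits catastrophic interference under
#' blocked training.
#'
#' @inheritParams run_next_state_experiment
#' @param baseline_eta Learning rate of the baseline (default 0.1;
#'   deliberately conventional rather than the memory model's high rate).
#' @return A list of class `study2_baseline_run` with `log` (as in
#'   [run_next_state_experiment()]) and the final parameters.
#' @export
run_rnn_baseline <- function(sequences, config = study2_config(),
                             seed = NULL, baseline_eta = 0.1) {
  stopifnot(inherits(config, "study2_config"))
  with_local_seed(seed, {
    n_states <- max(sequences$stimulus_id, sequences$next_id)
    d_c <- config$d_c
    params <- mgu_init(n_states, d_c,
      eta = baseline_eta,
      init_sd = config$init_sd
    )
    W <- matrix(
      stats::rnorm(n_states * d_c, 0, config$init_sd / sqrt(d_c)),
      n_states, d_c
    )
    b <- numeric(n_states)
    ctx <- fresh_context(d_c, 0.1)
    n <- nrow(sequences)
    pred <- integer(n)
    seq_ids <- sequences$sequence
    for (sq in unique(seq_ids)) {
      rows <- which(seq_ids == sq)
      k <- length(rows)
      caches <- vector("list", k)
      glog <- vector("list", k)
      ctxs <- matrix(0, k, d_c)
      for (j in seq_len(k)) {
        i <- rows[j]
        stim <- one_hot(sequences$stimulus_id[i], n_states)
        stepres <- mgu_step(params, ctx, stim)
        ctx <- stepres$context
        caches[[j]] <- stepres$cache
        ctxs[j, ] <- ctx
        p <- softmax(as.numeric(W %*% ctx) + b)
        pred[i] <- argmax_rand(p)
        gl <- p
        gl[sequences$next_id[i]] <- gl[sequences$next_id[i]] - 1
        glog[[j]] <- gl
      }
      # backprop through time within the sequence
      gW <- matrix(0, n_states, d_c)
      gb <- numeric(n_states)
      acc <- list(
        Wf = 0 * params$Wf, bf = 0 * params$bf,
        Wh = 0 * params$Wh, bh = 0 * params$bh
      )
      gnext <- numeric(d_c)
      for (j in rev(seq_len(k))) {
        gl <- glog[[j]]
        gW <- gW + gl %o% ctxs[j, ]
        gb <- gb + gl
        gctx <- as.numeric(crossprod(W, gl)) + gnext
        gr <- mgu_backward(params, caches[[j]], gctx)
        for (f in c("Wf", "bf", "Wh", "bh")) acc[[f]] <- acc[[f]] + gr[[f]]
        gnext <- gr$grad_prev
      }
      W <- W - baseline_eta * gW
      b <- b - baseline_eta * gb
      params <- mgu_update(params, acc)
    }
    structure(
      list(
        log = dplyr::mutate(sequences,
          prediction = pred,
          correct = pred == sequences$next_id
        ),
        params = params, W = W, b = b
      ),
      class = "study2_baseline_run"
    )
  })
}
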