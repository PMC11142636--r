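softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Configuration and state for the revaluation-task agent
#'
#' Builds a fresh agent for the multi-step revaluation task: an empty
#' episodic store over the six one-hot states plus a linear-integrator
#' context. The context is maintained over the state space itself
#' (`d_c = n_states`), so a context vector literally carries weighted traces
#' of predecessor states.
#'
#' @param n_states Number of task states (6).
#' @param rho Context decay per step, in \[0, 1\].
#' @param beta Input gain of the integrator.
#' @param gamma Blend weight for retrieved context, in \[0, 1\].
#' @param tau Retrieval softmax temperature.
#' @param stimulus_weight,context_weight Retrieval similarity mixing
#'   weights.
#' @param kappa Preference sharpness for [decide_preference()].
#' @param n_queries Rollout length in decision mode.
#' @param init_sd Standard deviation of the random context initialization
#'   at each sequence start and at decision onset (the per-instance "random
#'   initial conditions").
#' @param normalize Renormalize the context after each update.
#' @return A list of class `study1_model` with the store, context, and
#'   configuration.
#' @export
study1_model <- function(n_states = 6, rho = 0.5, beta = 1, gamma = 0.74,
                         tau = 0.13, stimulus_weight = 1, context_weight = 1,
                         kappa = 0.5, n_queries = 3, init_sd = 0.1,
                         normalize = TRUE) {
  stopifnot(n_queries >= 0)
  structure(
    list(
      store = memory_store(n_states, n_states, 1L),
      context = numeric(n_states),
      cfg = list(
        n_states = as.integer(n_states), rho = rho, beta = beta,
        gamma = gamma, kappa = kappa, n_queries = as.integer(n_queries),
        init_sd = init_sd, normalize = normalize,
        retrieval = retrieval_config(
          tau = tau,
          stimulus_weight = stimulus_weight,
          context_weight = context_weight
        )
      )
    ),
    class = "study1_model"
  )
}

fresh_context <- function(d, init_sd) {
  if (init_sd > 0) stats::rnorm(d, 0, init_sd) else numeric(d)
}

#' Run the agent in observation mode
#'
#' Passive exposure to a trial stream. At every step the agent (1) queries
#' episodic memory with the current stimulus and context, (2) blends the
#' retrieved context into its context, (3) stores the stimulus, the blended
#' context, and the observed reward as a new memory row, and (4) integrates
#' the current stimulus into its context. Because the stimulus is integrated
#' only *after* the write, each stored context carries traces of the
#' stimulus's predecessors but never of the stimulus itself. The context is
#' re-initialized (with fresh noise) at the start of every sequence.
#'
#' @param trials A trial tibble from [make_study1_trials()] (or any subset
#'   of its rows, e.g. one phase).
#' @param model A [study1_model()].
#' @return A list with `model` (updated state) and `log`, a tibble of the
#'   stored context per step (`phase`, `sequence`, `step`, `stimulus_id`,
#'   and `context` as a list-column).
#' @export
run_observation <- function(trials, model) {
  stopifnot(inherits(model, "study1_model"))
  cfg <- model$cfg
  store <- model$store
  ctx <- model$context
  n <- nrow(trials)
  contexts <- vector("list", n)
  for (i in seq_len(n)) {
    if (trials$step[i] == 1L) ctx <- fresh_context(cfg$n_states, cfg$init_sd)
    s <- one_hot(trials$stimulus_id[i], cfg$n_states)
    rec <- memory_recall(store, s, ctx, cfg$retrieval)
    if (!rec$empty) {
      ctx <- context_blend(ctx, rec$context, cfg$gamma, cfg$normalize)
    }
    memory_append(store, s, ctx, trials$reward[i])
    contexts[[i]] <- ctx
    ctx <- context_integrate(ctx, s, cfg$rho, cfg$beta, cfg$normalize)
  }
  model$context <- ctx
  log <- dplyr::mutate(
    trials[, intersect(
      c("phase", "pass", "sequence", "step", "stimulus_id"),
      names(trials)
    )],
    context = contexts
  )
  list(model = model, log = log)
}

#' Estimate a start state's long-run value by episodic rollout
#'
#' Decision mode: the agent simulates a trajectory from `start_state` by
#' repeatedly querying episodic memory and accumulating retrieved rewards.
#' The first query is keyed by the start state's one-hot and a freshly
#' initialized context; each retrieved memory then updates the context (the
#' retrieved context is blended in and the retrieved stimulus is
#' integrated), and subsequent queries are keyed by context alone (the
#' stimulus slot is zeroed). Because stored contexts respect the observed
#' transitions, the rollout tends to walk the remembered trajectory.
#'
#' @param model A [study1_model()] whose store is non-empty.
#' @param start_state State id to evaluate.
#' @param n_queries Number of memory queries (default from the model
#'   config); 0 gives `V = 0`.
#' @return A list of class `value_estimate`: `V` (summed retrieved reward)
#'   and `trace`, a tibble with the per-query retrieved state (argmax of
#'   the retrieved stimulus) and retrieved reward.
#' @export
estimate_value <- function(model, start_state, n_queries = NULL) {
  stopifnot(inherits(model, "study1_model"))
  cfg <- model$cfg
  if (is.null(n_queries)) n_queries <- cfg$n_queries
  if (n_queries < 0) stop("n_queries must be >= 0", call. = FALSE)
  if (memory_n(model$store) == 0L) {
    stop("no memories: run observation mode before estimating values",
      call. = FALSE
    )
  }
  ctx <- fresh_context(cfg$n_states, cfg$init_sd)
  key_s <- one_hot(start_state, cfg$n_states)
  V <- 0
  states <- integer(0)
  rewards <- numeric(0)
  if (n_queries > 0) {
    for (q in seq_len(n_queries)) {
      rec <- memory_recall(model$store, key_s, ctx, cfg$retrieval)
      V <- V + rec$outcome[1L]
      states <- c(states, which.max(rec$stimulus))
      rewards <- c(rewards, rec$outcome[1L])
      ctx <- context_blend(ctx, rec$context, cfg$gamma, cfg$normalize)
      ctx <- context_integrate(ctx, rec$stimulus, cfg$rho, cfg$beta, cfg$normalize)
      key_s <- numeric(cfg$n_states) # later queries are context-driven
    }
  }
  structure(
    list(
      V = V,
      trace = tibble::tibble(
        query = seq_len(n_queries),
        retrieved_state = states, retrieved_reward = rewards
      )
    ),
    class = "value_estimate"
  )
}

#' Preference between two start states
#'
#' Soft preference for the first state: `p = logistic(kappa * (V1 - V2))`.
#' Equal values give 0.5; large differences saturate at 0 or 1.
#'
#' @param V1,V2 Finite value estimates (scalars or `value_estimate`
#'   objects).
#' @param kappa Sharpness, > 0.
#' @return Preference for state 1, in \[0, 1\].
#' @export
decide_preference <- function(V1, V2, kappa = 1) {
  if (inherits(V1, "value_estimate")) V1 <- V1$V
  if (inherits(V2, "value_estimate")) V2 <- V2$V
  stopifnot(is.finite(V1), is.finite(V2), kappa > 0)
  logistic(kappa * (V1 - V2))
}

#' Run one simulated participant through the revaluation task
#'
#' Generates the trial stream, observes the learning phase, probes the two
#' start states (preference for the pre-revaluation-optimal one), observes
#' the revaluation phase, probes again, and returns the revaluation score
#' `clip(p_pre - p_post, 0, 1)`.
#'
#' @param spec A [study1_spec()].
#' @param model A fresh [study1_model()] (its store must be empty).
#' @param seed Integer seed controlling both the trial stream and the
#'   agent's random initial conditions.
#' @return A one-row tibble: `condition`, `p_pre`, `p_post`, `score`, and
#'   the four underlying value estimates.
#' @export
run_study1_instance <- function(spec, model = study1_model(), seed = NULL) {
  stopifnot(inherits(spec, "study1_spec"))
  with_local_seed(seed, {
    trials <- make_study1_trials(spec)
    learn <- dplyr::filter(trials, .data$phase == "learning")
    reval <- dplyr::filter(trials, .data$phase == "revaluation")
    model <- run_observation(learn, model)$model
    # pre-revaluation optimal start: the one whose trajectory pays more
    opt <- if (spec$r_a >= spec$r_b) 1L else 2L
    other <- 3L - opt
    v_pre <- c(
      estimate_value(model, 1L)$V,
      estimate_value(model, 2L)$V
    )
    p_pre <- decide_preference(v_pre[opt], v_pre[other], model$cfg$kappa)
    model <- run_observation(reval, model)$model
    v_post <- c(
      estimate_value(model, 1L)$V,
      estimate_value(model, 2L)$V
    )
    p_post <- decide_preference(v_post[opt], v_post[other], model$cfg$kappa)
    tibble::tibble(
      condition = spec$condition,
      p_pre = p_pre, p_post = p_post,
      score = revaluation_score(p_pre, p_post),
      v1_pre = v_pre[1], v2_pre = v_pre[2],
      v1_post = v_post[1], v2_post = v_post[2]
    )
  })
}
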