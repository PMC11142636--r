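# Evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards; with seed = NULL the current stream is used.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

#' Specification of the multi-step revaluation task
#'
#' Two disjoint three-state trajectories over six states, `1 -> 3 -> 5` and
#' `2 -> 4 -> 6`, each ending in a terminal reward. After a learning phase,
#' a revaluation phase changes either the rewards (the two terminal rewards
#' are swapped while the trajectories stay intact) or the transitions (the
#' third stimulus is swapped between trajectories, each third stimulus
#' keeping its original reward). Revaluation sequences start at the second
#' state of each trajectory (states 3 and 4), so the starting states 1 and 2
#' are never re-experienced -- the signature of the revaluation design.
#'
#' @param condition `"reward_revaluation"` or `"transition_revaluation"`.
#' @param r_a,r_b Terminal rewards of trajectory A (ending in state 5) and
#'   trajectory B (ending in state 6) during learning. Defaults 1 and 10.
#' @param n_passes Number of passes over each trajectory per phase.
#' @return A list of class `study1_spec`.
#' @export
study1_spec <- function(condition = c(
                          "reward_revaluation",
                          "transition_revaluation"
                        ),
                        r_a = 1, r_b = 10, n_passes = 20) {
  condition <- match.arg(condition)
  stopifnot(n_passes >= 1, r_a != r_b)
  structure(
    list(
      condition = condition, r_a = r_a, r_b = r_b,
      n_passes = as.integer(n_passes),
      traj_a = c(1L, 3L, 5L), traj_b = c(2L, 4L, 6L), n_states = 6L
    ),
    class = "study1_spec"
  )
}

#' Generate the multi-step revaluation trial stream
#'
#' Produces one row per state visit. The learning phase presents full
#' three-state trajectories with the terminal reward on the last state; the
#' revaluation phase presents two-state sequences starting at states 3/4
#' with the condition's edit applied. The A/B order within each pass is
#' shuffled by the seed (the "random initial conditions" across simulated
#' participants).
#'
#' @param spec A [study1_spec()].
#' @param seed Integer seed; the stream is a pure function of (spec, seed).
#' @return A tibble with columns `phase` (`"learning"`/`"revaluation"`),
#'   `pass`, `sequence`, `step`, `trajectory`, `stimulus_id`, `reward`.
#'   The decision-probe states are attached as `attr(, "probes")` (always
#'   `c(1, 2)`).
#' @export
make_study1_trials <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "study1_spec"))
  with_local_seed(seed, {
    # learning-phase sequences
    seqs <- list(
      A = list(states = spec$traj_a, rewards = c(0, 0, spec$r_a)),
      B = list(states = spec$traj_b, rewards = c(0, 0, spec$r_b))
    )
    # revaluation-phase sequences start at the second stimulus
    reval <- switch(spec$condition,
      reward_revaluation = list(
        A = list(states = c(3L, 5L), rewards = c(0, spec$r_b)),
        B = list(states = c(4L, 6L), rewards = c(0, spec$r_a))
      ),
      transition_revaluation = list(
        A = list(states = c(3L, 6L), rewards = c(0, spec$r_b)),
        B = list(states = c(4L, 5L), rewards = c(0, spec$r_a))
      )
    )
    emit <- function(phase, passes, defs) {
      purrr::map_dfr(seq_len(passes), function(p) {
        order <- sample(c("A", "B"))
        purrr::map_dfr(seq_along(order), function(k) {
          d <- defs[[order[k]]]
          tibble::tibble(
            phase = phase, pass = p, sequence = (p - 1L) * 2L + k,
            step = seq_along(d$states), trajectory = order[k],
            stimulus_id = d$states, reward = d$rewards
          )
        })
      })
    }
    out <- dplyr::bind_rows(
      emit("learning", spec$n_passes, seqs),
      emit("revaluation", spec$n_passes, reval)
    )
    attr(out, "probes") <- c(1L, 2L)
    out
  })
}

#' Specification of the two-graph next-state prediction task
#'
#' Ten states arranged into two five-state trajectories per graph. The two
#' graphs are orthogonal: every non-terminal state has a different successor
#' under graph 1 than under graph 2, and the graphs share no (state,
#' successor) edge. A sequence is a full pass through one trajectory of the
#' active graph.
#'
#' @param schedule `"blocked"` (contiguous runs of `block_length` sequences
#'   per graph, alternating) or `"interleaved"` (strict alternation,
#'   sequence by sequence).
#' @param block_length Sequences per block in the blocked schedule.
#' @param n_train,n_test Training and test sequence counts. The test segment
#'   is randomly interleaved for both schedules.
#' @return A list of class `study2_spec` carrying the two successor maps.
#' @export
study2_spec <- function(schedule = c("blocked", "interleaved"),
                        block_length = 40, n_train = 800, n_test = 200) {
  schedule <- match.arg(schedule)
  stopifnot(block_length >= 1, n_train >= 1, n_test >= 1)
  g1 <- list(c(1L, 3L, 5L, 7L, 9L), c(2L, 4L, 6L, 8L, 10L))
  g2 <- list(c(1L, 4L, 5L, 8L, 9L), c(2L, 3L, 6L, 7L, 10L))
  structure(
    list(
      schedule = schedule, block_length = as.integer(block_length),
      n_train = as.integer(n_train), n_test = as.integer(n_test),
      n_states = 10L, graphs = list(g1 = g1, g2 = g2)
    ),
    class = "study2_spec"
  )
}

#' Successor map of one graph of a `study2_spec`
#'
#' @param spec A [study2_spec()].
#' @param graph 1 or 2.
#' @return A named integer vector: `successors(spec, g)[as.character(s)]` is
#'   the successor of state `s` (terminal states are absent).
#' @export
study2_successors <- function(spec, graph) {
  trajs <- spec$graphs[[graph]]
  out <- integer(0)
  for (tr in trajs) {
    for (i in seq_len(length(tr) - 1L)) {
      out[as.character(tr[i])] <- tr[i + 1L]
    }
  }
  out
}

#' Generate the next-state prediction sequence stream
#'
#' One row per within-sequence transition (4 per five-state sequence). The
#' trajectory within the active graph is sampled uniformly per sequence.
#' Training follows the requested schedule; the test segment draws the graph
#' uniformly at random per sequence for both schedules.
#'
#' @param spec A [study2_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `sequence`, `phase` (`"train"`/`"test"`),
#'   `graph` (1/2), `step`, `stimulus_id`, `next_id`.
#' @export
make_study2_sequences <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "study2_spec"))
  with_local_seed(seed, {
    n_tr <- spec$n_train
    graph_seq <- if (spec$schedule == "blocked") {
      blk <- ceiling(seq_len(n_tr) / spec$block_length)
      ifelse(blk %% 2L == 1L, 1L, 2L)
    } else {
      rep_len(c(1L, 2L), n_tr)
    }
    graph_seq <- c(graph_seq, sample(c(1L, 2L), spec$n_test, replace = TRUE))
    phase <- rep(c("train", "test"), c(n_tr, spec$n_test))
    purrr::map_dfr(seq_along(graph_seq), function(s) {
      g <- graph_seq[s]
      tr <- spec$graphs[[g]][[sample.int(2L, 1L)]]
      k <- length(tr) - 1L
      tibble::tibble(
        sequence = s, phase = phase[s], graph = g,
        step = seq_len(k), stimulus_id = tr[seq_len(k)],
        next_id = tr[seq_len(k) + 1L]
      )
    })
  })
}

#' Specification of the context-cued category learning task
#'
#' Stimuli vary along two abstract feature dimensions on an
#' `n_levels x n_levels` grid; a context cue signals which dimension is
#' reward-relevant. The reward is the sign of the relevant feature level
#' relative to the grid midpoint (the midpoint level itself counts as
#' negative). Both contexts share the identical stimulus set.
#'
#' @param schedule `"blocked"` (context switches every `block_length`
#'   trials) or `"interleaved"` (context drawn uniformly at random each
#'   trial).
#' @param n_levels Feature levels per dimension (default 5).
#' @param block_length Trials per context block in the blocked schedule.
#' @param n_train,n_test Training and test trial counts; the test segment is
#'   interleaved for both schedules.
#' @return A list of class `study3_spec`.
#' @export
study3_spec <- function(schedule = c("blocked", "interleaved"),
                        n_levels = 5, block_length = 200,
                        n_train = 800, n_test = 100) {
  schedule <- match.arg(schedule)
  stopifnot(n_levels >= 2, block_length >= 1, n_train >= 1, n_test >= 1)
  structure(
    list(
      schedule = schedule, n_levels = as.integer(n_levels),
      block_length = as.integer(block_length),
      n_train = as.integer(n_train), n_test = as.integer(n_test),
      boundary = (n_levels + 1) / 2
    ),
    class = "study3_spec"
  )
}

study3_reward_sign <- function(level, boundary) {
  sgn <- sign(level - boundary)
  # stimuli on the boundary have zero reward: the sign the agent is scored
  # against is irreducibly ambiguous, realized as a random coin flip
  amb <- sgn == 0
  if (any(amb)) sgn[amb] <- sample(c(-1, 1), sum(amb), replace = TRUE)
  as.integer(sgn)
}

#' Generate the category-learning trial stream
#'
#' One row per trial. Stimuli are sampled uniformly from the feature grid;
#' the context label follows the schedule during training and is uniform
#' random during the test segment.
#'
#' @param spec A [study3_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `trial`, `phase` (`"train"`/`"test"`),
#'   `context` (1/2: the reward-relevant dimension), `f1`, `f2` (feature
#'   levels), `stimulus_id`, `reward` (+1/-1).
#' @export
make_study3_trials <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "study3_spec"))
  with_local_seed(seed, {
    n_tr <- spec$n_train
    ctx_train <- if (spec$schedule == "blocked") {
      blk <- ceiling(seq_len(n_tr) / spec$block_length)
      ifelse(blk %% 2L == 1L, 1L, 2L)
    } else {
      sample(c(1L, 2L), n_tr, replace = TRUE)
    }
    ctx <- c(ctx_train, sample(c(1L, 2L), spec$n_test, replace = TRUE))
    n <- n_tr + spec$n_test
    f1 <- sample.int(spec$n_levels, n, replace = TRUE)
    f2 <- sample.int(spec$n_levels, n, replace = TRUE)
    rel <- ifelse(ctx == 1L, f1, f2)
    tibble::tibble(
      trial = seq_len(n),
      phase = rep(c("train", "test"), c(n_tr, spec$n_test)),
      context = ctx, f1 = f1, f2 = f2,
      stimulus_id = (f1 - 1L) * spec$n_levels + f2,
      reward = study3_reward_sign(rel, spec$boundary)
    )
  })
}

#' Encode a two-feature stimulus as concatenated one-hots
#'
#' @param f1,f2 Feature levels (1-based).
#' @param n_levels Levels per dimension.
#' @return Numeric vector of length `2 * n_levels`.
#' @export
study3_encode_stimulus <- function(f1, f2, n_levels) {
  c(one_hot(f1, n_levels), one_hot(f2, n_levels))
}

#' Write / read a trial stream as a delimited table
#'
#' Trial streams are plain tibbles; these helpers write them as
#' tab-separated files with the generating seed recorded in a `# seed:`
#' header line, and read them back.
#'
#' @param trials A trial tibble from one of the `make_study*` generators.
#' @param path File path.
#' @param seed The seed used to generate the stream (recorded in the
#'   header).
#' @return `trials_export()` the path invisibly; `trials_import()` a tibble
#'   with the seed in `attr(, "seed")`.
#' @export
trials_export <- function(trials, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", seed), con)
  utils::write.table(trials, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trials_export
#' @export
trials_import <- function(path) {
  first <- readLines(path, n = 1L)
  seed <- if (grepl("^# seed:", first)) {
    suppressWarnings(as.integer(sub("^# seed:\\s*", "", first)))
  } else {
    NA_integer_
  }
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#"))
  attr(df, "seed") <- seed
  df
}
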