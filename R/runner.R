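#' Assemble a reproducible study-level run configuration
#'
#' Bundles everything a multi-instance simulated experiment needs: which
#' study, which condition or schedule, how many independent model instances
#' (simulated participants), the master seed, and any engine hyperparameter
#' overrides. Validation happens before any compute.
#'
#' @param study 1 (multi-step revaluation), 2 (next-state prediction), or
#'   3 (context-cued category learning).
#' @param condition For study 1: `"reward_revaluation"` or
#'   `"transition_revaluation"`. For studies 2-3: `"blocked"` or
#'   `"interleaved"`.
#' @param n_instances Number of simulated participants (default 58).
#' @param seed Master seed; per-instance seeds are derived from it (see
#'   [instance_seed()]).
#' @param model `"ego"` (the full memory-augmented agent) or, for study 2
#'   only, `"baseline"` (the recurrent network without episodic memory).
#' @param params Named list of overrides passed to the study's config
#'   constructor ([study1_model()], [study2_config()], [study3_config()]).
#' @param task Named list of overrides passed to the study's task spec
#'   constructor ([study1_spec()], [study2_spec()], [study3_spec()]).
#' @return A validated list of class `ego_run_config`.
#' @export
ego_config <- function(study, condition = NULL, n_instances = 58, seed = 1,
                       model = c("ego", "baseline"), params = list(),
                       task = list()) {
  model <- match.arg(model)
  study <- as.integer(study)
  if (!study %in% 1:3) stop("study must be 1, 2, or 3", call. = FALSE)
  if (n_instances < 1) stop("n_instances must be >= 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  valid_cond <- if (study == 1) {
    c("reward_revaluation", "transition_revaluation")
  } else {
    c("blocked", "interleaved")
  }
  if (is.null(condition)) condition <- valid_cond[1]
  condition <- match.arg(condition, valid_cond)
  if (model == "baseline" && study != 2) {
    stop("the recurrent baseline is only defined for study 2", call. = FALSE)
  }
  # validate overrides eagerly by constructing spec and engine config once
  spec <- build_task_spec(study, condition, task)
  engine_cfg <- build_engine_config(study, params)
  structure(
    list(
      study = study, condition = condition,
      n_instances = as.integer(n_instances), seed = as.integer(seed),
      model = model, params = params, task = task,
      spec = spec, engine = engine_cfg
    ),
    class = "ego_run_config"
  )
}

build_task_spec <- function(study, condition, task) {
  args <- c(list(condition), task)
  names(args)[1] <- if (study == 1) "condition" else "schedule"
  switch(study,
    do.call(study1_spec, args),
    do.call(study2_spec, args),
    do.call(study3_spec, args)
  )
}

build_engine_config <- function(study, params) {
  switch(study,
    do.call(study1_model, params)$cfg, # validated; rebuilt fresh per instance
    do.call(study2_config, params),
    do.call(study3_config, params)
  )
}

#' Derive the seed of one model instance from the master seed
#'
#' A fixed affine splitting rule: `(seed + 7919 * i) mod (2^31 - 1)`.
#' Instance `i`'s stream depends only on the master seed and `i`, never on
#' how many instances are run.
#'
#' @param seed Master seed.
#' @param i Instance index (1-based).
#' @return An integer seed.
#' @export
instance_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647)
}

run_instance_study1 <- function(config, s) {
  model <- do.call(study1_model, config$params)
  run_study1_instance(config$spec, model, seed = s)[
    ,
    c("condition", "p_pre", "p_post", "score")
  ]
}

run_instance_study2 <- function(config, s) {
  seqs <- make_study2_sequences(config$spec, s)
  if (config$model == "baseline") {
    run <- run_rnn_baseline(seqs, config$engine, s + 1)
    lg <- run$log
    test <- lg$phase == "test"
    pos <- (lg$sequence - 1) %% config$spec$block_length
    early <- pos < 5
    late <- pos >= config$spec$block_length - 5
    onset <- lg$sequence <= config$spec$n_train + 20
    return(tibble::tibble(
      test_accuracy = mean(lg$correct[test]),
      block_start_accuracy = mean(lg$correct[!test & early]),
      block_end_accuracy = mean(lg$correct[!test & late]),
      test_onset_accuracy = mean(lg$correct[test & onset]),
      final_train_accuracy = mean(lg$correct[!test &
        lg$sequence > 0.75 * config$spec$n_train])
    ))
  }
  run <- run_next_state_experiment(seqs, config$engine, s + 1)
  lg <- run$log
  test <- lg$phase == "test"
  # context-similarity structure over training steps (thinned for size)
  idx <- which(!test)
  idx <- idx[seq(1, length(idx), by = 16)]
  cs <- context_similarity_matrix(run$contexts[idx, , drop = FALSE])
  same <- outer(lg$graph[idx], lg$graph[idx], "==")
  ut <- upper.tri(cs)
  tibble::tibble(
    test_accuracy = mean(lg$correct[test]),
    train_accuracy = mean(lg$correct[!test]),
    decode_accuracy = decode_graph(run),
    within_graph_similarity = mean(cs[same & ut]),
    across_graph_similarity = mean(cs[!same & ut])
  )
}

run_instance_study3 <- function(config, s) {
  trials <- make_study3_trials(config$spec, s)
  run <- run_category_experiment(trials, config$engine, s + 1)
  lg <- run$log
  test <- lg$phase == "test"
  n_levels <- config$spec$n_levels
  fv <- representation_feature_variance(run$reps, run$conditions)
  tibble::tibble(
    test_accuracy = mean(lg$correct[test]),
    train_accuracy = mean(lg$correct[!test]),
    rsa_task_specific = rsa_template_correlation(
      run$reps, rsa_template(n_levels, "task_specific")
    ),
    rsa_task_general = rsa_template_correlation(
      run$reps, rsa_template(n_levels, "task_general")
    ),
    relevant_variance = mean(fv$variance[fv$relevant]),
    irrelevant_variance = mean(fv$variance[!fv$relevant])
  )
}

#' Run a full multi-instance simulated study
#'
#' Runs `n_instances` independently seeded model instances through the
#' configured study and condition, computes the study's per-instance
#' metrics, and returns them with a summary. Fully reproducible: the same
#' config and master seed give identical tables.
#'
#' Per-instance metrics by study: study 1 -- `p_pre`, `p_post`, `score`
#' (revaluation score); study 2 -- test/train accuracy, graph-decoding
#' accuracy, within- and across-graph context similarity (baseline model:
#' block-start/end, test-onset and final-train accuracies); study 3 --
#' test/train accuracy, RSA correlations with both templates, hidden-layer
#' variance along relevant and irrelevant feature dimensions.
#'
#' @param config An [ego_config()].
#' @return An object of class `ego_study_result`: a list with `study`,
#'   `condition`, `model`, `instances` (per-instance metric tibble),
#'   `summary` (one row per metric: mean, sd, sem, n), `config`, and
#'   `seeds`.
#' @export
#' @examples
#' \donttest{
#' res <- run_study(ego_config(1, "reward_revaluation", n_instances = 3))
#' glance(res)
#' }
run_study <- function(config) {
  stopifnot(inherits(config, "ego_run_config"))
  seeds <- vapply(seq_len(config$n_instances), function(i) {
    instance_seed(config$seed, i)
  }, integer(1))
  runner <- switch(config$study,
    run_instance_study1, run_instance_study2, run_instance_study3
  )
  instances <- purrr::map_dfr(seq_along(seeds), function(i) {
    dplyr::mutate(runner(config, seeds[i]),
      instance = i, seed = seeds[i], .before = 1
    )
  })
  metric_cols <- setdiff(
    names(instances)[vapply(instances, is.numeric, logical(1))],
    c("instance", "seed")
  )
  summary <- purrr::map_dfr(metric_cols, function(m) {
    v <- instances[[m]]
    tibble::tibble(
      metric = m, mean = mean(v), sd = stats::sd(v),
      sem = stats::sd(v) / sqrt(length(v)), n = length(v)
    )
  })
  structure(
    list(
      study = config$study, condition = config$condition,
      model = config$model, instances = instances, summary = summary,
      config = config, seeds = seeds
    ),
    class = "ego_study_result"
  )
}

#' @export
print.ego_study_result <- function(x, ...) {
  cat(sprintf(
    "<ego_study_result: study %d, %s, %s, %d instances>\n",
    x$study, x$condition, x$model, nrow(x$instances)
  ))
  print(x$summary)
  invisible(x)
}

#' Per-instance metrics of a study result
#'
#' @param x An `ego_study_result`.
#' @param ... Unused.
#' @return The per-instance metric tibble, one row per simulated
#'   participant.
#' @method tidy ego_study_result
#' @export
tidy.ego_study_result <- function(x, ...) {
  dplyr::mutate(x$instances,
    study = x$study, condition = x$condition,
    .before = 1
  )
}

#' One-row summary of a study result
#'
#' @param x An `ego_study_result`.
#' @param ... Unused.
#' @return A one-row tibble: study, condition, model, n, then one
#'   `<metric>_mean` / `<metric>_sem` pair per metric.
#' @method glance ego_study_result
#' @export
glance.ego_study_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary[, c("metric", "mean", "sem")],
    names_from = "metric", values_from = c("mean", "sem"),
    names_glue = "{metric}_{.value}"
  )
  dplyr::bind_cols(
    tibble::tibble(
      study = x$study, condition = x$condition,
      model = x$model, n = nrow(x$instances)
    ),
    wide
  )
}

#' Write a study result to a directory of delimited tables
#'
#' Writes `metrics.csv` (per-instance), `summary.csv`, `config.json`
#' (snapshot of the run configuration), and `seeds.txt`.
#'
#' @param result An `ego_study_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  stopifnot(inherits(result, "ego_study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$instances, file.path(dir, "metrics.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
    row.names = FALSE
  )
  cfg <- result$config[c(
    "study", "condition", "n_instances", "seed",
    "model", "params", "task"
  )]
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  writeLines(as.character(result$seeds), file.path(dir, "seeds.txt"))
  invisible(dir)
}
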