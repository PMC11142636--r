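# egoframe

Simulations of an episodic-memory-augmented agent for studying how the
temporal structure of experience shapes learning and generalization. The
agent couples three components:

* an **append-only episodic memory** — three row-aligned matrices of
  stimulus keys, context keys, and outcomes — queried by mixed cosine
  similarity with a softmax readout, so retrieval is a differentiable,
  similarity-weighted average of past experiences:
  `w = softmax((w_s cos(s*, S) + w_c cos(c*, C)) / τ)`,
  `retrieved = wᵀ [S C O]`;
* a **recurrent context module** — a linear temporal-context integrator
  `c ← ρ c + β x` for passive observation, or a Minimal Gated Unit trained
  online with truncated error backpropagation for the learning tasks — whose
  state both keys episodic retrieval and is shaped by gradients flowing back
  *through* retrieval;
* a **semantic pathway** — a context-dependent tanh layer
  `h = tanh(W_s s + W_c c + b)` — that slowly learns stimulus-to-response
  mappings under contextual gating.

The package ships generators for three synthetic task streams and the
engines and metrics to run the corresponding simulated experiments:

1. **Multi-step revaluation** (reward vs transition revaluation of two
   three-state trajectories), scored by the revaluation score
   `clip(p_pre − p_post, 0, 1)`;
2. **Next-state prediction** over two orthogonal graphs, blocked vs
   interleaved, with logistic-regression decoding of the active graph from
   context-layer activity;
3. **Context-cued category learning** on a 5 × 5 feature grid, with RSA of
   the context-dependent hidden layer against task-specific and
   task-general templates.

## Worked example

Run five simulated participants through the reward-revaluation condition:

```r
library(egoframe)
res <- run_study(ego_config(1, "reward_revaluation", n_instances = 5, seed = 42))
res
#> <ego_study_result: study 1, reward_revaluation, ego, 5 instances>
#> # A tibble: 3 × 5
#>   metric  mean     sd    sem     n
#>   <chr>  <dbl>  <dbl>  <dbl> <int>
#> 1 p_pre  0.950 0.0344 0.0154     5
#> 2 p_post 0.433 0.139  0.0620     5
#> 3 score  0.517 0.123  0.0549     5
```

Before revaluation the agents strongly prefer the higher-paying start state
(`p_pre ≈ 0.95`); after the terminal rewards are swapped the preference
drops toward indifference (`p_post ≈ 0.43`), because episodic retrieval now
mixes pre- and post-revaluation memories. The resulting mean revaluation
score ≈ 0.52 — preferences update substantially but incompletely, the
signature the task is designed to detect. `tidy(res)` returns the
per-instance table, `glance(res)` a one-row summary, and `autoplot(res)`
plots per-instance metrics.

Single instances are available at a lower level, e.g.
`run_next_state_experiment()` for the prediction task, with
`decode_graph()`, `context_similarity_matrix()`, `mds_embed()`,
`rsa_template_correlation()`, and `group_compare()` as the analysis layer.

A small command-line wrapper ships in `inst/scripts/ego`
(`run` / `validate-config` / `make-fixtures`), with default JSON configs
under `inst/configs/`.

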