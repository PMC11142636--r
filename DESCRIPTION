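Package: egoframe
Title: Episodic Memory, Learned Context, and Semantic Pathways for
    Simulating Generalization in Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates an agent that couples an append-only episodic memory
    with differentiable similarity-based retrieval, a recurrent context
    module (a linear temporal-context integrator or a learned Minimal Gated
    Unit), and a context-biased semantic pathway. Provides generators for
    three synthetic task streams (multi-step reward/transition revaluation,
    blocked versus interleaved next-state prediction on orthogonal graphs,
    and context-cued two-feature category learning), the simulation engines
    that run the agent on them, and the analysis layer (revaluation scores,
    context-similarity matrices, logistic-regression decoding of latent task
    labels, multidimensional scaling, and representational similarity
    analysis against idealized templates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
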