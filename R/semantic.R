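#' Initialize the semantic pathway
#'
#' The semantic pathway is a context-dependent hidden layer: a single
#' tanh layer that receives both the stimulus and the context and projects
#' to the output. It learns the stimulus-to-response mapping slowly and
#' statistically, in contrast to the one-shot episodic store, and its hidden
#' layer is where task-specific versus task-general representational
#' structure forms.
#'
#' @param d_s Stimulus input dimension.
#' @param d_c Context input dimension.
#' @param d_h Hidden-layer dimension.
#' @param d_o Output dimension (2 for accept/reject scores).
#' @param eta Learning rate for gradient updates, > 0.
#' @param init_sd Scale of the Gaussian weight initialization (divided by
#'   the square root of each layer's fan-in).
#' @param context_sd Initialization scale of the context-to-hidden weights
#'   (defaults to `init_sd`). Larger values let a well-separated context
#'   shift hidden units into or out of their saturating range -- the
#'   gating regime in which task-specific representations form.
#' @return A list of class `semantic_params`.
#' @export
semantic_init <- function(d_s, d_c, d_h, d_o = 2, eta = 0.1, init_sd = 1,
                          context_sd = init_sd) {
  stopifnot(d_s >= 1, d_c >= 1, d_h >= 1, d_o >= 1, eta > 0)
  structure(
    list(
      Ws = matrix(stats::rnorm(d_h * d_s, 0, init_sd / sqrt(d_s)), d_h, d_s),
      Wc = matrix(stats::rnorm(d_h * d_c, 0, context_sd / sqrt(d_c)), d_h, d_c),
      bh = numeric(d_h),
      Wo = matrix(stats::rnorm(d_o * d_h, 0, init_sd / sqrt(d_h)), d_o, d_h),
      bo = numeric(d_o),
      d_s = as.integer(d_s), d_c = as.integer(d_c),
      d_h = as.integer(d_h), d_o = as.integer(d_o), eta = eta
    ),
    class = "semantic_params"
  )
}

#' Semantic forward pass
#'
#' `hidden = tanh(Ws stimulus + Wc context + bh)`;
#' `output = Wo hidden + bo`. The hidden activation is returned so it can be
#' logged for representation analyses (MDS, RSA).
#'
#' @param params A `semantic_params` list.
#' @param stimulus Numeric vector of length `d_s`.
#' @param context Numeric vector of length `d_c`.
#' @return A list with `output`, `hidden`, and a `cache` for
#'   [semantic_backward()].
#' @export
semantic_forward <- function(params, stimulus, context) {
  if (length(stimulus) != params$d_s) {
    stop(sprintf(
      "stimulus has length %d but the pathway expects %d",
      length(stimulus), params$d_s
    ), call. = FALSE)
  }
  if (length(context) != params$d_c) {
    stop(sprintf(
      "context has length %d but the pathway expects %d",
      length(context), params$d_c
    ), call. = FALSE)
  }
  a <- as.numeric(params$Ws %*% stimulus) +
    as.numeric(params$Wc %*% context) + params$bh
  h <- tanh(a)
  out <- as.numeric(params$Wo %*% h) + params$bo
  list(
    output = out, hidden = h,
    cache = list(stimulus = stimulus, context = context, hidden = h)
  )
}

#' Combine the episodic and semantic output predictions
#'
#' The two pathways each produce an output-layer vector; the combined
#' prediction is their elementwise mean by default (`"sum"`,
#' `"semantic_only"`, and `"episodic_only"` are also available).
#'
#' @param episodic_output,semantic_output Numeric vectors of equal length.
#' @param mode Combination rule.
#' @return The combined output vector.
#' @export
combine_predictions <- function(episodic_output, semantic_output,
                                mode = c(
                                  "mean", "sum", "semantic_only",
                                  "episodic_only"
                                )) {
  mode <- match.arg(mode)
  if (length(episodic_output) != length(semantic_output)) {
    stop("episodic and semantic outputs have different lengths", call. = FALSE)
  }
  switch(mode,
    mean = (episodic_output + semantic_output) / 2,
    sum = episodic_output + semantic_output,
    semantic_only = semantic_output,
    episodic_only = episodic_output
  )
}

#' Semantic backward pass
#'
#' Gradients of a scalar loss with respect to all semantic weights, given
#' `grad_output = dL/d semantic_output`. Also returns `grad_context`, the
#' gradient with respect to the context input, so the error can continue
#' into the recurrent context module (where it is truncated at the previous
#' time step).
#'
#' @param params A `semantic_params` list.
#' @param cache The cache from [semantic_forward()].
#' @param grad_output Numeric vector of length `d_o`.
#' @return A list of gradients `Ws`, `Wc`, `bh`, `Wo`, `bo`, plus
#'   `grad_context`.
#' @export
semantic_backward <- function(params, cache, grad_output) {
  g <- as.numeric(grad_output)
  h <- cache$hidden
  delta <- as.numeric(crossprod(params$Wo, g)) * (1 - h^2)
  list(
    Wo = g %o% h,
    bo = g,
    Ws = delta %o% cache$stimulus,
    Wc = delta %o% cache$context,
    bh = delta,
    grad_context = as.numeric(crossprod(params$Wc, delta))
  )
}

#' Apply a gradient-descent update to semantic parameters
#'
#' `theta <- theta - eta * grad` for every weight and bias; aborts on
#' non-finite gradients.
#'
#' @param params A `semantic_params` list.
#' @param grads A gradient list from [semantic_backward()].
#' @return The updated `semantic_params`.
#' @export
semantic_update <- function(params, grads) {
  for (f in c("Ws", "Wc", "bh", "Wo", "bo")) {
    if (!all(is.finite(grads[[f]]))) {
      stop(sprintf("non-finite gradient in %s; aborting update", f),
        call. = FALSE
      )
    }
    params[[f]] <- params[[f]] - params$eta * grads[[f]]
  }
  params
}
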