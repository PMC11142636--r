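#' Linear temporal-context integration
#'
#' One step of the linear context integrator used for passive observation:
#' the new context is `rho * prev + beta * input`, optionally renormalized to
#' unit length. With `rho` in (0, 1) the context is a recency-weighted
#' running sum of the inputs, so temporally adjacent stimuli get similar
#' contexts -- the temporal-context-model view of drifting context.
#'
#' @param prev Numeric context vector.
#' @param input Numeric input vector (same length), typically a one-hot
#'   stimulus encoding.
#' @param rho Decay of the previous context, in \[0, 1\].
#' @param beta Input gain, > 0.
#' @param normalize If `TRUE` (default) the result is scaled to unit
#'   Euclidean norm (zero vectors are left as zero).
#' @return The updated context vector.
#' @export
#' @examples
#' context_integrate(c(0, 0, 0), c(1, 0, 0), normalize = FALSE)
context_integrate <- function(prev, input, rho = 0.5, beta = 1,
                              normalize = TRUE) {
  stopifnot(rho >= 0, rho <= 1, beta > 0)
  if (length(prev) != length(input)) {
    stop(sprintf(
      "input has length %d but the context has length %d",
      length(input), length(prev)
    ), call. = FALSE)
  }
  out <- rho * prev + beta * input
  if (normalize) out <- unit_norm(out)
  out
}

#' Blend a retrieved context into the current context
#'
#' Convex combination `(1 - gamma) * current + gamma * retrieved`, optionally
#' renormalized. This is how a context recalled from episodic memory is
#' folded back into the maintained context: `gamma = 0` ignores retrieval,
#' `gamma = 1` replaces the context outright.
#'
#' @param current,retrieved Numeric context vectors of equal length.
#' @param gamma Blend weight in \[0, 1\].
#' @inheritParams context_integrate
#' @return The blended context vector.
#' @export
context_blend <- function(current, retrieved, gamma = 0.5, normalize = TRUE) {
  if (gamma < 0 || gamma > 1) {
    stop("gamma must lie in [0, 1]", call. = FALSE)
  }
  if (length(current) != length(retrieved)) {
    stop("current and retrieved context lengths differ", call. = FALSE)
  }
  out <- (1 - gamma) * current + gamma * retrieved
  if (normalize) out <- unit_norm(out)
  out
}

unit_norm <- function(x) {
  n <- sqrt(sum(x^2))
  if (n > 0) x / n else x
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Initialize Minimal Gated Unit parameters
#'
#' The learned context module for the prediction and category-learning
#' engines is a Minimal Gated Unit (MGU): a single-gate recurrent cell with a
#' forget gate and a candidate state. Weights are drawn i.i.d. Gaussian with
#' standard deviation `init_sd / sqrt(d_in + d_c)`; biases start at zero.
#'
#' @param d_in Input dimension (what gets concatenated in front of the
#'   recurrent state, e.g. stimulus plus retrieved context).
#' @param d_c Hidden/context dimension.
#' @param eta Learning rate for [mgu_update()], > 0. Deliberately large by
#'   deep-learning standards: the engines learn online from a few hundred
#'   trials.
#' @param init_sd Scale of the random initialization.
#' @return A list of class `mgu_params` with weight matrices `Wf`, `Wh`
#'   (each `d_c x (d_in + d_c)`) and biases `bf`, `bh`.
#' @export
mgu_init <- function(d_in, d_c, eta = 0.5, init_sd = 1) {
  stopifnot(d_in >= 1, d_c >= 1, eta > 0)
  p <- d_in + d_c
  sd0 <- init_sd / sqrt(p)
  structure(
    list(
      Wf = matrix(stats::rnorm(d_c * p, 0, sd0), d_c, p),
      bf = numeric(d_c),
      Wh = matrix(stats::rnorm(d_c * p, 0, sd0), d_c, p),
      bh = numeric(d_c),
      d_in = as.integer(d_in), d_c = as.integer(d_c), eta = eta
    ),
    class = "mgu_params"
  )
}

#' One Minimal Gated Unit step
#'
#' Computes the standard MGU update
#' \deqn{f = \sigma(W_f [x; h] + b_f), \quad
#'       \tilde h = \tanh(W_h [x; f \circ h] + b_h), \quad
#'       h' = (1 - f) \circ h + f \circ \tilde h.}
#' The returned cache carries the intermediate activations needed by
#' [mgu_backward()].
#'
#' @param params An `mgu_params` list.
#' @param prev Previous context vector, length `d_c`.
#' @param input Input vector, length `d_in`.
#' @return A list with `context` (the new state) and `cache`.
#' @export
mgu_step <- function(params, prev, input) {
  if (length(input) != params$d_in) {
    stop(sprintf(
      "input has length %d but the MGU expects %d",
      length(input), params$d_in
    ), call. = FALSE)
  }
  if (length(prev) != params$d_c) {
    stop(sprintf(
      "prev has length %d but the MGU state dimension is %d",
      length(prev), params$d_c
    ), call. = FALSE)
  }
  z <- c(input, prev)
  f <- logistic(as.numeric(params$Wf %*% z) + params$bf)
  z2 <- c(input, f * prev)
  hcand <- tanh(as.numeric(params$Wh %*% z2) + params$bh)
  hnew <- (1 - f) * prev + f * hcand
  list(
    context = hnew,
    cache = list(z = z, z2 = z2, f = f, hcand = hcand, prev = prev)
  )
}

#' Truncated MGU backward pass
#'
#' Gradients of a scalar loss with respect to the MGU parameters, given the
#' gradient `grad_context` of that loss with respect to the step's output
#' state. Backpropagation is *truncated*: the previous context is treated as
#' a constant, so no gradient flows into earlier time steps and the per-step
#' cost is independent of sequence length.
#'
#' @param params An `mgu_params` list.
#' @param cache The cache returned by [mgu_step()].
#' @param grad_context Numeric vector, `dL/d context`, length `d_c`.
#' @return A list of gradients `Wf`, `bf`, `Wh`, `bh` matching the parameter
#'   shapes, plus `grad_prev` (`dL/d prev`) for callers that unroll over a
#'   window instead of truncating (the truncated engines simply ignore it).
#' @export
mgu_backward <- function(params, cache, grad_context) {
  g <- as.numeric(grad_context)
  f <- cache$f
  hcand <- cache$hcand
  prev <- cache$prev
  d_in <- params$d_in
  prev_slots <- (d_in + 1):(d_in + params$d_c)
  delta_h <- g * f * (1 - hcand^2) # into the candidate pre-activation
  q_prev <- as.numeric(crossprod(params$Wh, delta_h))[prev_slots] # gated slot
  df <- g * (hcand - prev) + q_prev * prev
  delta_f <- df * f * (1 - f)
  list(
    Wf = delta_f %o% cache$z,
    bf = delta_f,
    Wh = delta_h %o% cache$z2,
    bh = delta_h,
    grad_prev = g * (1 - f) + q_prev * f +
      as.numeric(crossprod(params$Wf, delta_f))[prev_slots]
  )
}

#' Apply a gradient-descent update to MGU parameters
#'
#' Plain (momentum-free) gradient descent with the step size stored in the
#' parameters: `theta <- theta - eta * grad`. Aborts with a diagnostic if any
#' gradient entry is non-finite.
#'
#' @param params An `mgu_params` list.
#' @param grads A gradient list as returned by [mgu_backward()].
#' @return The updated `mgu_params`.
#' @export
mgu_update <- function(params, grads) {
  for (f in c("Wf", "bf", "Wh", "bh")) {
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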