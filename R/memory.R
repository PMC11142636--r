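#' Create an empty episodic memory store
#'
#' The episodic store keeps three row-aligned matrices -- stimulus keys,
#' context keys, and outcomes -- one row per stored experience. Writing is
#' append-only: rows are never modified or overwritten once stored, so the
#' store accumulates the full history of experiences. Internally the store
#' uses an environment with preallocated, doubling buffers so that appends
#' are O(1) amortized; this gives the store *reference* semantics, like a
#' connection or an R6 object (appending mutates the store in place).
#'
#' Alongside the raw key matrices the store caches row-normalized copies, so
#' similarity queries reduce to a single matrix-vector product.
#'
#' @param d_s Stimulus key dimension (columns of the stimulus matrix).
#' @param d_c Context key dimension.
#' @param d_o Outcome dimension (1 for a scalar reward, a one-hot length for
#'   a next-state or category code).
#' @param capacity Initial row capacity; grows automatically by doubling.
#' @return An object of class `memory_store`.
#' @seealso [memory_append()], [memory_recall()], [memory_weights()]
#' @export
#' @examples
#' m <- memory_store(d_s = 3, d_c = 3, d_o = 1)
#' memory_append(m, c(1, 0, 0), c(0, 0, 0), 1)
#' memory_n(m)
memory_store <- function(d_s, d_c, d_o, capacity = 128L) {
  stopifnot(d_s >= 1, d_c >= 1, d_o >= 1, capacity >= 1)
  st <- new.env(parent = baseenv())
  st$d_s <- as.integer(d_s)
  st$d_c <- as.integer(d_c)
  st$d_o <- as.integer(d_o)
  st$n <- 0L
  st$cap <- as.integer(capacity)
  st$S <- matrix(0, capacity, d_s)
  st$C <- matrix(0, capacity, d_c)
  st$O <- matrix(0, capacity, d_o)
  # row-normalized copies of the key matrices (zero rows stay zero, which
  # implements the cosine(0, x) = 0 convention)
  st$Sn <- matrix(0, capacity, d_s)
  st$Cn <- matrix(0, capacity, d_c)
  # writer closure evaluated inside the store environment: superassignment
  # modifies the matrices in place, where a complex assignment through `$`
  # from another function's frame would copy the whole buffer each append
  st$.write <- eval(
    quote(function(i, s, cc, o, sn, cn) {
      S[i, ] <<- s
      C[i, ] <<- cc
      O[i, ] <<- o
      Sn[i, ] <<- sn
      Cn[i, ] <<- cn
      n <<- i
    }),
    st
  )
  class(st) <- "memory_store"
  st
}

#' @export
print.memory_store <- function(x, ...) {
  cat(sprintf(
    "<memory_store: %d rows (d_s = %d, d_c = %d, d_o = %d)>\n",
    x$n, x$d_s, x$d_c, x$d_o
  ))
  invisible(x)
}

#' Number of rows stored in an episodic memory
#' @param store A `memory_store`.
#' @return Integer row count.
#' @export
memory_n <- function(store) {
  stopifnot(inherits(store, "memory_store"))
  store$n
}

grow_store <- function(store, need) {
  while (store$cap < need) {
    newcap <- store$cap * 2L
    for (f in c("S", "C", "O", "Sn", "Cn")) {
      old <- store[[f]]
      new <- matrix(0, newcap, ncol(old))
      if (store$n > 0L) new[seq_len(store$n), ] <- old[seq_len(store$n), ]
      store[[f]] <- new
    }
    store$cap <- newcap
  }
  invisible(store)
}

#' Append one experience to episodic memory
#'
#' Appends a (stimulus, context, outcome) triplet as a new row. Existing rows
#' are never touched; duplicates are stored again rather than merged. The
#' store is modified in place and returned invisibly so calls can be piped.
#'
#' @param store A `memory_store`.
#' @param stimulus Numeric vector of length `d_s`.
#' @param context Numeric vector of length `d_c`.
#' @param outcome Numeric vector of length `d_o` (scalars are fine for
#'   `d_o = 1`).
#' @return The store, invisibly.
#' @export
memory_append <- function(store, stimulus, context, outcome) {
  stopifnot(inherits(store, "memory_store"))
  stimulus <- as.numeric(stimulus)
  context <- as.numeric(context)
  outcome <- as.numeric(outcome)
  if (length(stimulus) != store$d_s) {
    stop(sprintf(
      "stimulus has length %d but the store's stimulus dimension is %d",
      length(stimulus), store$d_s
    ), call. = FALSE)
  }
  if (length(context) != store$d_c) {
    stop(sprintf(
      "context has length %d but the store's context dimension is %d",
      length(context), store$d_c
    ), call. = FALSE)
  }
  if (length(outcome) != store$d_o) {
    stop(sprintf(
      "outcome has length %d but the store's outcome dimension is %d",
      length(outcome), store$d_o
    ), call. = FALSE)
  }
  i <- store$n + 1L
  grow_store(store, i)
  ns <- sqrt(sum(stimulus^2))
  nc <- sqrt(sum(context^2))
  store$.write(
    i, stimulus, context, outcome,
    if (ns > 0) stimulus / ns else numeric(store$d_s),
    if (nc > 0) context / nc else numeric(store$d_c)
  )
  invisible(store)
}

#' Retrieval configuration for episodic memory
#'
#' Controls how per-row match scores are turned into retrieval weights. A
#' row's score is `stimulus_weight * cos(query_stimulus, stimulus_row) +
#' context_weight * cos(query_context, context_row)`; the cosine of a zero
#' vector is defined as 0. Scores become weights either through a
#' temperature-`tau` softmax (default; differentiable, with a
#' nearest-neighbour limit as `tau -> 0`) or through clipped linear
#' normalization of the raw scores.
#'
#' @param tau Softmax temperature, > 0. Smaller is sharper.
#' @param stimulus_weight,context_weight Nonnegative mixing weights for the
#'   two key similarities; at least one must be positive.
#' @param transform `"softmax"` (default) or `"linear"` (raw scores clipped
#'   at zero and normalized to sum to one).
#' @return A list of class `retrieval_config`.
#' @export
retrieval_config <- function(tau = 0.1, stimulus_weight = 1, context_weight = 1,
                             transform = c("softmax", "linear")) {
  transform <- match.arg(transform)
  stopifnot(tau > 0, stimulus_weight >= 0, context_weight >= 0)
  if (stimulus_weight + context_weight <= 0) {
    stop("at least one of stimulus_weight, context_weight must be positive",
      call. = FALSE
    )
  }
  structure(
    list(
      tau = tau, stimulus_weight = stimulus_weight,
      context_weight = context_weight, transform = transform
    ),
    class = "retrieval_config"
  )
}

# raw per-row match scores; norms of zero rows/queries give cosine 0
memory_scores <- function(store, query_stimulus, query_context, cfg) {
  n <- store$n
  idx <- seq_len(n)
  sc <- numeric(n)
  if (cfg$stimulus_weight > 0) {
    qs <- as.numeric(query_stimulus)
    nq <- sqrt(sum(qs^2))
    if (nq > 0) {
      sc <- sc + cfg$stimulus_weight * as.numeric(store$Sn %*% (qs / nq))[idx]
    }
  }
  if (cfg$context_weight > 0) {
    qc <- as.numeric(query_context)
    nq <- sqrt(sum(qc^2))
    if (nq > 0) {
      sc <- sc + cfg$context_weight * as.numeric(store$Cn %*% (qc / nq))[idx]
    }
  }
  sc
}

#' Similarity-based retrieval weights
#'
#' Scores every stored row against a (stimulus, context) query by mixed
#' cosine similarity and converts the scores to a simplex weight vector (see
#' [retrieval_config()]). The softmax transform makes the weights -- and any
#' retrieved quantity built from them -- differentiable in the query context,
#' which the learning engines rely on.
#'
#' @param store A non-empty `memory_store`.
#' @param query_stimulus Numeric vector of length `d_s` (may be all zero, in
#'   which case the stimulus similarity contributes 0 to every score).
#' @param query_context Numeric vector of length `d_c` (same convention).
#' @param cfg A [retrieval_config()].
#' @return Numeric weight vector of length `memory_n(store)`; nonnegative,
#'   sums to 1.
#' @export
memory_weights <- function(store, query_stimulus, query_context,
                           cfg = retrieval_config()) {
  stopifnot(inherits(store, "memory_store"))
  if (store$n == 0L) {
    stop("no memories: the store is empty, nothing to retrieve", call. = FALSE)
  }
  if (length(query_stimulus) != store$d_s) {
    stop(sprintf(
      "query_stimulus has length %d but the store's stimulus dimension is %d",
      length(query_stimulus), store$d_s
    ), call. = FALSE)
  }
  if (length(query_context) != store$d_c) {
    stop(sprintf(
      "query_context has length %d but the store's context dimension is %d",
      length(query_context), store$d_c
    ), call. = FALSE)
  }
  sc <- memory_scores(store, query_stimulus, query_context, cfg)
  scores_to_weights(sc, cfg)
}

scores_to_weights <- function(sc, cfg) {
  if (cfg$transform == "softmax") {
    z <- sc / cfg$tau
    w <- exp(z - max(z))
    w / sum(w)
  } else {
    w <- pmax(sc, 0)
    s <- sum(w)
    if (s <= 0) rep(1 / length(w), length(w)) else w / s
  }
}

#' Read from episodic memory with a given weight vector
#'
#' Forms the retrieved memory as the weights-weighted average of the stored
#' rows: a retrieved stimulus, retrieved context, and retrieved outcome. With
#' simplex weights each retrieved component is a convex combination of the
#' stored values.
#'
#' @param store A non-empty `memory_store`.
#' @param weights Numeric vector of length `memory_n(store)`, nonnegative and
#'   summing to 1 (within 1e-8).
#' @return A list of class `retrieved_memory` with elements `stimulus`,
#'   `context`, `outcome`, `weights`, and `empty = FALSE`.
#' @export
memory_read <- function(store, weights) {
  stopifnot(inherits(store, "memory_store"))
  n <- store$n
  if (length(weights) != n) {
    stop(sprintf(
      "weights has length %d but the store holds %d rows",
      length(weights), n
    ), call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < -1e-12)) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  wfull <- numeric(store$cap)
  wfull[seq_len(n)] <- weights
  structure(
    list(
      stimulus = as.numeric(crossprod(store$S, wfull)),
      context = as.numeric(crossprod(store$C, wfull)),
      outcome = as.numeric(crossprod(store$O, wfull)),
      weights = weights,
      empty = FALSE
    ),
    class = "retrieved_memory"
  )
}

empty_retrieval <- function(store) {
  structure(
    list(
      stimulus = numeric(store$d_s),
      context = numeric(store$d_c),
      outcome = numeric(store$d_o),
      weights = numeric(0),
      empty = TRUE
    ),
    class = "retrieved_memory"
  )
}

#' Query episodic memory
#'
#' Convenience wrapper: computes retrieval weights for a (stimulus, context)
#' query and reads the weighted-average memory. An empty store returns an
#' all-zero retrieval flagged `empty = TRUE` rather than an error, which is
#' how the engines treat the very first trial.
#'
#' @inheritParams memory_weights
#' @return A `retrieved_memory` (see [memory_read()]).
#' @export
memory_recall <- function(store, query_stimulus, query_context,
                          cfg = retrieval_config()) {
  stopifnot(inherits(store, "memory_store"))
  if (store$n == 0L) {
    return(empty_retrieval(store))
  }
  w <- memory_weights(store, query_stimulus, query_context, cfg)
  memory_read(store, w)
}

#' Gradient of a retrieval-based loss with respect to the query context
#'
#' For a scalar loss `L = sum(upstream * outcome_hat)` where `outcome_hat` is
#' the softmax-weighted retrieved outcome, returns `dL/d query_context`.
#' This is the analytic gradient the learning engines backpropagate through
#' episodic retrieval; it is exact for the `"softmax"` transform (and is what
#' the finite-difference tests check).
#'
#' @inheritParams memory_weights
#' @param upstream Numeric vector of length `d_o`: the gradient of the loss
#'   with respect to the retrieved outcome.
#' @return Numeric vector of length `d_c`.
#' @export
memory_context_grad <- function(store, query_stimulus, query_context, upstream,
                                cfg = retrieval_config()) {
  stopifnot(inherits(store, "memory_store"), store$n > 0L)
  if (cfg$transform != "softmax") {
    stop("analytic retrieval gradients are only defined for the softmax transform",
      call. = FALSE
    )
  }
  n <- store$n
  qc <- as.numeric(query_context)
  nq <- sqrt(sum(qc^2))
  if (nq == 0 || cfg$context_weight == 0) {
    # cosine of a zero query is constant 0; no gradient flows
    return(numeric(store$d_c))
  }
  w <- memory_weights(store, query_stimulus, query_context, cfg)
  wfull <- numeric(store$cap)
  wfull[seq_len(n)] <- w
  a <- as.numeric(store$O %*% as.numeric(upstream))[seq_len(n)] # dL/dw_i
  b <- w * (a - sum(w * a)) / cfg$tau # dL/dscore_i through softmax
  bfull <- numeric(store$cap)
  bfull[seq_len(n)] <- b
  v <- cfg$context_weight * as.numeric(crossprod(store$Cn, bfull)) # dL/d(unit qc)
  u <- qc / nq
  (v - u * sum(u * v)) / nq # through the normalization of the query
}

# Fast-path recall used by the simulation engines: computes the similarity
# scores once and shares them between the retrieval and its context
# gradient (returned as a closure). Mathematically identical to
# memory_weights() + memory_read() + memory_context_grad(); the equivalence
# is unit-tested.
recall_with_grad <- function(store, query_stimulus, query_context, cfg,
                             with_stimulus = TRUE) {
  n <- store$n
  if (n == 0L) {
    out <- empty_retrieval(store)
    out$context_grad <- function(upstream) numeric(store$d_c)
    return(out)
  }
  idx <- seq_len(n)
  qc <- as.numeric(query_context)
  nqc <- sqrt(sum(qc^2))
  sc <- memory_scores(store, query_stimulus, qc, cfg)
  w <- scores_to_weights(sc, cfg)
  wfull <- numeric(store$cap)
  wfull[idx] <- w
  structure(
    list(
      stimulus = if (with_stimulus) {
        as.numeric(crossprod(store$S, wfull))
      } else {
        NULL
      },
      context = as.numeric(crossprod(store$C, wfull)),
      outcome = as.numeric(crossprod(store$O, wfull)),
      weights = w,
      empty = FALSE,
      context_grad = function(upstream) {
        if (nqc == 0 || cfg$context_weight == 0) {
          return(numeric(store$d_c))
        }
        upstream <- as.numeric(upstream)
        nz <- which(upstream != 0)
        a <- if (length(nz) == 1L) {
          # single-component upstream (cross-entropy): one column read
          upstream[nz] * store$O[idx, nz]
        } else {
          as.numeric(store$O %*% upstream)[idx]
        }
        b <- w * (a - sum(w * a)) / cfg$tau
        bfull <- numeric(store$cap)
        bfull[idx] <- b
        v <- cfg$context_weight * as.numeric(crossprod(store$Cn, bfull))
        u <- qc / nqc
        (v - u * sum(u * v)) / nqc
      }
    ),
    class = "retrieved_memory"
  )
}

#' Dump an episodic memory as a tibble
#'
#' One row per memory, with columns `s_1..s_ds`, `c_1..c_dc`, `o_1..o_do`,
#' prefixed by field. Useful for inspection and for round-tripping through a
#' delimited file (see [memory_export()]).
#'
#' @param x A `memory_store`.
#' @param ... Unused.
#' @return A tibble with `memory_n(x)` rows.
#' @method as_tibble memory_store
#' @export
as_tibble.memory_store <- function(x, ...) {
  idx <- seq_len(x$n)
  s <- x$S[idx, , drop = FALSE]
  cc <- x$C[idx, , drop = FALSE]
  o <- x$O[idx, , drop = FALSE]
  colnames(s) <- paste0("s_", seq_len(x$d_s))
  colnames(cc) <- paste0("c_", seq_len(x$d_c))
  colnames(o) <- paste0("o_", seq_len(x$d_o))
  tibble::as_tibble(cbind(
    as.data.frame(s), as.data.frame(cc),
    as.data.frame(o)
  ))
}

#' Write / read an episodic memory as a delimited table
#'
#' `memory_export()` writes the row dump of [as_tibble.memory_store()] as a
#' tab-separated file; `memory_import()` reconstructs an equivalent store
#' from such a file (column prefixes `s_`, `c_`, `o_` determine the field
#' dimensions).
#'
#' @param store A `memory_store`.
#' @param path File path.
#' @return `memory_export()` the path invisibly; `memory_import()` a new
#'   `memory_store`.
#' @export
memory_export <- function(store, path) {
  df <- as_tibble.memory_store(store)
  utils::write.table(df, path,
    sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  invisible(path)
}

#' @rdname memory_export
#' @export
memory_import <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  s_cols <- grep("^s_", names(df))
  c_cols <- grep("^c_", names(df))
  o_cols <- grep("^o_", names(df))
  if (!length(s_cols) || !length(c_cols) || !length(o_cols)) {
    stop("file does not look like a memory dump (need s_/c_/o_ columns)",
      call. = FALSE
    )
  }
  st <- memory_store(length(s_cols), length(c_cols), length(o_cols),
    capacity = max(1L, nrow(df))
  )
  for (i in seq_len(nrow(df))) {
    memory_append(
      st, as.numeric(df[i, s_cols]), as.numeric(df[i, c_cols]),
      as.numeric(df[i, o_cols])
    )
  }
  st
}
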