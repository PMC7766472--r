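# Discrete Hopfield network: Hebbian one-shot training, recall dynamics and
# the quadratic energy function.
#
# A network of N fully connected threshold neurons stores bipolar patterns as
# attractors. Training is the outer-product (Hebb) rule
#   W = eta * sum_p p p^T,  diag(W) = 0,
# which is symmetric with no self-feedback, the conditions under which the
# asynchronous dynamics admit the Lyapunov energy
#   E(v) = -1/2 sum_ij W_ij v_i v_j - sum_i I_i v_i
# and converge to a fixed point. Recall iterates u_i = sum_j W_ij v_j + I_i,
# v_i = sign(u_i) (u_i = 0 keeps the previous state).

#' Fit a Hopfield associative memory by Hebbian storage
#'
#' Stores one or more bipolar patterns in a symmetric zero-diagonal weight
#' matrix by the outer-product Hebb rule. The learning rate `eta` scales all
#' weights uniformly; since recall thresholds on the sign of the local field,
#' any `eta > 0` yields identical recall.
#'
#' @param patterns a [template()], a list of templates, a bipolar vector, or
#'   a matrix with one bipolar pattern per row.
#' @param eta learning rate, must be positive.
#' @return an object of class `hopfield`: list with `weights` (N x N),
#'   `eta`, `n` (neuron count), `patterns` (stored patterns, one per row).
#' @examples
#' p <- rep(c(1, -1), length.out = 25)
#' net <- hopfield(p)
#' all.equal(predict(net, p), p)
#' @seealso [recall()], [energy()], [simulate.hopfield()] for the
#'   analog-circuit backend.
#' @export
hopfield <- function(patterns, eta = 1) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta > 0)
  P <- as_pattern_matrix(patterns)
  n <- ncol(P)
  W <- eta * crossprod(P)        # sum over patterns of outer products
  diag(W) <- 0                   # no self-feedback
  structure(list(weights = unname(W), eta = eta, n = n, patterns = P),
            class = "hopfield")
}

## Accept either a fitted net or a raw weight matrix; validate the Hopfield
## structural conditions that the energy argument relies on.
as_weights <- function(object) {
  W <- if (inherits(object, "hopfield")) object$weights else as.matrix(object)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (!isSymmetric(unname(W), tol = 1e-12)) {
    stop("weight matrix must be symmetric (Wij = Wji)")
  }
  if (any(diag(W) != 0)) stop("weight matrix must have a zero diagonal (no self-feedback)")
  unname(W)
}

#' @export
print.hopfield <- function(x, ...) {
  cat(sprintf("<hopfield> %d neurons, %d stored pattern(s), eta = %g\n",
              x$n, nrow(x$patterns), x$eta))
  invisible(x)
}

#' @export
summary.hopfield <- function(object, ...) {
  W <- object$weights
  res <- list(n = object$n, n_patterns = nrow(object$patterns),
              eta = object$eta, weight_range = range(W[upper.tri(W)]),
              load = nrow(object$patterns) / object$n,
              stored_are_fixed = vapply(seq_len(nrow(object$patterns)),
                                        function(k) is_fixed_point(object, object$patterns[k, ]),
                                        logical(1)))
  class(res) <- "summary.hopfield"
  res
}

#' @export
print.summary.hopfield <- function(x, ...) {
  cat(sprintf("Hopfield network: %d neurons, %d stored pattern(s) (load %.3f), eta = %g\n",
              x$n, x$n_patterns, x$load, x$eta))
  cat(sprintf("off-diagonal weight range: [%g, %g]\n",
              x$weight_range[1], x$weight_range[2]))
  cat(sprintf("stored patterns that are fixed points: %d / %d\n",
              sum(x$stored_are_fixed), x$n_patterns))
  invisible(x)
}

#' @export
coef.hopfield <- function(object, ...) object$weights

#' Hopfield energy of a state
#'
#' The quadratic Lyapunov function
#' `E(v) = -1/2 * t(v) %*% W %*% v - sum(I * v)`. Under asynchronous updates
#' with symmetric zero-diagonal weights, E never increases.
#'
#' @param object a `hopfield` fit or a symmetric zero-diagonal weight matrix.
#' @param v bipolar state vector.
#' @param I external input (bias) vector, recycled scalar allowed.
#' @return the scalar energy.
#' @export
energy <- function(object, v, I = 0) {
  W <- as_weights(object)
  assert_bipolar(v, "state")
  stopifnot(length(v) == nrow(W))
  I <- rep_len(I, length(v))
  -0.5 * sum(v * (W %*% v)) - sum(I * v)
}

#' Is a state a fixed point of the recall dynamics?
#'
#' `TRUE` iff one synchronous sweep (with the keep-state tie rule at zero
#' field) leaves the state unchanged, i.e. no neuron's sign disagrees with
#' its local field.
#'
#' @inheritParams energy
#' @export
is_fixed_point <- function(object, v, I = 0) {
  W <- as_weights(object)
  assert_bipolar(v, "state")
  stopifnot(length(v) == nrow(W))
  I <- rep_len(I, length(v))
  u <- as.vector(W %*% v) + I
  all(sign_threshold(u, v) == v)
}

#' Associative recall from a probe state
#'
#' Iterates the discrete Hopfield dynamics from `init` until a full sweep
#' changes no neuron or `max_sweeps` is reached. Asynchronous mode updates
#' one neuron at a time in a fresh seeded random order each sweep and records
#' the energy after every single-neuron update (the trace is non-increasing);
#' synchronous mode updates all neurons at once and records energy per sweep.
#'
#' @param object a `hopfield` fit or weight matrix.
#' @param init bipolar probe vector.
#' @param I external input (bias) vector; default 0.
#' @param mode `"async"` (default) or `"sync"`.
#' @param max_sweeps sweep budget.
#' @param seed seed for the asynchronous update order (ignored for sync).
#' @return a `hopfield_recall`: list with `state` (final bipolar vector),
#'   `converged`, `sweeps`, `energy` (trace, starting at the probe's energy),
#'   `mode`, `init`.
#' @export
recall <- function(object, init, I = 0, mode = c("async", "sync"),
                   max_sweeps = 100L, seed = NULL) {
  W <- as_weights(object)
  mode <- match.arg(mode)
  assert_bipolar(init, "init")
  n <- nrow(W)
  stopifnot(length(init) == n, max_sweeps >= 1)
  I <- rep_len(I, n)
  v <- init
  etrace <- energy(W, v, I)
  converged <- FALSE
  sweeps <- 0L
  with_seed(seed, {
    for (s in seq_len(max_sweeps)) {
      sweeps <- s
      if (mode == "sync") {
        u <- as.vector(W %*% v) + I
        vnew <- sign_threshold(u, v)
        changed <- any(vnew != v)
        v <- vnew
        etrace <- c(etrace, energy(W, v, I))
      } else {
        changed <- FALSE
        for (i in sample.int(n)) {
          u_i <- sum(W[i, ] * v) + I[i]
          v_i <- if (u_i > 0) 1 else if (u_i < 0) -1 else v[i]
          if (v_i != v[i]) changed <- TRUE
          v[i] <- v_i
          etrace <- c(etrace, energy(W, v, I))
        }
      }
      if (!changed) { converged <- TRUE; break }
    }
  })
  structure(list(state = v, converged = converged, sweeps = sweeps,
                 energy = etrace, mode = mode, init = init),
            class = "hopfield_recall")
}

#' @export
print.hopfield_recall <- function(x, ...) {
  cat(sprintf("<hopfield_recall> %s, %s after %d sweep(s), E = %g\n",
              x$mode, if (x$converged) "converged" else "NOT converged",
              x$sweeps, x$energy[length(x$energy)]))
  invisible(x)
}

#' Recall stored patterns from probe states
#'
#' `predict` runs [recall()] from each probe and returns the final states;
#' use [recall()] directly when the energy trace or convergence diagnostics
#' are needed.
#'
#' @param object a `hopfield` fit.
#' @param newdata a bipolar vector, a matrix with one probe per row, or a
#'   [template()].
#' @param ... passed to [recall()] (`I`, `mode`, `max_sweeps`, `seed`).
#' @return a vector (single probe) or matrix (one recalled state per row).
#' @export
predict.hopfield <- function(object, newdata, ...) {
  single <- is.vector(newdata) || inherits(newdata, "pattern_template")
  P <- as_pattern_matrix(newdata)
  out <- t(apply(P, 1, function(p) recall(object, p, ...)$state))
  if (single) out[1, ] else out
}

#' Plot a Hopfield weight matrix
#'
#' @param x a `hopfield` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.hopfield <- function(x, ...) {
  W <- x$weights
  graphics::image(seq_len(x$n), seq_len(x$n), t(W[x$n:1, ]),
                  xlab = "neuron j", ylab = "neuron i", main = "Hebbian weights",
                  ...)
  invisible(x)
}

#' Plot the energy trace of a recall
#'
#' @param x a `hopfield_recall`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hopfield_recall <- function(x, ...) {
  graphics::plot(seq_along(x$energy) - 1, x$energy, type = "s",
                 xlab = "update", ylab = "energy E", main = "Recall energy trace",
                 ...)
  invisible(x)
}

#' Enumerate all fixed points of a small network
#'
#' Exhaustively checks every bipolar state of an N-neuron network
#' (2^N states), so it is only practical for small N. Intended as a
#' brute-force oracle for validating recall dynamics.
#'
#' @param object a `hopfield` fit or weight matrix (N <= 20).
#' @param I external input vector.
#' @return matrix with one fixed-point state per row.
#' @export
fixed_points <- function(object, I = 0) {
  W <- as_weights(object)
  n <- nrow(W)
  if (n > 20L) stop("exhaustive enumeration limited to N <= 20 neurons")
  states <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(states) <- NULL
  keep <- apply(states, 1, function(v) is_fixed_point(W, v, I))
  states[keep, , drop = FALSE]
}
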