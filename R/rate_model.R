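#' Transition rate models for discrete-trait Markov evolution
#'
#' A rate model constrains the instantaneous rate matrix Q of the Mk model:
#' it specifies which transitions are forbidden (index 0) and which share a
#' rate parameter (equal positive indices). The three standard models are
#' equal rates (ER, one shared rate), symmetric (SYM, `k(k-1)/2` rates with
#' `q_ij = q_ji`) and all rates different (ARD, `k(k-1)` free rates).
#'
#' @param kind `"ER"`, `"SYM"`, `"ARD"`, or a `k x k` integer index matrix
#'   for a custom model (diagonal ignored; 0 forbids a transition, equal
#'   positive entries share a rate).
#' @param k Number of categories (>= 2); inferred from a custom matrix.
#' @param states Optional character vector of category labels.
#' @return Object of class `rate_model` with fields `k`, `index` and
#'   `states`.
#' @examples
#' rate_model("ER", 3)   # 1 free parameter
#' rate_model("ARD", 3)  # 6 free parameters
#' @export
rate_model <- function(kind = "ER", k = NULL, states = NULL) {
  if (is.matrix(kind)) {
    idx <- kind
    if (nrow(idx) != ncol(idx)) stop("index matrix must be square")
    k <- nrow(idx)
    storage.mode(idx) <- "integer"
    if (any(idx[row(idx) != col(idx)] < 0L, na.rm = TRUE))
      stop("index entries must be >= 0")
    diag(idx) <- 0L
    # renumber indices compactly, preserving order of first appearance
    off <- idx[row(idx) != col(idx)]
    pos <- unique(off[off > 0L])
    idx[] <- ifelse(idx > 0L, match(idx, pos), 0L)
  } else {
    kind <- match.arg(toupper(kind), c("ER", "SYM", "ARD"))
    if (is.null(k) || k < 2) stop("k must be >= 2")
    idx <- matrix(0L, k, k)
    o <- which(row(idx) != col(idx))
    if (kind == "ER") {
      idx[o] <- 1L
    } else if (kind == "ARD") {
      idx[o] <- seq_along(o)
    } else { # SYM
      cnt <- 0L
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        cnt <- cnt + 1L
        idx[i, j] <- idx[j, i] <- cnt
      }
    }
  }
  if (!is.null(states) && length(states) != k)
    stop("states must have length k")
  structure(list(k = k, index = idx, states = states,
                 name = if (is.matrix(kind)) "custom" else kind),
            class = "rate_model")
}

#' Number of free rate parameters of a rate model
#' @param model A `rate_model`.
#' @return Integer count of distinct positive indices.
#' @export
n_free_params <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  length(unique(model$index[model$index > 0L]))
}

#' Test whether one rate model is nested in another
#'
#' `simple` is nested in `complex` when constraining the parameters of
#' `complex` (equating some, zeroing others) can realise `simple`: every
#' transition `complex` forbids must be forbidden in `simple`, and all
#' transitions sharing a rate in `complex` must share a fate in `simple`
#' (all forbidden, or all in one equality class).
#'
#' @param simple,complex `rate_model` objects with the same `k`.
#' @return `TRUE` or `FALSE`.
#' @export
is_nested <- function(simple, complex) {
  stopifnot(inherits(simple, "rate_model"), inherits(complex, "rate_model"))
  if (simple$k != complex$k) stop("rate models have different k")
  s <- simple$index; cx <- complex$index
  off <- row(s) != col(s)
  if (any(cx[off] == 0L & s[off] != 0L)) return(FALSE)
  for (cls in unique(cx[off & cx > 0L])) {
    lab <- s[off & cx == cls]
    if (length(unique(lab)) > 1L) return(FALSE)
  }
  # constraining can only reduce the parameter count
  n_free_params(simple) <= n_free_params(complex)
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("Rate model '%s': k = %d, %d free parameter(s)\n",
              x$name, x$k, n_free_params(x)))
  m <- x$index
  dimnames(m) <- list(x$states %||% seq_len(x$k), x$states %||% seq_len(x$k))
  print(m)
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a rate matrix Q from free rates and a rate model
#'
#' Off-diagonal entries take the rate of their index class (0 where
#' forbidden); rows sum to zero.
#'
#' @param rates Numeric vector, one value (>= 0) per free parameter.
#' @param model A `rate_model`.
#' @return `k x k` rate matrix.
#' @export
build_Q <- function(rates, model) {
  stopifnot(inherits(model, "rate_model"))
  if (length(rates) != n_free_params(model))
    stop("expected ", n_free_params(model), " rates")
  if (any(rates < 0)) stop("rates must be >= 0")
  Q <- matrix(0, model$k, model$k)
  pos <- model$index > 0L
  Q[pos] <- rates[model$index[pos]]
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(model$states, model$states)
  Q
}
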