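# Continuous-time Markov (Mk) model machinery: likelihood by pruning,
# maximum-likelihood fitting, marginal ancestral reconstruction and
# rate-model comparison.

# Per-edge transition probability matrices exp(Q t), one per edge, computed
# once per unique branch length. Eigen-decomposition fast path with a
# Matrix::expm fallback when Q is defective or reconstruction is inaccurate.
#' @keywords internal
edge_pmats <- function(Q, lens) {
  k <- nrow(Q)
  ulen <- unique(lens)
  pm <- vector("list", length(ulen))
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eg) && all(is.finite(eg$values))) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      recon <- Re(eg$vectors %*% diag(eg$values, k) %*% Vi)
      use_eigen <- max(abs(recon - Q)) < 1e-8 * max(1, max(abs(Q)))
    }
  }
  for (i in seq_along(ulen)) {
    t_i <- ulen[i]
    if (t_i == 0) {
      P <- diag(k)
    } else if (use_eigen) {
      P <- Re(eg$vectors %*% (exp(eg$values * t_i) * Vi))
    } else {
      P <- as.matrix(Matrix::expm(Q * t_i))
    }
    P[P < 0] <- 0
    P <- P / rowSums(P)
    pm[[i]] <- P
  }
  pm[match(lens, ulen)]
}

# Map a named species -> category vector onto tree tip order, returning
# integer state indices (NA allowed = ambiguous tip) and the category levels
# in first-appearance order unless 'states' fixes them.
#' @keywords internal
tip_state_indices <- function(tree, tip_states, states = NULL) {
  tips <- tree$tip.label
  if (is.null(names(tip_states)))
    stop("tip_states must be named by species")
  missing_sp <- setdiff(tips, names(tip_states))
  if (length(missing_sp))
    stop("tip_states missing species: ", paste(missing_sp, collapse = ", "))
  v <- tip_states[tips]
  if (is.factor(tip_states)) {
    lev <- levels(tip_states)
    v <- as.character(v)
  } else {
    v <- as.character(v)
    lev <- unique(v[!is.na(v)])
  }
  if (!is.null(states)) {
    bad <- setdiff(unique(v[!is.na(v)]), states)
    if (length(bad))
      stop("state label(s) not in category set: ", paste(bad, collapse = ", "))
    lev <- states
  }
  list(idx = match(v, lev), states = lev)
}

#' @keywords internal
resolve_root_prior <- function(root_prior, Q, k) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k || any(root_prior < 0))
      stop("root prior must be a length-k nonnegative vector")
    if (abs(sum(root_prior) - 1) > 1e-8) stop("root prior must sum to 1")
    return(root_prior)
  }
  switch(match.arg(root_prior, c("flat", "stationary")),
    flat = rep(1 / k, k),
    stationary = stationary_dist(Q)
  )
}

# Left null vector of Q (pi Q = 0), normalised; flat when Q is ~ 0.
#' @keywords internal
stationary_dist <- function(Q) {
  k <- nrow(Q)
  if (max(abs(Q)) < 1e-12) return(rep(1 / k, k))
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- tryCatch(as.vector(qr.solve(A, b)), error = function(e) rep(1 / k, k))
  pi_hat[pi_hat < 0] <- 0
  pi_hat / sum(pi_hat)
}

# Felsenstein pruning with per-message rescaling. Returns the scaled
# conditional likelihood matrix (rows = nodes), the accumulated log scale,
# and the per-edge upward messages needed by the downward pass.
#' @keywords internal
mk_pruning <- function(tree, tipidx, pmats, k) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- matrix(1, nnode, k)
  for (i in seq_len(ntip))
    if (!is.na(tipidx[i])) L[i, ] <- as.numeric(seq_len(k) == tipidx[i])
  msg <- matrix(NA_real_, nrow(tree$edge), k)
  logscale <- 0
  dead <- FALSE
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    w <- as.vector(pmats[[e]] %*% L[ch, ])
    m <- max(w)
    if (m <= 0) { dead <- TRUE; m <- 1 }
    w <- w / m
    logscale <- logscale + log(m)
    msg[e, ] <- w
    L[par, ] <- L[par, ] * w
  }
  list(L = L, msg = msg, logscale = if (dead) -Inf else logscale)
}

#' Log-likelihood of tip data under an Mk model
#'
#' Computes, by Felsenstein pruning with per-node rescaling, the log of the
#' probability of the observed tip categories summed over all internal state
#' assignments, each edge contributing a factor `(e^{Q t})[x, y]` and the
#' root weighted by `root_prior`.
#'
#' @param tree `phylo` with branch lengths (zero lengths allowed).
#' @param tip_states Named vector (species -> category label), or factor.
#'   `NA` marks a tip with unknown state (integrated out).
#' @param Q Rate matrix (off-diagonals >= 0, rows summing to 0).
#' @param root_prior `"flat"` (default), `"stationary"`, or a probability
#'   vector of length `k`.
#' @param states Optional category labels fixing the state order; otherwise
#'   first-appearance order of `tip_states` (or `levels()` for a factor).
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "flat", states = NULL) {
  tree <- stats::reorder(tree, "postorder")
  k <- nrow(Q)
  if (any(abs(rowSums(Q)) > 1e-8) || any(Q[row(Q) != col(Q)] < 0))
    stop("Q rows must sum to 0 with nonnegative off-diagonals")
  ts <- tip_state_indices(tree, tip_states, states)
  if (length(ts$states) > k)
    stop("more observed categories than states in Q")
  prior <- resolve_root_prior(root_prior, Q, k)
  pm <- edge_pmats(Q, tree$edge.length)
  pr <- mk_pruning(tree, ts$idx, pm, k)
  root <- length(tree$tip.label) + 1L
  log(sum(prior * pr$L[root, ])) + pr$logscale
}

#' Marginal ancestral state likelihoods
#'
#' Two-pass (tipward then rootward) message passing giving, for every node,
#' the normalised marginal likelihood of each state given all tip data.
#' Works on non-dichotomous trees; on an unrooted tree stored with an
#' arbitrary basal multifurcation the marginals are invariant to the choice
#' of pruning root when the root prior is the stationary distribution of
#' `Q`.
#'
#' @inheritParams mk_loglik
#' @return Object of class `ancestral_likelihoods`: a `(n_tips + n_internal)
#'   x k` matrix, rows summing to 1, tip rows one-hot on the observed state.
#'   Attribute `"states"` carries the category labels.
#' @export
marginal_asr <- function(tree, tip_states, Q, root_prior = "flat",
                         states = NULL) {
  tree <- stats::reorder(tree, "postorder")
  k <- nrow(Q)
  ts <- tip_state_indices(tree, tip_states, states)
  prior <- resolve_root_prior(root_prior, Q, k)
  pm <- edge_pmats(Q, tree$edge.length)
  A <- marginal_asr_core(tree, ts$idx, pm, prior, k)
  dimnames(A) <- list(NULL, ts$states)
  structure(A, states = ts$states, ntip = length(tree$tip.label),
            class = c("ancestral_likelihoods", "matrix", "array"))
}

# two-pass marginals with precomputed per-edge transition matrices
#' @keywords internal
marginal_asr_core <- function(tree, tipidx, pm, prior, k) {
  pr <- mk_pruning(tree, tipidx, pm, k)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  D <- matrix(NA_real_, nnode, k)
  D[root, ] <- prior
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  for (e in rev(seq_len(nrow(tree$edge)))) {    # preorder
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    excl <- D[par, ]
    for (e2 in children[[as.character(par)]])
      if (e2 != e) excl <- excl * pr$msg[e2, ]
    d <- as.vector(excl %*% pm[[e]])            # sum over parent state
    m <- max(d)
    D[ch, ] <- if (m > 0) d / m else rep(1 / k, k)
  }
  A <- pr$L * D
  rs <- rowSums(A)
  bad <- rs <= 0 | !is.finite(rs)
  if (any(bad)) A[bad, ] <- 1 / k
  A / rowSums(A)
}

#' Assign each node its maximum marginal likelihood state
#'
#' Ties are broken toward the lowest state index with a warning.
#'
#' @param A An `ancestral_likelihoods` matrix (or any nodes x states matrix).
#' @return Factor of length `nrow(A)` over the state labels.
#' @export
max_state_assignment <- function(A) {
  states <- attr(A, "states") %||% colnames(A) %||% as.character(seq_len(ncol(A)))
  idx <- integer(nrow(A))
  tie <- FALSE
  for (i in seq_len(nrow(A))) {
    r <- A[i, ]
    j <- which(r >= max(r) - 1e-12)
    if (length(j) > 1L) tie <- TRUE
    idx[i] <- j[1L]
  }
  if (tie) warning("tie(s) in marginal likelihoods broken toward the lowest state index")
  factor(states[idx], levels = states)
}

#' Fit an Mk model of categorical trait evolution by maximum likelihood
#'
#' Estimates the free transition rates of `model` by bounded quasi-Newton
#' optimisation (L-BFGS-B) on log-rates with a deterministic three-point
#' multi-start (rates 0.1, 1 and 10 times the reciprocal tree height).
#'
#' @inheritParams mk_loglik
#' @param model A [rate_model()], or `"ER"`, `"SYM"`, `"ARD"`.
#' @param states Optional category labels; every listed category must be
#'   observed in at least one tip.
#' @param control Passed to [stats::optim()] (defaults set a 1e-8 relative
#'   tolerance on the log-likelihood).
#' @return Object of class `mk_fit` with the tree, tip states, rate model,
#'   fitted rates and `Q`, log-likelihood, convergence flag and optimiser
#'   diagnostics. Methods: `print`, `summary`, `coef`, `logLik`,
#'   `simulate`, `predict`, `plot`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
#' ph <- c(A = "x", B = "x", C = "y", D = "y")
#' fit <- fit_mk(tr, ph, "ER")
#' coef(fit)
#' @export
fit_mk <- function(tree, tip_states, model = "ER", root_prior = "flat",
                   states = NULL, control = list()) {
  tree <- stats::reorder(tree, "postorder")
  ts <- tip_state_indices(tree, tip_states, states)
  lev <- ts$states
  observed <- table(factor(lev[ts$idx], levels = lev))
  if (any(observed == 0))
    stop("category with zero observed tips: ",
         paste(names(observed)[observed == 0], collapse = ", "))
  if (sum(observed > 0) < 2)
    stop("need at least 2 categories observed among tips")
  if (!inherits(model, "rate_model")) model <- rate_model(model, k = length(lev))
  if (model$k != length(lev))
    stop("rate model has k = ", model$k, " but ", length(lev),
         " categories are observed")
  model$states <- lev
  k <- model$k
  np <- n_free_params(model)
  lens <- tree$edge.length
  h <- max(tree_height(tree), .Machine$double.eps)
  ctrl <- modifyList(list(factr = 1e6, maxit = 500), control)

  nll <- function(logr) {
    Q <- build_Q(exp(logr), model)
    prior <- resolve_root_prior(root_prior, Q, k)
    pm <- edge_pmats(Q, lens)
    pr <- mk_pruning(tree, ts$idx, pm, k)
    ll <- log(sum(prior * pr$L[length(tree$tip.label) + 1L, ])) + pr$logscale
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  for (r0 in c(0.1, 1, 10) / h) {
    o <- tryCatch(
      stats::optim(rep(log(r0), np), nll, method = "L-BFGS-B",
                   lower = rep(-25, np), upper = rep(25, np), control = ctrl),
      error = function(e) list(par = rep(log(r0), np), value = 1e10,
                               convergence = 99L, message = conditionMessage(e))
    )
    if (is.null(best) || o$value < best$value) best <- o
  }
  rates <- exp(best$par)
  Q <- build_Q(rates, model)
  prior <- resolve_root_prior(root_prior, Q, k)
  names(rates) <- free_rate_names(model)
  structure(list(
    tree = tree,
    tip_states = factor(lev[ts$idx], levels = lev),
    states = lev,
    model = model,
    rates = rates,
    Q = Q,
    loglik = -best$value,
    converged = isTRUE(best$convergence == 0) && best$value < 1e10,
    root_prior = root_prior,
    prior = prior,
    optim = best
  ), class = "mk_fit")
}

#' @keywords internal
free_rate_names <- function(model) {
  idx <- model$index
  lev <- model$states %||% as.character(seq_len(model$k))
  vapply(seq_len(n_free_params(model)), function(cl) {
    cell <- which(idx == cl, arr.ind = TRUE)[1L, ]
    paste0(lev[cell[1L]], "->", lev[cell[2L]])
  }, "")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk model fit (%s, k = %d): logLik = %.4f%s\n",
              x$model$name, x$model$k, x$loglik,
              if (x$converged) "" else " [NOT converged]"))
  cat("Rates:\n")
  print(signif(x$rates, 5))
  invisible(x)
}

#' @export
summary.mk_fit <- function(object, ...) {
  cat(sprintf("Mk model fit: rate model '%s', %d categories (%s)\n",
              object$model$name, object$model$k,
              paste(object$states, collapse = ", ")))
  cat(sprintf("logLik = %.4f on %d free rate(s); AIC = %.4f; converged: %s\n",
              object$loglik, n_free_params(object$model),
              2 * n_free_params(object$model) - 2 * object$loglik,
              object$converged))
  cat("Fitted Q (events per branch-length unit):\n")
  print(signif(object$Q, 5))
  cat(sprintf("Root prior: %s\n",
              if (is.numeric(object$root_prior)) "user-supplied"
              else object$root_prior))
  invisible(object)
}

#' @export
coef.mk_fit <- function(object, ...) object$rates

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = n_free_params(object$model),
            nobs = length(object$tip_states), class = "logLik")
}

#' @export
predict.mk_fit <- function(object, type = c("marginal", "states"), ...) {
  A <- marginal_asr(object$tree, stats::setNames(as.character(object$tip_states),
                                                 object$tree$tip.label),
                    object$Q, object$root_prior, states = object$states)
  if (match.arg(type) == "marginal") A else max_state_assignment(A)
}

#' @export
simulate.mk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            simulate_phenotype(object$tree, object$Q, object$prior),
            simplify = FALSE)
}

#' @export
plot.mk_fit <- function(x, ...) {
  A <- predict(x, "marginal")
  ntip <- length(x$tree$tip.label)
  ape::plot.phylo(x$tree, ...)
  ape::nodelabels(pie = A[(ntip + 1L):nrow(A), , drop = FALSE], cex = 0.5)
  ape::tiplabels(pch = 19, col = as.integer(x$tip_states) + 1L)
  invisible(x)
}

#' Likelihood-ratio comparison of two fitted rate models
#'
#' Automatically detects whether the simpler model is nested in the more
#' complex one. Nested: the statistic `2 (logL_complex - logL_simple)` is
#' referred to a chi-squared distribution with degrees of freedom equal to
#' the difference in free rate parameters. Non-nested: tip data are
#' resimulated under the simpler fit, both models are refit to each
#' replicate (single start at the generating rates, an approximation that
#' bounds runtime), and the p-value is the proportion of null statistics at
#' least as large as the observed one.
#'
#' @param fit_simple,fit_complex `mk_fit` objects on identical data.
#' @param n_montecarlo Replicates for the non-nested case.
#' @param seed Optional RNG seed for the Monte-Carlo path.
#' @return Object of class `mk_lrt`: fields `lr`, `df` (nested case),
#'   `p_value`, `nested`, `n_montecarlo`.
#' @export
likelihood_ratio_test <- function(fit_simple, fit_complex,
                                  n_montecarlo = 199, seed = NULL) {
  stopifnot(inherits(fit_simple, "mk_fit"), inherits(fit_complex, "mk_fit"))
  if (!isTRUE(all.equal(fit_simple$tree$edge, fit_complex$tree$edge)) ||
      !identical(as.character(fit_simple$tip_states),
                 as.character(fit_complex$tip_states)))
    stop("fits are not on identical tree and tip data")
  lr <- 2 * (fit_complex$loglik - fit_simple$loglik)
  nested <- is_nested(fit_simple$model, fit_complex$model)
  if (nested) {
    df <- n_free_params(fit_complex$model) - n_free_params(fit_simple$model)
    if (df <= 0) stop("nested comparison requires the complex model to have more free parameters")
    p <- stats::pchisq(max(lr, 0), df, lower.tail = FALSE)
    res <- list(lr = lr, df = df, p_value = p, nested = TRUE,
                n_montecarlo = NA_integer_)
  } else {
    if (!is.null(seed)) set.seed(seed)
    tree <- fit_simple$tree
    tips <- tree$tip.label
    null_lr <- numeric(n_montecarlo)
    for (r in seq_len(n_montecarlo)) {
      repeat {
        sim <- simulate_phenotype(tree, fit_simple$Q, fit_simple$prior)
        st <- stats::setNames(fit_simple$states[sim[seq_along(tips)]], tips)
        if (length(unique(st)) >= 2) break
      }
      f1 <- refit_at(fit_simple, st)
      f2 <- refit_at(fit_complex, st)
      null_lr[r] <- 2 * (f2 - f1)
    }
    p <- mean(null_lr >= lr)
    res <- list(lr = lr, df = NA_integer_, p_value = p, nested = FALSE,
                n_montecarlo = n_montecarlo)
  }
  structure(res, class = "mk_lrt")
}

# single-start refit used by the Monte-Carlo LRT; returns the log-likelihood
#' @keywords internal
refit_at <- function(fit, tip_states) {
  model <- fit$model
  tree <- fit$tree
  ts <- tip_state_indices(tree, tip_states, states = fit$states)
  np <- n_free_params(model)
  k <- model$k
  lens <- tree$edge.length
  nll <- function(logr) {
    Q <- build_Q(exp(logr), model)
    prior <- resolve_root_prior(fit$root_prior, Q, k)
    pr <- mk_pruning(tree, ts$idx, edge_pmats(Q, lens), k)
    ll <- log(sum(prior * pr$L[length(tree$tip.label) + 1L, ])) + pr$logscale
    if (!is.finite(ll)) 1e10 else -ll
  }
  start <- pmin(pmax(log(pmax(fit$rates, 1e-10)), -25), 25)
  o <- stats::optim(start, nll, method = "L-BFGS-B",
                    lower = rep(-25, np), upper = rep(25, np),
                    control = list(factr = 1e7, maxit = 200))
  -o$value
}

#' @export
print.mk_lrt <- function(x, ...) {
  if (x$nested)
    cat(sprintf("Likelihood ratio test (nested): LR = %.4f, df = %d, p = %.5g\n",
                x$lr, x$df, x$p_value))
  else
    cat(sprintf("Likelihood ratio test (non-nested, %d Monte-Carlo replicates): LR = %.4f, p = %.5g\n",
                x$n_montecarlo, x$lr, x$p_value))
  invisible(x)
}
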