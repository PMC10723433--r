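# Permulations: phylogenetically plausible null categorical phenotypes.
#
# A permulated phenotype is produced in three steps: (1) simulate the trait
# down the tree from the fitted Markov model and reject simulations whose
# extant per-category counts stray from the observed counts (exactly, or
# within a relaxation band); (2) discard the simulated internal states and
# permute the *originally reconstructed* internal states onto the internal
# nodes, weighted by the ancestral likelihoods computed from the simulated
# tips, so internal category counts are conserved exactly; (3) reorganise
# the internal states by a simulated-annealing swap search that can only
# exchange states between two nodes, driving the tree likelihood back up
# while leaving every category count untouched.

#' Permulation settings
#'
#' @param n_permulations Number of null phenotypes to generate (>= 1).
#' @param relaxation Fraction in `[0, 1)`: a simulated phenotype is accepted
#'   when every category's extant count is within
#'   `floor(relaxation * observed_count)` of the observed count. 0 (default)
#'   requires exact matches. Internal counts are always matched exactly.
#' @param T0,alpha Annealing temperature schedule `T_k = T0 / (1 + alpha k)`
#'   over cycles `k` (defaults 10 and 0.9).
#' @param n_cycles,iters_per_cycle Annealing effort (defaults 100 and 10,
#'   i.e. 1000 proposals per permulation).
#' @param max_attempts Rejection-sampler ceiling per permulation; exceeding
#'   it is an error suggesting a relaxation (default 1e6).
#' @param dh_scale `"log"` (default): the annealing penalty `dh` is the
#'   log-likelihood difference before minus after, so a neutral swap has
#'   acceptance probability 1. `"ratio"`: `dh` is the raw likelihood ratio.
#' @param seed Optional integer seed making the whole run reproducible.
#' @param batch Rejection-sampler batch size (vectorised simulation).
#' @return List of class `permulation_config`.
#' @export
permulation_config <- function(n_permulations = 100, relaxation = 0,
                               T0 = 10, alpha = 0.9, n_cycles = 100,
                               iters_per_cycle = 10, max_attempts = 1e6,
                               dh_scale = c("log", "ratio"), seed = NULL,
                               batch = 256) {
  stopifnot(n_permulations >= 1, relaxation >= 0, relaxation < 1,
            T0 > 0, n_cycles >= 1, iters_per_cycle >= 1, batch >= 1)
  structure(list(n_permulations = as.integer(n_permulations),
                 relaxation = relaxation, T0 = T0, alpha = alpha,
                 n_cycles = as.integer(n_cycles),
                 iters_per_cycle = as.integer(iters_per_cycle),
                 max_attempts = max_attempts,
                 dh_scale = match.arg(dh_scale), seed = seed,
                 batch = as.integer(batch)),
            class = "permulation_config")
}

#' Simulate a categorical phenotype down a tree
#'
#' Draws the root state from `root_prior` and each child state from the row
#' of `exp(Q t)` selected by its parent's state.
#'
#' @inheritParams mk_loglik
#' @return Integer vector of node states (1..k), tips first, in `phylo`
#'   node order. Attribute `"states"` carries labels when `Q` has dimnames.
#' @export
simulate_phenotype <- function(tree, Q, root_prior = "flat") {
  tree <- stats::reorder(tree, "postorder")
  k <- nrow(Q)
  prior <- resolve_root_prior(root_prior, Q, k)
  pmc <- lapply(edge_pmats(Q, tree$edge.length),
                function(P) t(apply(P, 1L, cumsum)))
  drop(simulate_batch(tree, pmc, prior, 1L))
}

# B simulations at once; returns B x nnode integer matrix
#' @keywords internal
simulate_batch <- function(tree, pm_cum, prior, B) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  k <- length(prior)
  s <- matrix(0L, B, nnode)
  s[, ntip + 1L] <- findInterval(stats::runif(B), cumsum(prior)) + 1L
  for (e in rev(seq_len(nrow(tree$edge)))) {   # preorder: parents first
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    cum <- pm_cum[[e]][s[, par], , drop = FALSE]
    u <- stats::runif(B)
    s[, ch] <- 1L + as.integer(rowSums(u > cum[, -k, drop = FALSE]))
  }
  s
}

#' Rejection rule on extant category counts
#'
#' Accepts a simulated tip assignment when every category count is within
#' `floor(relaxation * observed)` of the observed count (exact match at
#' relaxation 0). The band is floored, so a 10% relaxation leaves a
#' category of 5 with tolerance 0 but a category of 10 with tolerance 1.
#'
#' @param sim_tip_states Simulated tip states (factor, character or integer
#'   indices into the observed count names).
#' @param observed_counts Named integer vector of observed per-category tip
#'   counts.
#' @param relaxation Fraction in `[0, 1)`.
#' @return `TRUE`/`FALSE`.
#' @export
rejection_accept <- function(sim_tip_states, observed_counts, relaxation = 0) {
  lev <- names(observed_counts)
  cnt <- if (is.numeric(sim_tip_states))
    tabulate(sim_tip_states, nbins = length(lev))
  else as.integer(table(factor(as.character(sim_tip_states), levels = lev)))
  tol <- floor(relaxation * observed_counts)
  all(abs(cnt - observed_counts) <= tol)
}

#' Likelihood-weighted permutation of the original internal states
#'
#' Reassigns the originally reconstructed internal states to internal nodes
#' without replacement: nodes are visited in random order and each draws a
#' state from the remaining multiset with probability proportional to the
#' node's ancestral likelihood for that state (renormalised over the states
#' still available). Internal category counts therefore match the original
#' reconstruction exactly, every draw.
#'
#' @param original_internal_states Integer vector (1..k) of the original
#'   reconstruction's internal node states.
#' @param A_sim Internal-node rows of the ancestral likelihoods computed
#'   from the *simulated* tip states (matrix, same row count).
#' @return Integer vector of permuted internal states.
#' @export
permute_internal <- function(original_internal_states, A_sim) {
  ni <- length(original_internal_states)
  A <- as.matrix(A_sim)
  if (nrow(A) != ni)
    stop("A_sim must have one row per internal node")
  k <- ncol(A)
  rem <- tabulate(original_internal_states, nbins = k)
  out <- integer(ni)
  for (i in sample.int(ni)) {
    w <- A[i, ] * (rem > 0)
    if (sum(w) <= 0) w <- as.numeric(rem > 0)
    x <- sample.int(k, 1L, prob = w)
    out[i] <- x
    rem[x] <- rem[x] - 1L
  }
  out
}

#' Log-likelihood of a full node-state assignment
#'
#' Sum over edges of `log (e^{Q t})[x, y]` with `x` the ancestor and `y`
#' the descendant state; `-Inf` when any transition has probability zero.
#'
#' @inheritParams assign_edge_states
#' @param Q Rate matrix.
#' @param node_states Integer (1..k) or factor/character states for all
#'   nodes.
#' @return Log-likelihood (scalar, possibly `-Inf`).
#' @export
tree_log_likelihood <- function(tree, node_states, Q) {
  tree <- stats::reorder(tree, "postorder")
  s <- node_state_indices(node_states, nrow(Q), Q)
  logP <- lapply(edge_pmats(Q, tree$edge.length), function(P) log(P))
  tot <- 0
  for (e in seq_len(nrow(tree$edge)))
    tot <- tot + logP[[e]][s[tree$edge[e, 1L]], s[tree$edge[e, 2L]]]
  tot
}

#' @keywords internal
node_state_indices <- function(node_states, k, Q = NULL) {
  if (is.numeric(node_states)) return(as.integer(node_states))
  lev <- if (is.factor(node_states)) levels(node_states)
         else colnames(Q) %||% unique(as.character(node_states))
  m <- match(as.character(node_states), lev)
  if (anyNA(m)) stop("unknown state label in node_states")
  m
}

#' Simulated-annealing reorganisation of internal states
#'
#' Improves the likelihood of a constrained internal-state assignment by
#' proposing swaps between pairs of internal nodes. For node `i` in state
#' `y`, the preference ratio for another state `x` is `A[i, x] / A[i, y]`;
#' the first swap partner is drawn with probability proportional to these
#' ratios (restricted to ratios above 1 when any exist), the second among
#' nodes currently in the target state likewise. A swap that improves the
#' likelihood is kept; otherwise it is kept with probability
#' `u = exp(-dh / T_k)`, with the temperature `T_k = T0 / (1 + alpha k)`
#' decreasing each cycle. Every swap exchanges two nodes' states, so
#' category counts are invariant.
#'
#' @param tree `phylo`.
#' @param node_states Full node-state vector (integer 1..k); tip entries are
#'   never modified.
#' @param Q Rate matrix.
#' @param A Ancestral likelihood matrix for all nodes (internal rows used).
#' @param config A [permulation_config()] (schedule fields used).
#' @return List: `node_states` (reorganised), `log_likelihood`,
#'   `initial_log_likelihood`, `swaps_accepted`, `proposals`, `skipped`.
#' @export
anneal_reorganize <- function(tree, node_states, Q, A,
                              config = permulation_config()) {
  tree <- stats::reorder(tree, "postorder")
  k <- nrow(Q)
  s <- node_state_indices(node_states, k, Q)
  logP <- lapply(edge_pmats(Q, tree$edge.length), function(P) log(P))
  anneal_core(tree, s, logP, as.matrix(A), config)
}

#' @keywords internal
anneal_core <- function(tree, s, logP, A, config) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ni <- nnode - ntip
  k <- ncol(A)
  edge <- tree$edge
  # incident edges per node
  inc <- vector("list", nnode)
  for (e in seq_len(nrow(edge))) {
    inc[[edge[e, 1L]]] <- c(inc[[edge[e, 1L]]], e)
    inc[[edge[e, 2L]]] <- c(inc[[edge[e, 2L]]], e)
  }
  edge_ll <- function(E, st) {
    tot <- 0
    for (e in E) tot <- tot + logP[[e]][st[edge[e, 1L]], st[edge[e, 2L]]]
    tot
  }
  cur_ll <- edge_ll(seq_len(nrow(edge)), s)
  init_ll <- cur_ll

  Ai <- pmax(A[(ntip + 1L):nnode, , drop = FALSE], 1e-12)
  s_int <- s[(ntip + 1L):nnode]
  ratio <- Ai / Ai[cbind(seq_len(ni), s_int)]
  ratio[cbind(seq_len(ni), s_int)] <- NA_real_

  accepted <- 0L; proposals <- 0L; skipped <- 0L
  for (cyc in seq_len(config$n_cycles)) {
    Tk <- config$T0 / (1 + config$alpha * (cyc - 1L))
    for (it in seq_len(config$iters_per_cycle)) {
      proposals <- proposals + 1L
      cand <- which(!is.na(ratio))
      w <- ratio[cand]
      hi <- w > 1
      if (any(hi)) { cand <- cand[hi]; w <- w[hi] } else w <- rep(1, length(cand))
      pick <- cand[sample.int(length(cand), 1L, prob = w)]
      i <- ((pick - 1L) %% ni) + 1L
      x <- ((pick - 1L) %/% ni) + 1L
      y <- s_int[i]
      js <- which(s_int == x)
      js <- js[js != i]
      if (!length(js)) { skipped <- skipped + 1L; next }
      w2 <- ratio[cbind(js, rep(y, length(js)))]
      hi2 <- w2 > 1
      if (any(hi2)) { js <- js[hi2]; w2 <- w2[hi2] } else w2 <- rep(1, length(js))
      j <- js[if (length(js) == 1L) 1L else sample.int(length(js), 1L, prob = w2)]

      gi <- ntip + i; gj <- ntip + j
      E <- unique(c(inc[[gi]], inc[[gj]]))
      before <- edge_ll(E, s)
      s2 <- s; s2[gi] <- x; s2[gj] <- y
      after <- edge_ll(E, s2)
      dh <- before - after
      keep <- if (!is.finite(before) && !is.finite(after)) TRUE
              else if (dh <= 0) TRUE
              else {
        u <- if (config$dh_scale == "log") exp(-dh / Tk)
             else exp(-exp(min(dh, 700)) / Tk)
        stats::runif(1) < u
      }
      if (keep) {
        s <- s2
        s_int[i] <- x; s_int[j] <- y
        cur_ll <- cur_ll + (after - before)
        accepted <- accepted + 1L
        for (n2 in c(i, j)) {
          ratio[n2, ] <- Ai[n2, ] / Ai[n2, s_int[n2]]
          ratio[n2, s_int[n2]] <- NA_real_
        }
      }
    }
  }
  list(node_states = s, log_likelihood = cur_ll,
       initial_log_likelihood = init_ll,
       swaps_accepted = accepted, proposals = proposals, skipped = skipped)
}

#' Generate permulated null phenotypes (complete-case method)
#'
#' Runs the three-step permulation pipeline (rejection-sampled Markov
#' simulation, likelihood-weighted internal permutation, annealing
#' reorganisation) `n_permulations` times against a fitted Mk model. Every
#' output matches the original internal category counts exactly and the
#' extant counts within the relaxation band.
#'
#' @param fit An [fit_mk()] object (tree, Q, tip states, root prior).
#' @param reconstruction Node-state assignment of the observed data
#'   (factor/integer over all nodes); defaults to the maximum marginal
#'   likelihood assignment from `fit`.
#' @param config A [permulation_config()].
#' @return Object of class `permulation_set`: list with `phenotypes` (each
#'   with `tip_states`, `internal_states`, `log_likelihood`,
#'   `sim_log_likelihood`, `step2_log_likelihood`, `attempts`,
#'   `swaps_accepted`), plus `states`, `config`, `tree`, `Q`.
#' @export
permulate <- function(fit, reconstruction = NULL,
                      config = permulation_config()) {
  stopifnot(inherits(fit, "mk_fit"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  k <- nrow(fit$Q)
  lev <- fit$states
  if (is.null(reconstruction))
    reconstruction <- max_state_assignment(
      marginal_asr(tree, stats::setNames(as.character(fit$tip_states),
                                         tree$tip.label),
                   fit$Q, fit$root_prior, states = lev))
  rec <- node_state_indices(reconstruction, k, fit$Q)
  if (length(rec) != nnode) stop("reconstruction must cover all nodes")
  orig_internal <- rec[(ntip + 1L):nnode]
  obs_counts <- table(factor(as.character(fit$tip_states), levels = lev))
  obs_counts <- stats::setNames(as.integer(obs_counts), lev)

  pm <- edge_pmats(fit$Q, tree$edge.length)
  pm_cum <- lapply(pm, function(P) t(apply(P, 1L, cumsum)))
  logP <- lapply(pm, log)
  prior <- fit$prior
  tol <- floor(config$relaxation * obs_counts)

  out <- vector("list", config$n_permulations)
  for (p in seq_len(config$n_permulations)) {
    attempts <- 0L
    sim <- NULL
    while (is.null(sim)) {
      B <- min(config$batch, max(1, config$max_attempts - attempts))
      batch <- simulate_batch(tree, pm_cum, prior, B)
      cnts <- matrix(0L, B, k)
      for (c_ in seq_len(k))
        cnts[, c_] <- rowSums(batch[, seq_len(ntip), drop = FALSE] == c_)
      ok <- rowSums(abs(cnts - rep(obs_counts, each = B)) >
                      rep(tol, each = B)) == 0
      hit <- which(ok)
      if (length(hit)) {
        attempts <- attempts + hit[1L]
        sim <- batch[hit[1L], ]
      } else {
        attempts <- attempts + B
        if (attempts >= config$max_attempts)
          stop("rejection sampler exceeded ", config$max_attempts,
               " attempts; consider a relaxation > 0")
      }
    }
    sim_ll <- 0
    for (e in seq_len(nrow(tree$edge)))
      sim_ll <- sim_ll + logP[[e]][sim[tree$edge[e, 1L]], sim[tree$edge[e, 2L]]]
    A_sim <- marginal_asr_core(tree, sim[seq_len(ntip)], pm, prior, k)
    internal0 <- permute_internal(orig_internal,
                                  A_sim[(ntip + 1L):nnode, , drop = FALSE])
    s0 <- c(sim[seq_len(ntip)], internal0)
    ann <- anneal_core(tree, s0, logP, A_sim, config)
    out[[p]] <- list(
      tip_states = factor(lev[sim[seq_len(ntip)]], levels = lev),
      internal_states = factor(lev[ann$node_states[(ntip + 1L):nnode]],
                               levels = lev),
      log_likelihood = ann$log_likelihood,
      sim_log_likelihood = sim_ll,
      step2_log_likelihood = ann$initial_log_likelihood,
      attempts = attempts,
      swaps_accepted = ann$swaps_accepted
    )
  }
  structure(list(phenotypes = out, states = lev, config = config,
                 tree = tree, Q = fit$Q), class = "permulation_set")
}

#' @export
print.permulation_set <- function(x, ...) {
  att <- vapply(x$phenotypes, `[[`, 0, "attempts")
  cat(sprintf(
    "Permulation set: %d null phenotypes (relaxation %.2f), median %d simulation attempts each\n",
    length(x$phenotypes), x$config$relaxation, as.integer(stats::median(att))))
  invisible(x)
}

#' Empirical p-values from permulation null statistics
#'
#' One-sided (omnibus): `p = (#\{null >= obs\} + 1) / (N + 1)`; two-sided
#' (pairwise): the same rule on absolute values. The add-one estimator
#' never returns 0; `estimator = "proportion"` gives the plain proportion.
#'
#' @param observed Named numeric vector of observed statistics (NA gives NA).
#' @param nulls Matrix of null statistics, `N` permulations x genes
#'   (columns aligned with `observed`, checked by name when present).
#' @param sided `"one"` or `"two"`.
#' @param estimator `"add_one"` (default) or `"proportion"`.
#' @return Numeric vector of empirical p-values.
#' @export
empirical_pvalues <- function(observed, nulls, sided = c("one", "two"),
                              estimator = c("add_one", "proportion")) {
  sided <- match.arg(sided)
  estimator <- match.arg(estimator)
  nulls <- as.matrix(nulls)
  if (length(observed) != ncol(nulls))
    stop("observed length does not match null statistic columns")
  if (!is.null(names(observed)) && !is.null(colnames(nulls)) &&
      !identical(names(observed), colnames(nulls)))
    stop("gene id mismatch between observed and nulls")
  if (sided == "two") {
    observed <- abs(observed)
    nulls <- abs(nulls)
  }
  b <- colSums(sweep(nulls, 2L, observed, ">="), na.rm = TRUE)
  N <- colSums(!is.na(nulls))
  p <- if (estimator == "add_one") (b + 1) / (N + 1) else b / N
  p[is.na(observed) | N == 0] <- NA_real_
  stats::setNames(p, names(observed))
}

#' Permulation-corrected gene p-values
#'
#' Reruns the association tests on each permulated phenotype's edge states
#' (reusing the observed RER matrix, per the complete-case design) and
#' converts the null statistics into empirical p-values: one-sided on the
#' omnibus statistic, two-sided on the pairwise statistics.
#'
#' @param observed An `rer_association` from [associate_genes()] on the
#'   observed edge states.
#' @param rers The same RER matrix.
#' @param perm_set A [permulate()] result on the same tree.
#' @param estimator Passed to [empirical_pvalues()].
#' @param branch_subset As in [associate_genes()] (must match the observed
#'   call).
#' @return Object of class `rer_permtest`: `omnibus` and `pairwise` data
#'   frames with a `perm_p` column added, plus `nulls` (the null statistic
#'   and parametric-p matrices, permulations x genes) for enrichment reuse.
#' @export
permulation_pvalues <- function(observed, rers, perm_set,
                                estimator = c("add_one", "proportion"),
                                branch_subset = NULL) {
  stopifnot(inherits(observed, "rer_association"),
            inherits(perm_set, "permulation_set"))
  estimator <- match.arg(estimator)
  tree <- perm_set$tree
  lev <- observed$levels
  X <- as.matrix(rers)
  if (!is.null(branch_subset)) X <- X[, branch_subset, drop = FALSE]
  prep <- assoc_prepare(X)
  genes <- prep$genes
  P <- length(perm_set$phenotypes)
  npair <- length(lev) * (length(lev) - 1) / 2

  null_stat <- matrix(NA_real_, P, length(genes), dimnames = list(NULL, genes))
  null_p <- null_stat
  null_pw_stat <- replicate(npair, null_stat, simplify = FALSE)
  null_pw_p <- replicate(npair, null_stat, simplify = FALSE)

  for (i in seq_len(P)) {
    ph <- perm_set$phenotypes[[i]]
    ns <- factor(c(as.character(ph$tip_states),
                   as.character(ph$internal_states)), levels = lev)
    es <- assign_edge_states(tree, ns)
    if (!is.null(branch_subset)) es <- es[branch_subset]
    G <- group_indicator(es, lev)
    if (observed$method == "kruskal") {
      kw <- kw_engine(prep, G)
      dn <- dunn_engine(prep, G, kw)
      null_stat[i, ] <- kw$H; null_p[i, ] <- kw$p
      for (j in seq_len(npair)) {
        null_pw_stat[[j]][i, ] <- dn$Z[, j]
        null_pw_p[[j]][i, ] <- dn$p[, j]
      }
      pairs <- dn$pairs
    } else {
      an <- anova_engine(prep, G)
      tk <- tukey_engine(prep, G, an)
      null_stat[i, ] <- an$F; null_p[i, ] <- an$p
      for (j in seq_len(npair)) {
        null_pw_stat[[j]][i, ] <- tk$diff[, j]
        null_pw_p[[j]][i, ] <- tk$p[, j]
      }
      pairs <- tk$pairs
    }
  }

  omnibus <- observed$omnibus
  obs_stat <- stats::setNames(omnibus$statistic, omnibus$gene)
  omnibus$perm_p <- empirical_pvalues(obs_stat, null_stat, "one", estimator)

  pairwise <- observed$pairwise
  pairwise$perm_p <- NA_real_
  for (j in seq_len(npair)) {
    a <- lev[pairs[j, 1L]]; b <- lev[pairs[j, 2L]]
    sel <- pairwise$group1 == a & pairwise$group2 == b
    obs_j <- stats::setNames(pairwise$statistic[sel], pairwise$gene[sel])
    pairwise$perm_p[sel] <- empirical_pvalues(obs_j, null_pw_stat[[j]],
                                              "two", estimator)
  }
  structure(list(omnibus = omnibus, pairwise = pairwise, levels = lev,
                 method = observed$method,
                 nulls = list(omnibus_stat = null_stat, omnibus_p = null_p,
                              pairwise_stat = null_pw_stat,
                              pairwise_p = null_pw_p, pairs = pairs)),
            class = "rer_permtest")
}

#' @export
print.rer_permtest <- function(x, ...) {
  cat(sprintf("Permulation-corrected association (%s): %d genes, %d permulations\n",
              x$method, ncol(x$nulls$omnibus_stat), nrow(x$nulls$omnibus_stat)))
  invisible(x)
}
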