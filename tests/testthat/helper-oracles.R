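# Independent oracles and small fixtures shared across tests. The oracles
# deliberately avoid the package's own pruning/engine code paths:
# likelihoods come from exhaustive enumeration over internal states with
# transition matrices from Matrix::expm, and rank statistics from textbook
# formulas on explicitly computed ranks.

# exp(Q t) straight from Matrix::expm (no eigen shortcut, no caching)
oracle_pmat <- function(Q, t) {
  if (t == 0) return(diag(nrow(Q)))
  as.matrix(Matrix::expm(Q * t))
}

# Joint probability of a full node-state assignment
oracle_joint <- function(tree, states, Q, prior) {
  tree <- reorder(tree, "postorder")
  p <- prior[states[length(tree$tip.label) + 1L]]
  for (e in seq_len(nrow(tree$edge))) {
    P <- oracle_pmat(Q, tree$edge.length[e])
    p <- p * P[states[tree$edge[e, 1L]], states[tree$edge[e, 2L]]]
  }
  p
}

# Likelihood of tip data by exhaustive enumeration of internal states
oracle_loglik <- function(tree, tipidx, Q, prior) {
  ntip <- length(tree$tip.label)
  ni <- tree$Nnode
  k <- nrow(Q)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), ni)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    tot <- tot + oracle_joint(tree, c(tipidx, grid[g, ]), Q, prior)
  }
  log(tot)
}

# Marginal state probabilities at every node by enumeration
oracle_marginals <- function(tree, tipidx, Q, prior) {
  ntip <- length(tree$tip.label)
  ni <- tree$Nnode
  k <- nrow(Q)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), ni)))
  M <- matrix(0, ntip + ni, k)
  for (g in seq_len(nrow(grid))) {
    s <- c(tipidx, grid[g, ])
    w <- oracle_joint(tree, s, Q, prior)
    for (v in seq_along(s)) M[v, s[v]] <- M[v, s[v]] + w
  }
  M / rowSums(M)
}

# Random tree of n tips, optionally with polytomies (collapse short internal
# edges), branch lengths ~ Exp(2)
random_test_tree <- function(n, polytomies = FALSE) {
  tr <- ape::rtree(n)
  tr$edge.length <- rexp(nrow(tr$edge), 2)
  if (polytomies && n >= 4) {
    internal <- which(tr$edge[, 2L] > n)
    drop <- internal[runif(length(internal)) < 0.4]
    if (length(drop)) {
      tr$edge.length[drop] <- 0
      tr <- ape::di2multi(tr, tol = 1e-12)
      tr$edge.length <- rexp(nrow(tr$edge), 2)
    }
  }
  reorder(tr, "postorder")
}

# Random valid rate matrix for k states
random_Q <- function(k, max_rate = 2) {
  Q <- matrix(runif(k * k, 0.05, max_rate), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Small reference experiment reused by several association tests
small_experiment <- function(seed = 42, n_genes = 200, n_tips = 25) {
  spec <- synthetic_spec(n_tips = n_tips, n_genes = n_genes,
                         fraction_shifted = 0.1, effect_size = 2,
                         missing_rate = 0.05, seed = seed)
  gen_experiment(spec)
}
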