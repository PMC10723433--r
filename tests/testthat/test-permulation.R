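test_that("rejection rule uses a floored per-category band", {
  obs <- c(a = 10, b = 10, c = 5)
  expect_true(rejection_accept(rep(c("a", "b", "c"), c(10, 10, 5)), obs, 0))
  expect_false(rejection_accept(rep(c("a", "b", "c"), c(11, 9, 5)), obs, 0))
  # categories of 10 off by one pass at 10% (floor(1.0) = 1) ...
  expect_true(rejection_accept(rep(c("a", "b", "c"), c(11, 9, 5)), obs, 0.10))
  # ... but a category of 5 off by one does not (floor(0.5) = 0)
  expect_false(rejection_accept(rep(c("a", "b", "c"), c(10, 9, 6)), obs, 0.10))
  # integer state indices are accepted too
  expect_true(rejection_accept(rep(1:3, c(10, 10, 5)), obs, 0))
})

test_that("phenotype simulation follows the Markov model", {
  # zero-length tree: every node inherits the root draw
  tr0 <- read_newick(text = "((A:0,B:0):0,C:0);")
  Q <- random_Q(3)
  set.seed(1)
  for (i in 1:20) {
    s <- simulate_phenotype(tr0, Q)
    expect_equal(length(unique(s)), 1L)
  }

  # single-edge transition frequencies match the matrix exponential row
  tr1 <- read_newick(text = "(A:0.7);")
  Qe <- build_Q(c(0.9, 0.3), rate_model(matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE)))
  P <- oracle_pmat(Qe, 0.7)
  set.seed(2)
  draws <- replicate(10000, simulate_phenotype(tr1, Qe, c(1, 0))[1])
  phat <- mean(draws == 2)
  se <- sqrt(P[1, 2] * (1 - P[1, 2]) / 10000)
  expect_lt(abs(phat - P[1, 2]), 4 * se)

  # long-branch star tree under ER: tip frequencies reach the stationary 1/k
  star <- read_newick(text = "(A:50,B:50,C:50,D:50,E:50);")
  Qs <- build_Q(0.5, rate_model("ER", 3))
  set.seed(3)
  tips <- replicate(2000, simulate_phenotype(star, Qs)[1:5])
  cnt <- tabulate(tips, 3)
  expect_gt(chisq.test(cnt)$p.value, 0.001)
})

test_that("internal permutation conserves counts and respects flat weights", {
  set.seed(4)
  # one internal node gets the single original state
  expect_equal(permute_internal(2L, matrix(c(0.2, 0.5, 0.3), 1)), 2L)

  # counts conserved for arbitrary weights
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    ni <- sample(3:10, 1)
    orig <- sample(seq_len(k), ni, replace = TRUE)
    A <- matrix(runif(ni * k), ni, k)
    out <- permute_internal(orig, A)
    expect_equal(tabulate(out, k), tabulate(orig, k))
  }

  # flat weights give a uniform permutation of a 3-state multiset
  orig <- 1:3
  A <- matrix(1 / 3, 3, 3)
  draws <- replicate(10000, paste(permute_internal(orig, A), collapse = ""))
  tab <- table(draws)
  expect_equal(length(tab), 6L)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("tree_log_likelihood is the sum of per-edge log transition terms", {
  tr <- read_newick(text = "((A:0.3,B:0.9):0.2,(C:0.5,D:0.1):0.4);")
  Q <- random_Q(2)
  ns <- c(1L, 2L, 1L, 1L, 2L, 1L, 2L)
  ll <- tree_log_likelihood(tr, ns, Q)
  tr_po <- reorder(tr, "postorder")
  manual <- 0
  for (e in seq_len(nrow(tr_po$edge))) {
    P <- oracle_pmat(Q, tr_po$edge.length[e])
    manual <- manual + log(P[ns[tr_po$edge[e, 1L]], ns[tr_po$edge[e, 2L]]])
  }
  expect_equal(ll, manual, tolerance = 1e-12)

  # single edge
  tr1 <- read_newick(text = "(A:1.2);")
  expect_equal(tree_log_likelihood(tr1, c(2L, 1L), Q),
               log(oracle_pmat(Q, 1.2)[1, 2]), tolerance = 1e-12)

  # zero-length constant tree has likelihood one
  tr0 <- read_newick(text = "((A:0,B:0):0,C:0);")
  expect_equal(tree_log_likelihood(tr0, rep(1L, 5), Q), 0)

  # a forbidden transition yields -Inf
  Qf <- build_Q(0.5, rate_model(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)))
  expect_identical(tree_log_likelihood(tr1, c(1L, 2L), Qf), -Inf)
})

test_that("annealing preserves category counts and raises the likelihood", {
  set.seed(5)
  finals <- c(); inits <- c()
  for (rep in 1:20) {
    tr <- random_test_tree(15)
    k <- 3
    Q <- build_Q(c(0.4, 0.7, 0.3), rate_model("SYM", k))
    s <- simulate_phenotype(tr, Q)
    ph <- setNames(paste0("s", s[1:15]), tr$tip.label)
    A <- marginal_asr(tr, ph, Q, states = paste0("s", 1:k))
    # scramble the internal states (count-preserving permutation)
    ntip <- 15
    nnode <- ntip + tr$Nnode
    scram <- s
    scram[(ntip + 1):nnode] <- sample(s[(ntip + 1):nnode])
    res <- anneal_reorganize(tr, scram, Q, unclass(A),
                             permulation_config(n_cycles = 30))
    expect_equal(tabulate(res$node_states[(ntip + 1):nnode], k),
                 tabulate(s[(ntip + 1):nnode], k))
    expect_equal(res$node_states[1:ntip], s[1:ntip])  # tips untouched
    finals <- c(finals, res$log_likelihood)
    inits <- c(inits, res$initial_log_likelihood)
    # the reported likelihood is consistent with a fresh evaluation
    expect_equal(res$log_likelihood,
                 tree_log_likelihood(tr, res$node_states, Q),
                 tolerance = 1e-9)
  }
  expect_gte(median(finals), median(inits))
})

test_that("permulations conserve counts and are seed-reproducible", {
  set.seed(6)
  tr <- ape::rphylo(20, 1, 0)
  tr$tip.label <- paste0("t", 1:20)
  Q <- build_Q(0.5, rate_model("ER", 2))
  repeat {
    s <- simulate_phenotype(tr, Q)
    if (min(tabulate(s[1:20], 2)) >= 5) break
  }
  ph <- setNames(c("x", "y")[s[1:20]], tr$tip.label)
  fit <- fit_mk(tr, ph, "ER")
  rec <- suppressWarnings(predict(fit, "states"))

  cfg <- permulation_config(n_permulations = 100, seed = 11)
  ps <- permulate(fit, rec, cfg)
  expect_length(ps$phenotypes, 100L)
  obs_tip <- table(factor(ph, levels = fit$states))
  obs_int <- table(factor(as.character(rec[21:39]), levels = fit$states))
  for (p in ps$phenotypes) {
    expect_equal(as.vector(table(p$tip_states)), as.vector(obs_tip))
    expect_equal(as.vector(table(p$internal_states)), as.vector(obs_int))
    expect_true(is.finite(p$log_likelihood))
    expect_gte(p$attempts, 1)
  }
  # same seed, byte-identical output
  ps2 <- permulate(fit, rec, cfg)
  expect_identical(ps, ps2)
})

test_that("relaxed permulations stay inside the band, internal counts exact", {
  set.seed(7)
  tr <- ape::rphylo(24, 1, 0)
  tr$tip.label <- paste0("t", 1:24)
  Q <- build_Q(0.6, rate_model("ER", 3))
  repeat {
    s <- simulate_phenotype(tr, Q)
    if (min(tabulate(s[1:24], 3)) >= 4) break
  }
  ph <- setNames(paste0("c", s[1:24]), tr$tip.label)
  fit <- fit_mk(tr, ph, "ER")
  rec <- suppressWarnings(predict(fit, "states"))
  cfg <- permulation_config(n_permulations = 50, relaxation = 0.2, seed = 3)
  ps <- permulate(fit, rec, cfg)
  obs_tip <- as.vector(table(factor(ph, levels = fit$states)))
  tol <- floor(0.2 * obs_tip)
  obs_int <- as.vector(table(factor(as.character(rec[25:47]), levels = fit$states)))
  for (p in ps$phenotypes) {
    expect_true(all(abs(as.vector(table(p$tip_states)) - obs_tip) <= tol))
    expect_equal(as.vector(table(p$internal_states)), obs_int)
  }
})

test_that("empirical p-values follow the add-one rule", {
  nulls <- matrix(rep(1:100, 2), 100, 2)
  colnames(nulls) <- c("g1", "g2")
  obs <- c(g1 = 1000, g2 = 50)
  p <- empirical_pvalues(obs, nulls, "one")
  expect_equal(unname(p["g1"]), 1 / 101)
  expect_equal(unname(p["g2"]), (51 + 1) / 101)   # 51 nulls >= 50

  # two-sided uses absolute values
  p2 <- empirical_pvalues(c(g1 = -1000, g2 = 0), nulls, "two")
  expect_equal(unname(p2["g1"]), 1 / 101)
  expect_equal(unname(p2["g2"]), 1)

  # plain-proportion estimator can reach zero
  p3 <- empirical_pvalues(obs, nulls, "one", estimator = "proportion")
  expect_equal(unname(p3["g1"]), 0)

  # NA observed propagates, mismatched ids are fatal
  pna <- empirical_pvalues(c(g1 = NA, g2 = 50), nulls, "one")
  expect_true(is.na(pna["g1"]))
  expect_error(empirical_pvalues(c(a = 1, b = 2), nulls), "mismatch")
})

test_that("permulation p-values are wired through the association engine", {
  exp_ <- small_experiment(seed = 31, n_genes = 60, n_tips = 20)
  ph <- exp_$phenotype$tip_states
  fit <- fit_mk(exp_$tree, ph, "ER")
  assoc <- associate_genes(exp_$rers, exp_$edge_states)
  ps <- permulate(fit, config = permulation_config(20, seed = 5))
  pt <- permulation_pvalues(assoc, exp_$rers, ps)
  expect_equal(nrow(pt$omnibus), 60L)
  ok <- !is.na(pt$omnibus$p_value)
  expect_true(all(pt$omnibus$perm_p[ok] > 0 & pt$omnibus$perm_p[ok] <= 1))
  expect_true(all(is.na(pt$omnibus$perm_p[!ok])))
  expect_true(all(pt$pairwise$perm_p[!is.na(pt$pairwise$p_value)] > 0))
  expect_equal(dim(pt$nulls$omnibus_stat), c(20L, 60L))
})
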