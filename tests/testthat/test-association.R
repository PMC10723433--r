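test_that("Kruskal-Wallis matches the hand-computed two-group fixture", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(res$epsilon_squared, res$statistic / 5, tolerance = 1e-12)

  # identical multisets give H = 0, epsilon^2 = 0
  res0 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$epsilon_squared, 0, tolerance = 1e-12)

  expect_error(kruskal_wallis(c(1, 2, 3), c("a", "a", "a")), "one group")
  expect_error(kruskal_wallis(c(1, 2), c("a", "b")), "fewer than 3")
})

test_that("Kruskal-Wallis agrees with stats::kruskal.test, ties included", {
  set.seed(50)
  for (rep in 1:30) {
    n <- sample(8:30, 1)
    k <- sample(2:4, 1)
    v <- sample(1:6, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0, 0.5)
    g <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(g)) < 2) next
    res <- kruskal_wallis(v, g)
    ref <- kruskal.test(v, factor(g))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    expect_gte(res$epsilon_squared, 0)
    expect_lte(res$epsilon_squared, 1)
  }
})

test_that("Dunn Z matches hand rank arithmetic on a 9-point fixture", {
  v <- c(1, 2, 3, 101, 102, 103, 4, 5, 6)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  dn <- dunn_pairwise(v, g)
  # mean ranks 2, 8, 5; no ties so sigma^2 = n(n+1)/12 = 7.5
  se <- sqrt(7.5 * (1 / 3 + 1 / 3))
  expect_equal(dn$Z[dn$group1 == "g1" & dn$group2 == "g2"], (2 - 8) / se,
               tolerance = 1e-12)
  expect_equal(dn$Z[dn$group1 == "g1" & dn$group2 == "g3"], (2 - 5) / se,
               tolerance = 1e-12)
  expect_equal(dn$Z[dn$group1 == "g2" & dn$group2 == "g3"], (8 - 5) / se,
               tolerance = 1e-12)
  # group 2 ranks above both others
  expect_true(all(dn$Z[dn$group2 == "g2"] < 0 | dn$group1 == "g2"))
  expect_true(all(dn$Z[dn$group1 == "g2"] > 0))

  # identical groups: Z = 0, adjusted p = 1
  dn0 <- dunn_pairwise(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(dn0$Z, 0)
  expect_equal(dn0$p_adjusted, 1)
})

test_that("ANOVA and Tukey agree with aov/TukeyHSD", {
  set.seed(60)
  for (rep in 1:15) {
    n <- sample(12:30, 1)
    k <- sample(2:4, 1)
    v <- rnorm(n)
    g <- factor(sample(letters[1:k], n, replace = TRUE))
    if (any(table(g) < 2)) next
    res <- anova_tukey(v, g)
    fit <- aov(v ~ g)
    sm <- summary(fit)[[1]]
    expect_equal(res$statistic, sm$`F value`[1], tolerance = 1e-8)
    expect_equal(res$p_value, sm$`Pr(>F)`[1], tolerance = 1e-8)
    expect_equal(res$eta_squared,
                 sm$`Sum Sq`[1] / sum(sm$`Sum Sq`), tolerance = 1e-8)
    th <- TukeyHSD(fit)$g
    for (i in seq_len(nrow(res$tukey))) {
      key1 <- paste0(res$tukey$group2[i], "-", res$tukey$group1[i])
      key2 <- paste0(res$tukey$group1[i], "-", res$tukey$group2[i])
      row <- if (key1 %in% rownames(th)) th[key1, ] else th[key2, ]
      expect_equal(res$tukey$p_adjusted[i], unname(row["p adj"]),
                   tolerance = 1e-6)
      expect_equal(abs(res$tukey$diff[i]), abs(unname(row["diff"])),
                   tolerance = 1e-8)
    }
  }
})

test_that("eta squared follows its sums-of-squares definition", {
  v <- c(1, 2, 6, 7, 3, 5)
  g <- rep(c("a", "b", "c"), each = 2)
  res <- anova_tukey(v, g)
  gm <- mean(v)
  ssb <- 2 * sum((tapply(v, g, mean) - gm)^2)
  sst <- sum((v - gm)^2)
  expect_equal(res$eta_squared, ssb / sst, tolerance = 1e-12)

  # exactly equal group means: F = 0, eta^2 = 0
  res0 <- anova_tukey(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$eta_squared, 0, tolerance = 1e-12)

  # zero within-group variance: eta^2 = 1 and p undefined
  resd <- anova_tukey(c(0, 0, 1, 1, 2, 2), rep(c("a", "b", "c"), each = 2))
  expect_equal(resd$eta_squared, 1, tolerance = 1e-12)
  expect_true(resd$degenerate)
  expect_true(is.na(resd$p_value))
})

test_that("associate_genes screens genes and preserves exchangeability", {
  set.seed(70)
  nb <- 30
  es <- factor(sample(c("a", "b", "c"), nb, replace = TRUE))
  names(es) <- as.character(seq_len(nb))
  X <- matrix(rnorm(5 * nb), 5, nb,
              dimnames = list(paste0("g", 1:5), names(es)))
  X[2, ] <- NA                      # all-masked gene
  X[3, seq_len(nb - 4)] <- NA       # too few branches
  res <- associate_genes(X, es)
  expect_equal(res$omnibus$reason[2], "insufficient data")
  expect_true(is.na(res$omnibus$p_value[2]))
  expect_equal(res$omnibus$reason[3], "insufficient data")
  expect_false(is.na(res$omnibus$p_value[1]))
  expect_equal(nrow(res$pairwise), 5 * 3)

  # permuting branches within a category leaves every statistic unchanged
  perm <- unlist(lapply(levels(es), function(l) sample(which(es == l))))
  X2 <- X[, perm]; es2 <- es[perm]
  colnames(X2) <- names(es2) <- as.character(seq_len(nb))
  res2 <- associate_genes(X2, es2)
  expect_equal(res2$omnibus$statistic, res$omnibus$statistic, tolerance = 1e-12)
  expect_equal(res2$pairwise$statistic, res$pairwise$statistic, tolerance = 1e-12)

  # ordering mismatch is fatal
  bad <- X
  colnames(bad) <- rev(colnames(X))
  expect_error(associate_genes(bad, es), "ordering mismatch")
})

test_that("single-gene wrappers agree with the matrix engine", {
  set.seed(71)
  nb <- 40
  es <- factor(sample(c("a", "b", "c"), nb, replace = TRUE))
  X <- matrix(rnorm(10 * nb), 10, nb)
  X[runif(length(X)) < 0.1] <- NA
  for (method in c("kruskal", "anova")) {
    res <- associate_genes(X, es, method, min_branches = 5)
    for (i in c(1, 5, 10)) {
      v <- X[i, ]; keep <- !is.na(v)
      single <- if (method == "kruskal")
        kruskal_wallis(v[keep], es[keep])$statistic
      else anova_tukey(v[keep], es[keep])$statistic
      expect_equal(res$omnibus$statistic[i], single, tolerance = 1e-10)
    }
  }
})

test_that("planted category shifts are detected against null genes", {
  exp_ <- small_experiment(seed = 83, n_genes = 300)
  res <- associate_genes(exp_$rers, exp_$edge_states)
  shifted <- exp_$truth$class == "shifted"
  p_shift <- res$omnibus$p_value[shifted]
  p_null <- res$omnibus$p_value[!shifted]
  expect_lt(median(p_shift, na.rm = TRUE), quantile(p_null, 0.25, na.rm = TRUE))
  # the shifted category's pairwise contrasts carry the signal
  pw <- res$pairwise
  target <- levels(exp_$edge_states)[1]
  inv <- pw$group1 == target | pw$group2 == target
  p_inv <- pw$p_value[inv & pw$gene %in% exp_$truth$gene[shifted]]
  expect_lt(median(p_inv, na.rm = TRUE),
            median(p_null, na.rm = TRUE))
})

test_that("parametric omnibus p-values are uniform on independent null RERs", {
  set.seed(90)
  nb <- 60
  es <- factor(rep(c("a", "b", "c"), each = 20))
  X <- matrix(rnorm(2000 * nb), 2000, nb)
  res <- associate_genes(X, es)
  p <- res$omnibus$p_value
  # ranks put H on a lattice, so ignore the KS ties warning
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
  expect_true(all(res$omnibus$effect_size >= 0 & res$omnibus$effect_size <= 1,
                  na.rm = TRUE))
})
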