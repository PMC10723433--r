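# Association of per-gene RERs with per-branch categories.
#
# The same vectorised engine serves the observed analysis and the
# permulation nulls: per-gene ranks, tie corrections and missingness masks
# depend only on the RER matrix, so they are computed once and reused for
# every null label vector. The engine is cross-checked against
# stats::kruskal.test, aov/TukeyHSD and hand rank arithmetic in the tests.

# Precompute per-gene quantities that do not depend on the branch labels.
#' @keywords internal
assoc_prepare <- function(rers) {
  X <- as.matrix(rers)
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  M <- !is.na(X)
  R <- matrix(0, nrow(X), ncol(X))
  tie_sum <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    v <- X[i, M[i, ]]
    if (length(v)) {
      r <- rank(v)
      R[i, M[i, ]] <- r
      tt <- table(v)
      tie_sum[i] <- sum(tt^3 - tt)
    }
  }
  X0 <- X
  X0[!M] <- 0
  list(X0 = X0, M = M * 1, R = R, tie_sum = tie_sum,
       n = rowSums(M), ssq = rowSums(X0^2), genes = rownames(X))
}

# Kruskal-Wallis H (tie-corrected), epsilon squared H/(n-1), chi-squared p.
#' @keywords internal
kw_engine <- function(prep, G) {
  S <- prep$R %*% G
  N <- prep$M %*% G
  n <- prep$n
  term <- S^2 / N
  term[N == 0] <- 0
  H_raw <- 12 / (n * (n + 1)) * rowSums(term) - 3 * (n + 1)
  C <- 1 - prep$tie_sum / pmax(n^3 - n, 1)
  H <- ifelse(C > 0, pmax(H_raw, 0) / C, 0)
  k_eff <- rowSums(N > 0)
  df <- k_eff - 1
  p <- ifelse(df >= 1, stats::pchisq(H, pmax(df, 1), lower.tail = FALSE), NA_real_)
  list(H = H, eps2 = H / (n - 1), p = p, df = df, S = S, N = N)
}

# Dunn pairwise Z with tie-corrected pooled variance.
#' @keywords internal
dunn_engine <- function(prep, G, kw = NULL) {
  if (is.null(kw)) kw <- kw_engine(prep, G)
  S <- kw$S; N <- kw$N
  n <- prep$n
  V <- n * (n + 1) / 12 - prep$tie_sum / (12 * pmax(n - 1, 1))
  k <- ncol(G)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  Z <- matrix(NA_real_, nrow(S), nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    a <- pairs[j, 1L]; b <- pairs[j, 2L]
    se <- sqrt(V * (1 / N[, a] + 1 / N[, b]))
    Z[, j] <- (S[, a] / N[, a] - S[, b] / N[, b]) / se
  }
  p <- 2 * stats::pnorm(-abs(Z))
  list(Z = Z, p = pmin(p, 1), pairs = pairs)
}

# One-way ANOVA F, eta squared, and Tukey HSD pairwise p.
#' @keywords internal
anova_engine <- function(prep, G) {
  S1 <- prep$X0 %*% G
  N <- prep$M %*% G
  n <- prep$n
  Tt <- rowSums(S1)
  term <- S1^2 / N
  term[N == 0] <- 0
  SSB <- rowSums(term) - Tt^2 / n
  SST <- prep$ssq - Tt^2 / n
  SSW <- pmax(SST - SSB, 0)
  k_eff <- rowSums(N > 0)
  dfb <- k_eff - 1
  dfw <- n - k_eff
  MSW <- SSW / dfw
  degenerate <- SSW <= 1e-12 * pmax(SST, 1) & SST > 0
  F_ <- (SSB / dfb) / MSW
  eta2 <- ifelse(SST > 0, SSB / SST, NA_real_)
  p <- ifelse(dfb >= 1 & dfw >= 1 & !degenerate,
              stats::pf(F_, pmax(dfb, 1), pmax(dfw, 1), lower.tail = FALSE),
              NA_real_)
  list(F = F_, eta2 = eta2, p = p, S1 = S1, N = N, MSW = MSW, dfw = dfw,
       k_eff = k_eff, degenerate = degenerate)
}

#' @keywords internal
tukey_engine <- function(prep, G, an = NULL) {
  if (is.null(an)) an <- anova_engine(prep, G)
  k <- ncol(G)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  means <- an$S1 / an$N
  D <- matrix(NA_real_, nrow(means), nrow(pairs))
  P <- matrix(NA_real_, nrow(means), nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    a <- pairs[j, 1L]; b <- pairs[j, 2L]
    d <- means[, a] - means[, b]
    se <- sqrt(an$MSW / 2 * (1 / an$N[, a] + 1 / an$N[, b]))
    q <- abs(d) / se
    D[, j] <- d
    P[, j] <- stats::ptukey(q, an$k_eff, an$dfw, lower.tail = FALSE)
  }
  list(diff = D, p = P, pairs = pairs)
}

#' @keywords internal
group_indicator <- function(groups, levels) {
  g <- factor(as.character(groups), levels = levels)
  G <- matrix(0, length(g), length(levels))
  G[cbind(seq_along(g), as.integer(g))] <- 1
  colnames(G) <- levels
  G
}

#' Kruskal-Wallis omnibus test with epsilon-squared effect size
#'
#' Tie-corrected (midrank) Kruskal-Wallis test of a numeric vector across
#' `k >= 2` categories; the effect size is `epsilon^2 = H / (n - 1)` where
#' `n` is the number of usable observations.
#'
#' @param values Numeric vector (NAs dropped).
#' @param groups Category labels, same length.
#' @return List with `statistic` (H), `epsilon_squared`, `p_value`, `n`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  if (length(values) < 3) stop("fewer than 3 usable observations")
  lev <- unique(groups)
  if (length(lev) < 2) stop("all values in one group")
  prep <- assoc_prepare(matrix(values, 1))
  kw <- kw_engine(prep, group_indicator(groups, lev))
  list(statistic = unname(kw$H[1]), epsilon_squared = unname(kw$eps2[1]),
       p_value = unname(kw$p[1]), n = length(values))
}

#' Dunn pairwise post-hoc tests
#'
#' Pairwise Z statistics on mean ranks with the tie-corrected pooled
#' standard error; two-sided p-values adjusted across the `k(k-1)/2` pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjust_method Passed to [stats::p.adjust()] (default `"BH"`).
#' @return `data.frame` with `group1`, `group2`, `Z`, `p_value`,
#'   `p_adjusted`, `direction`.
#' @export
dunn_pairwise <- function(values, groups, adjust_method = "BH") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  if (length(values) < 3) stop("fewer than 3 usable observations")
  lev <- unique(groups)
  if (length(lev) < 2) stop("all values in one group")
  prep <- assoc_prepare(matrix(values, 1))
  dn <- dunn_engine(prep, group_indicator(groups, lev))
  data.frame(
    group1 = lev[dn$pairs[, 1L]], group2 = lev[dn$pairs[, 2L]],
    Z = unname(dn$Z[1, ]), p_value = unname(dn$p[1, ]),
    p_adjusted = stats::p.adjust(dn$p[1, ], adjust_method),
    direction = sign(dn$Z[1, ]),
    stringsAsFactors = FALSE
  )
}

#' One-way ANOVA with eta-squared effect size and Tukey HSD post-hoc
#'
#' `eta^2 = SS_effect / (SS_effect + SS_residual)`. Zero residual variance
#' leaves the p-value undefined (`NA`) with `degenerate = TRUE`.
#'
#' @inheritParams kruskal_wallis
#' @return List with `statistic` (F), `eta_squared`, `p_value`, `n`,
#'   `degenerate`, and `tukey` (`data.frame` of pairwise mean differences
#'   and Tukey-adjusted p-values).
#' @export
anova_tukey <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lev <- unique(groups)
  if (length(lev) < 2) stop("all values in one group")
  if (length(values) - length(lev) < 2) stop("need at least 2 residual df")
  prep <- assoc_prepare(matrix(values, 1))
  G <- group_indicator(groups, lev)
  an <- anova_engine(prep, G)
  tk <- tukey_engine(prep, G, an)
  list(statistic = unname(an$F[1]), eta_squared = unname(an$eta2[1]),
       p_value = unname(an$p[1]), n = length(values),
       degenerate = unname(an$degenerate[1]),
       tukey = data.frame(
         group1 = lev[tk$pairs[, 1L]], group2 = lev[tk$pairs[, 2L]],
         diff = unname(tk$diff[1, ]), p_adjusted = unname(tk$p[1, ]),
         direction = sign(tk$diff[1, ]),
         stringsAsFactors = FALSE))
}

#' Associate every gene's RERs with branch categories
#'
#' Runs the omnibus test (Kruskal-Wallis or ANOVA) and all pairwise
#' post-hoc tests (Dunn or Tukey) for each gene of an RER matrix against a
#' per-branch category labelling. Genes with too little usable data get NA
#' rows with a reason code. Internal and terminal branches are both used by
#' default; pass `branch_subset` to restrict (e.g. extant-only).
#'
#' @param rers Genes x branches numeric matrix (NA = missing); columns must
#'   align with `edge_states` (checked by name when both are named).
#' @param edge_states Factor over branches from [assign_edge_states()] /
#'   [composite_edge_states()].
#' @param method `"kruskal"` (default) or `"anova"`.
#' @param min_branches Minimum usable branches per tested gene (default 8).
#' @param min_per_category Minimum usable branches in each of at least two
#'   categories (default 2).
#' @param adjust_method Pairwise multiple-comparison adjustment within each
#'   gene (default `"BH"`).
#' @param branch_subset Optional logical/integer selector of branches.
#' @return Object of class `rer_association`: list with `omnibus` and
#'   `pairwise` data frames, the category `levels`, and the settings.
#' @export
associate_genes <- function(rers, edge_states, method = c("kruskal", "anova"),
                            min_branches = 8, min_per_category = 2,
                            adjust_method = "BH", branch_subset = NULL) {
  method <- match.arg(method)
  X <- as.matrix(rers)
  es <- edge_states
  if (!is.null(colnames(X)) && !is.null(names(es))) {
    if (!identical(colnames(X), names(es)))
      stop("branch ordering mismatch between RER matrix columns and edge states")
  }
  if (ncol(X) != length(es))
    stop("RER matrix has ", ncol(X), " branches but edge states has ",
         length(es))
  if (!is.null(branch_subset)) {
    X <- X[, branch_subset, drop = FALSE]
    es <- es[branch_subset]
  }
  lev <- levels(factor(es))
  prep <- assoc_prepare(X)
  G <- group_indicator(es, lev)
  N <- prep$M %*% G
  eligible <- prep$n >= min_branches & rowSums(N >= min_per_category) >= 2
  reason <- ifelse(eligible, NA_character_, "insufficient data")

  if (method == "kruskal") {
    kw <- kw_engine(prep, G)
    dn <- dunn_engine(prep, G, kw)
    stat <- kw$H; eff <- kw$eps2; p <- kw$p
    pw_stat <- dn$Z; pw_p <- dn$p; pairs <- dn$pairs
  } else {
    an <- anova_engine(prep, G)
    tk <- tukey_engine(prep, G, an)
    stat <- an$F; eff <- an$eta2; p <- an$p
    pw_stat <- tk$diff; pw_p <- tk$p; pairs <- tk$pairs
    reason[eligible & an$degenerate] <- "zero residual variance"
  }
  stat[!eligible] <- NA_real_; eff[!eligible] <- NA_real_
  p[!eligible] <- NA_real_
  pw_stat[!eligible, ] <- NA_real_; pw_p[!eligible, ] <- NA_real_
  pw_padj <- t(apply(pw_p, 1L, stats::p.adjust, method = adjust_method))
  if (ncol(pw_p) == 1L) pw_padj <- matrix(pw_padj, ncol = 1L)

  genes <- prep$genes
  omnibus <- data.frame(
    gene = genes, statistic = stat, effect_size = eff, p_value = p,
    n = prep$n, reason = reason, stringsAsFactors = FALSE)
  np <- nrow(pairs)
  pairwise <- data.frame(
    gene = rep(genes, each = np),
    group1 = rep(lev[pairs[, 1L]], times = length(genes)),
    group2 = rep(lev[pairs[, 2L]], times = length(genes)),
    statistic = as.vector(t(pw_stat)),
    p_value = as.vector(t(pw_p)),
    p_adjusted = as.vector(t(pw_padj)),
    direction = sign(as.vector(t(pw_stat))),
    stringsAsFactors = FALSE)
  structure(list(omnibus = omnibus, pairwise = pairwise, levels = lev,
                 method = method, adjust_method = adjust_method,
                 min_branches = min_branches,
                 min_per_category = min_per_category),
            class = "rer_association")
}

#' @export
print.rer_association <- function(x, ...) {
  tested <- sum(!is.na(x$omnibus$p_value))
  cat(sprintf("RER association (%s): %d of %d genes tested, %d categories (%s)\n",
              x$method, tested, nrow(x$omnibus), length(x$levels),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}
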