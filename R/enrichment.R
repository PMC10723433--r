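# Rank-based pathway enrichment with permulation correction.

#' Read gene sets from a GMT file
#'
#' One pathway per line: name, description, then one gene per field,
#' tab-separated. Duplicate genes within a set are collapsed.
#'
#' @param path GMT file path.
#' @return Object of class `gene_set_collection`: named list of character
#'   vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0),
                     class = "gene_set_collection"))
  }
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": expected name, description and >= 1 gene")
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene id vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions (defaults to the names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Per-gene ranking score from association results
#'
#' Omnibus mode: `-log10(p)` (the omnibus test is one-sided, no sign);
#' pairwise mode: `sign(statistic) * -log10(p)`. Genes with NA p-values are
#' excluded from the universe (dropped).
#'
#' @param results `data.frame` with `gene`, `p_value` and (pairwise mode)
#'   `statistic` columns, e.g. a slice of [associate_genes()] output.
#' @param mode `"omnibus"` or `"pairwise"`.
#' @return Named numeric vector of scores.
#' @export
rank_statistic <- function(results, mode = c("omnibus", "pairwise")) {
  mode <- match.arg(mode)
  keep <- !is.na(results$p_value)
  p <- pmax(results$p_value[keep], 1e-300)
  s <- -log10(p)
  if (mode == "pairwise") s <- sign(results$statistic[keep]) * s
  stats::setNames(s, results$gene[keep])
}

# Rank-sum W of the in-set genes, normal z with tie and continuity
# correction; cross-checked against stats::wilcox.test in the tests.
#' @keywords internal
wilcox_z <- function(scores, inset) {
  n <- length(scores)
  n1 <- sum(inset); n2 <- n - n1
  r <- rank(scores)
  W <- sum(r[inset])
  EW <- n1 * (n + 1) / 2
  tt <- table(scores)
  tiecorr <- sum(tt^3 - tt) / (n * (n - 1))
  V <- n1 * n2 / 12 * ((n + 1) - tiecorr)
  d <- W - EW
  z <- if (V > 0) (d - sign(d) * 0.5) / sqrt(V) else 0
  list(W = W, z = z, p = min(1, 2 * stats::pnorm(-abs(z))),
       direction = sign(d))
}

#' Wilcoxon rank-sum enrichment of one gene set
#'
#' Tests whether the genes of a set are shifted in rank relative to the
#' rest of the universe (two-sample Wilcoxon rank-sum, normal approximation
#' with tie and continuity correction).
#'
#' @param scores Named per-gene scores (see [rank_statistic()]).
#' @param set Character vector of gene ids.
#' @param min_size Minimum in-universe set size (default 10).
#' @return List with `W` (rank-sum of the in-set genes), `z`, `p_value`,
#'   `direction` (+1 toward larger scores), `n_genes_in_set`; `NULL` fields
#'   with a `reason` when the set is too small.
#' @export
wilcoxon_enrichment <- function(scores, set, min_size = 10) {
  inset <- names(scores) %in% set
  n1 <- sum(inset)
  if (n1 < min_size || n1 >= length(scores))
    return(list(W = NA_real_, z = NA_real_, p_value = NA_real_,
                direction = NA_real_, n_genes_in_set = n1,
                reason = "set size out of bounds"))
  wz <- wilcox_z(scores, inset)
  list(W = wz$W, z = wz$z, p_value = wz$p, direction = wz$direction,
       n_genes_in_set = n1, reason = NA_character_)
}

#' Pathway enrichment over a gene set collection
#'
#' @inheritParams wilcoxon_enrichment
#' @param sets A `gene_set_collection` (or named list of gene id vectors).
#' @param max_size Maximum in-universe set size (default 500).
#' @return `data.frame`: `pathway`, `W`, `z`, `p_value`, `p_adjusted`
#'   (Benjamini-Hochberg across pathways), `n_genes_in_set`, `direction`.
#' @export
enrich_pathways <- function(scores, sets, min_size = 10, max_size = 500) {
  rows <- lapply(names(sets), function(nm) {
    res <- wilcoxon_enrichment(scores, sets[[nm]], min_size)
    if (!is.na(res$n_genes_in_set) && res$n_genes_in_set > max_size)
      res[c("W", "z", "p_value", "direction")] <- NA_real_
    data.frame(pathway = nm, W = res$W, z = res$z, p_value = res$p_value,
               n_genes_in_set = res$n_genes_in_set,
               direction = res$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out[, c("pathway", "W", "z", "p_value", "p_adjusted",
          "n_genes_in_set", "direction")]
}

#' Permulation-corrected pathway enrichment
#'
#' Recomputes the ranking score and the Wilcoxon enrichment for every
#' permulation's null gene statistics and reports, per pathway,
#' `perm_p = (#\{|z_null| >= |z_obs|\} + 1) / (N + 1)`. The gene universe is
#' fixed to the observed analysis; null replicates where a pathway has no
#' usable genes contribute NA and shrink that pathway's denominator.
#'
#' @param permtest An `rer_permtest` from [permulation_pvalues()].
#' @param sets Gene set collection.
#' @param mode `"omnibus"` or `"pairwise"`; pairwise requires `pair`.
#' @param pair Length-2 character vector naming the category pair.
#' @param min_size,max_size Set size bounds within the universe.
#' @return The [enrich_pathways()] table for the observed scores with a
#'   `perm_p` column appended.
#' @export
permulation_enrichment <- function(permtest, sets, mode = c("omnibus", "pairwise"),
                                   pair = NULL, min_size = 10, max_size = 500) {
  stopifnot(inherits(permtest, "rer_permtest"))
  mode <- match.arg(mode)
  if (mode == "omnibus") {
    obs_tab <- permtest$omnibus
    null_p <- permtest$nulls$omnibus_p
    null_stat <- permtest$nulls$omnibus_stat
  } else {
    if (is.null(pair) || length(pair) != 2)
      stop("pairwise mode needs 'pair = c(group1, group2)'")
    sel <- permtest$pairwise$group1 == pair[1] & permtest$pairwise$group2 == pair[2]
    if (!any(sel)) stop("unknown category pair")
    obs_tab <- permtest$pairwise[sel, ]
    j <- which(permtest$levels[permtest$nulls$pairs[, 1L]] == pair[1] &
               permtest$levels[permtest$nulls$pairs[, 2L]] == pair[2])
    null_p <- permtest$nulls$pairwise_p[[j]]
    null_stat <- permtest$nulls$pairwise_stat[[j]]
  }
  scores_obs <- rank_statistic(obs_tab, mode)
  obs <- enrich_pathways(scores_obs, sets, min_size, max_size)
  universe <- names(scores_obs)

  N <- nrow(null_p)
  zmat <- matrix(NA_real_, N, nrow(obs), dimnames = list(NULL, obs$pathway))
  insets <- lapply(obs$pathway, function(nm) universe %in% sets[[nm]])
  for (i in seq_len(N)) {
    df <- data.frame(gene = colnames(null_p), p_value = null_p[i, ],
                     statistic = null_stat[i, ], stringsAsFactors = FALSE)
    sc <- rank_statistic(df[df$gene %in% universe, ], mode)
    sc <- sc[universe]     # fixed universe; genes NA in a replicate drop out
    ok <- !is.na(sc)
    for (j in seq_along(insets)) {
      ins <- insets[[j]] & ok
      n1 <- sum(ins)
      if (n1 >= min_size && n1 < sum(ok))
        zmat[i, j] <- wilcox_z(sc[ok], insets[[j]][ok])$z
    }
  }
  b <- colSums(sweep(abs(zmat), 2L, abs(obs$z), ">="), na.rm = TRUE)
  Nv <- colSums(!is.na(zmat))
  obs$perm_p <- ifelse(is.na(obs$z) | Nv == 0, NA_real_, (b + 1) / (Nv + 1))
  obs
}
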