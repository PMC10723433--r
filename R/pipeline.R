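# Stage drivers tying the workflow together:
# ASR -> association -> permulation -> enrichment.

#' Fit rate models, compare them, and reconstruct ancestral states
#'
#' Fits each requested rate model on the master tree, runs the
#' likelihood-ratio test between every model and each of its more complex
#' alternatives, selects a model, and returns the marginal reconstruction,
#' node-state assignment, per-branch categories and transition counts.
#' Species present in the tree but absent from the phenotype are dropped by
#' pruning (with a warning); composite branches then take the state of
#' their most tipward master branch.
#'
#' @param tree Master `phylo` (or a newick file path).
#' @param phenotype Named species -> category vector (or a table path for
#'   [read_phenotype()]).
#' @param models Character vector of rate models to fit (default
#'   `c("ER", "SYM", "ARD")`) or a list of [rate_model()] objects.
#' @param select `"auto"` (most complex model that significantly beats the
#'   current choice, in order of increasing free parameters), or the name /
#'   index of a model.
#' @param alpha Significance level for auto selection (default 0.05).
#' @param root_prior Passed to [fit_mk()].
#' @param n_montecarlo Replicates for non-nested comparisons.
#' @return Object of class `catrer_asr`: `fits`, `lrt` (comparison table),
#'   `selected`, `asr` (ancestral likelihoods), `node_states`,
#'   `edge_states`, `transitions`, `paths` (NULL when no pruning).
#' @export
run_asr <- function(tree, phenotype, models = c("ER", "SYM", "ARD"),
                    select = "auto", alpha = 0.05, root_prior = "flat",
                    n_montecarlo = 199) {
  if (is.character(tree) && length(tree) == 1) tree <- read_newick(file = tree)
  if (is.character(phenotype) && length(phenotype) == 1 && file.exists(phenotype))
    phenotype <- read_phenotype(phenotype)
  tree <- stats::reorder(tree, "postorder")
  common <- intersect(tree$tip.label, names(phenotype))
  if (length(common) < 2)
    stop("tree and phenotype share fewer than 2 species; tree-only: ",
         paste(head(setdiff(tree$tip.label, names(phenotype)), 5), collapse = ", "),
         "; phenotype-only: ",
         paste(head(setdiff(names(phenotype), tree$tip.label), 5), collapse = ", "))
  paths <- NULL
  fit_tree <- tree
  if (length(common) < length(tree$tip.label)) {
    warning("dropping ", length(tree$tip.label) - length(common),
            " species without phenotype data")
    paths <- build_paths(tree, common)
    fit_tree <- paths$tree
  }
  ph <- phenotype[common]

  if (!is.list(models)) {
    lev <- if (is.factor(ph)) levels(factor(as.character(ph))) else unique(as.character(ph))
    k <- length(unique(as.character(ph)))
    nms <- models
    models <- lapply(models, rate_model, k = k)
    names(models) <- nms
  }
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  fits <- lapply(models, function(m) fit_mk(fit_tree, ph, m, root_prior))

  np <- vapply(fits, function(f) n_free_params(f$model), 0L)
  ord <- order(np)
  cmp <- list()
  for (a in seq_along(ord)) for (b in seq_along(ord)) {
    if (b <= a) next
    i <- ord[a]; j <- ord[b]
    if (np[j] <= np[i]) next
    lt <- likelihood_ratio_test(fits[[i]], fits[[j]], n_montecarlo)
    cmp[[length(cmp) + 1L]] <- data.frame(
      simple = names(fits)[i], complex = names(fits)[j],
      lr = lt$lr, df = lt$df, p_value = lt$p_value, nested = lt$nested,
      stringsAsFactors = FALSE)
  }
  lrt <- if (length(cmp)) do.call(rbind, cmp) else NULL

  if (identical(select, "auto")) {
    if (length(fits) < 2 && identical(select, "auto"))
      chosen <- 1L
    else {
      chosen <- ord[1L]
      for (b in 2:length(ord)) {
        j <- ord[b]
        row <- lrt[lrt$simple == names(fits)[chosen] &
                   lrt$complex == names(fits)[j], ]
        if (nrow(row) && !is.na(row$p_value[1]) && row$p_value[1] < alpha)
          chosen <- j
      }
    }
  } else chosen <- if (is.character(select)) match(select, names(fits)) else select
  fit <- fits[[chosen]]

  A <- predict(fit, "marginal")
  ns <- max_state_assignment(A)
  es <- assign_edge_states(fit_tree, ns)
  structure(list(fits = fits, lrt = lrt, selected = names(fits)[chosen],
                 fit = fit, asr = A, node_states = ns, edge_states = es,
                 transitions = count_transitions(fit_tree, ns),
                 tree = fit_tree, paths = paths),
            class = "catrer_asr")
}

#' @export
print.catrer_asr <- function(x, ...) {
  cat("Categorical ancestral reconstruction\n")
  cat("  selected rate model:", x$selected, "\n")
  if (!is.null(x$lrt)) {
    cat("  model comparisons:\n")
    print(x$lrt, row.names = FALSE)
  }
  cat("  transition counts (ancestor row -> descendant column):\n")
  print(x$transitions)
  invisible(x)
}

#' Full observed-plus-permulation analysis on in-memory objects
#'
#' Convenience driver: associate genes, permulate, compute permulation
#' p-values, and (optionally) permulation-corrected enrichment.
#'
#' @param asr A `catrer_asr` from [run_asr()].
#' @param rers RER matrix aligned to the (possibly pruned) tree's branches.
#' @param pathways Optional gene set collection.
#' @param method Association method.
#' @param config [permulation_config()].
#' @param min_size,max_size Enrichment set-size bounds.
#' @return List: `association`, `permulations`, `permtest`, `enrichment`
#'   (omnibus-mode table or NULL).
#' @export
run_pipeline <- function(asr, rers, pathways = NULL,
                         method = c("kruskal", "anova"),
                         config = permulation_config(),
                         min_size = 10, max_size = 500) {
  method <- match.arg(method)
  assoc <- associate_genes(rers, asr$edge_states, method)
  perms <- permulate(asr$fit, config = config)
  pt <- permulation_pvalues(assoc, rers, perms)
  enr <- if (!is.null(pathways))
    permulation_enrichment(pt, pathways, "omnibus",
                           min_size = min_size, max_size = max_size)
  list(association = assoc, permulations = perms, permtest = pt,
       enrichment = enr)
}
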