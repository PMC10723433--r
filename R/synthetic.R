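# Synthetic fixtures: trees, Mk phenotypes, RER matrices with planted
# category-specific rate shifts, and pathway collections. The generator
# emulates the shape of a real analysis (a master tree with rate branch
# lengths, a diet-like k-category phenotype, a genes x branches RER matrix
# with missingness) at reduced scale.

#' Specification for a synthetic experiment
#'
#' Defaults describe the package's reference synthetic condition: a 40-tip
#' Yule tree, a 3-category phenotype evolved under an equal-rates Mk model
#' at rate 0.5 per branch-length unit (a handful of transitions per
#' root-to-tip path, so all categories are usually represented), 2,000
#' genes of unit-variance branch noise of which 5% carry a +2 SD shift on
#' the branches of one category, and 5% missing values.
#'
#' @param n_tips Tips in the master tree (>= 4).
#' @param birth Yule birth rate (branch durations are exponential).
#' @param k Number of categories.
#' @param rate Shared transition rate of the generating (ER) `Q`; or pass a
#'   full `Q` via `Q`.
#' @param Q Optional generating rate matrix overriding `rate`.
#' @param n_genes Number of genes.
#' @param fraction_shifted Fraction of genes with a planted shift.
#' @param shift_target Category (index or label) whose branches are shifted.
#' @param effect_size Mean RER offset on target branches, in noise SD units.
#' @param noise_sd Branch noise standard deviation.
#' @param noise `"normal"` (default) or `"t"` (Student t, df 5, heavier
#'   tails for robustness checks).
#' @param missing_rate Fraction of entries masked at random.
#' @param clique_size Genes in an optional co-shifting clique sharing a
#'   branch-level latent factor (0 disables).
#' @param clique_cor Correlation weight of the clique latent factor.
#' @param seed RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tips = 40, birth = 1, k = 3, rate = 0.5,
                           Q = NULL, n_genes = 2000, fraction_shifted = 0.05,
                           shift_target = 1, effect_size = 2, noise_sd = 1,
                           noise = c("normal", "t"), missing_rate = 0.05,
                           clique_size = 0, clique_cor = 0.7, seed = NULL) {
  stopifnot(n_tips >= 4, k >= 2, fraction_shifted >= 0, fraction_shifted <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(Q)) Q <- build_Q(rate, rate_model("ER", k))
  structure(list(n_tips = n_tips, birth = birth, k = k, Q = Q,
                 n_genes = n_genes, fraction_shifted = fraction_shifted,
                 shift_target = shift_target, effect_size = effect_size,
                 noise_sd = noise_sd, noise = match.arg(noise),
                 missing_rate = missing_rate, clique_size = clique_size,
                 clique_cor = clique_cor, seed = seed),
            class = "synthetic_spec")
}

#' Generate a Yule master tree
#'
#' Pure-birth tree via [ape::rphylo()] with the spec's birth rate; tips are
#' relabelled `sp01, sp02, ...` and edges put in the package's canonical
#' postorder.
#'
#' @param spec A [synthetic_spec()].
#' @return `phylo` with `n_tips` tips.
#' @export
gen_tree <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  tr <- ape::rphylo(spec$n_tips, birth = spec$birth, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(spec$n_tips))
  validate_tree(tr)
}

#' Generate a phenotype under the spec's Markov model
#'
#' Simulates the trait down the tree, resampling (up to 100 times) until at
#' least two categories are present at the tips; the true node states are
#' retained for reconstruction-accuracy testing.
#'
#' @param tree Master tree.
#' @param spec A [synthetic_spec()].
#' @return List: `tip_states` (named factor over `cat1..catk`),
#'   `node_states` (factor over all nodes, the truth), `Q`.
#' @export
gen_phenotype <- function(tree, spec) {
  lev <- paste0("cat", seq_len(spec$k))
  ntip <- length(tree$tip.label)
  for (try in seq_len(100)) {
    s <- simulate_phenotype(tree, spec$Q)
    if (length(unique(s[seq_len(ntip)])) >= 2)
      return(list(
        tip_states = stats::setNames(factor(lev[s[seq_len(ntip)]], levels = lev),
                                     tree$tip.label),
        node_states = factor(lev[s], levels = lev),
        Q = spec$Q))
  }
  stop("phenotype simulation produced < 2 tip categories in 100 attempts")
}

#' Generate an RER matrix with planted category shifts
#'
#' Null genes are independent noise per branch; shifted genes add
#' `effect_size * noise_sd` on the branches whose true state is the target
#' category; clique genes share a branch-level latent factor (correlated
#' nulls, no mean shift). Entries are masked at `missing_rate`.
#'
#' @param tree Master tree.
#' @param edge_states_truth Factor over branches (true branch categories,
#'   from [assign_edge_states()] on the truth).
#' @param spec A [synthetic_spec()].
#' @return List: `rers` (genes x branches matrix, NA = missing), `truth`
#'   (`data.frame` with `gene`, `class` in `null`/`shifted`/`clique`).
#' @export
gen_rer_matrix <- function(tree, edge_states_truth, spec) {
  nb <- length(edge_states_truth)
  ng <- spec$n_genes
  noise <- if (spec$noise == "t")
    matrix(stats::rt(ng * nb, df = 5), ng, nb) * spec$noise_sd / sqrt(5 / 3)
  else matrix(stats::rnorm(ng * nb, sd = spec$noise_sd), ng, nb)
  X <- noise
  n_shift <- round(spec$fraction_shifted * ng)
  classes <- rep("null", ng)
  if (n_shift > 0) {
    lev <- levels(edge_states_truth)
    target <- if (is.numeric(spec$shift_target)) lev[spec$shift_target]
              else as.character(spec$shift_target)
    on <- as.character(edge_states_truth) == target
    idx <- seq_len(n_shift)
    X[idx, on] <- X[idx, on] + spec$effect_size * spec$noise_sd
    classes[idx] <- "shifted"
  }
  if (spec$clique_size > 0) {
    idx <- (n_shift + 1):(n_shift + spec$clique_size)
    latent <- stats::rnorm(nb, sd = spec$noise_sd)
    rho <- spec$clique_cor
    X[idx, ] <- sqrt(1 - rho^2) * X[idx, ] +
      rho * matrix(latent, length(idx), nb, byrow = TRUE)
    classes[idx] <- "clique"
  }
  if (spec$missing_rate > 0)
    X[matrix(stats::runif(ng * nb) < spec$missing_rate, ng, nb)] <- NA
  rownames(X) <- sprintf("gene%04d", seq_len(ng))
  colnames(X) <- as.character(seq_len(nb))
  list(rers = X,
       truth = data.frame(gene = rownames(X), class = classes,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic pathway collection
#'
#' Random gene sets plus, optionally, one set enriched for the planted
#' shifted genes and one holding the co-shifting clique.
#'
#' @param gene_ids Universe of gene ids.
#' @param n_pathways Number of random sets.
#' @param size_range Length-2 integer range of set sizes.
#' @param shifted_genes Optional ids for the planted-enrichment set.
#' @param planted_overlap Fraction of the planted set drawn from
#'   `shifted_genes` (1 = subset of the shifted genes).
#' @param clique_genes Optional ids forming the clique set verbatim.
#' @return `gene_set_collection`.
#' @export
gen_pathways <- function(gene_ids, n_pathways = 20, size_range = c(15, 60),
                         shifted_genes = NULL, planted_overlap = 1,
                         clique_genes = NULL) {
  sets <- list()
  for (i in seq_len(n_pathways)) {
    sz <- min(sample(size_range[1]:size_range[2], 1), length(gene_ids))
    sets[[sprintf("random%02d", i)]] <- sample(gene_ids, sz)
  }
  if (!is.null(shifted_genes) && length(shifted_genes)) {
    sz <- min(length(shifted_genes), max(size_range[1], 20))
    n_in <- round(planted_overlap * sz)
    sets[["planted_shift"]] <- unique(c(
      sample(shifted_genes, n_in),
      sample(setdiff(gene_ids, shifted_genes), sz - n_in)))
  }
  if (!is.null(clique_genes) && length(clique_genes))
    sets[["clique"]] <- clique_genes
  structure(sets, descriptions = stats::setNames(names(sets), names(sets)),
            class = "gene_set_collection")
}

#' Generate a complete synthetic experiment
#'
#' Tree, phenotype, truth edge states, RER matrix and pathways in one call.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `tree`, `phenotype` (from [gen_phenotype()]),
#'   `edge_states` (truth), `rers`, `truth`, `pathways`, `spec`.
#' @export
gen_experiment <- function(spec = synthetic_spec()) {
  tree <- gen_tree(spec)
  ph <- gen_phenotype(tree, spec)
  es <- assign_edge_states(tree, ph$node_states)
  rr <- gen_rer_matrix(tree, es, spec)
  shifted <- rr$truth$gene[rr$truth$class == "shifted"]
  clique <- rr$truth$gene[rr$truth$class == "clique"]
  pw <- gen_pathways(rownames(rr$rers),
                     shifted_genes = if (length(shifted)) shifted,
                     clique_genes = if (length(clique)) clique)
  list(tree = tree, phenotype = ph, edge_states = es, rers = rr$rers,
       truth = rr$truth, pathways = pw, spec = spec)
}
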