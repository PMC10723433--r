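Package: catrer
Title: Association of Relative Evolutionary Rates with Categorical Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for associating per-gene relative evolutionary rates (RERs)
    with non-ordinal multi-category phenotypes on a phylogeny. Implements
    maximum-likelihood fitting of continuous-time Markov (Mk) models of
    discrete-trait evolution with user-defined rate models (ER, SYM, ARD or
    custom), marginal ancestral state reconstruction on rooted or unrooted
    trees with polytomies, likelihood-ratio comparison of nested and
    non-nested rate models, Kruskal-Wallis/Dunn and ANOVA/Tukey association
    of RERs with per-branch categories, phylogeny-aware "permulation" null
    phenotype generation (rejection sampling from the fitted Markov model,
    likelihood-weighted permutation of internal states and a simulated
    annealing reorganisation step, with an optional relaxation of extant
    category counts), and rank-based pathway enrichment with
    permulation-corrected p-values. A synthetic-data generator emulating
    trees, Mk phenotypes and RER matrices with planted rate shifts supports
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    stats,
    utils
Suggests:
    phytools,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
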