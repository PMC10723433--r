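# Plain-text I/O: phenotype tables, RER matrices, result tables.

#' Read a species-to-category phenotype table
#'
#' Two columns (`species`, `category`), TSV or CSV (sniffed from the
#' header). Category labels are arbitrary strings; their order of first
#' appearance fixes the internal state order.
#'
#' @param path File path.
#' @return Named factor, species -> category.
#' @export
read_phenotype <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype table needs 'species' and 'category' columns")
  names(df)[1:2] <- c("species", "category")
  if (anyDuplicated(df$species))
    stop("duplicate species in phenotype table")
  stats::setNames(factor(df$category, levels = unique(df$category)), df$species)
}

#' Write a phenotype table (TSV)
#' @param phenotype Named vector/factor, species -> category.
#' @param path Output path.
#' @export
write_phenotype <- function(phenotype, path) {
  utils::write.table(
    data.frame(species = names(phenotype),
               category = as.character(phenotype)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x branches RER matrix (TSV)
#'
#' Header row of branch indices, one row per gene (first column = gene id),
#' `NA` for missing values.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and branch colnames.
#' @export
read_rer_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a genes x branches RER matrix (TSV)
#' @param rers Matrix with gene rownames.
#' @param path Output path.
#' @export
write_rer_matrix <- function(rers, path) {
  df <- data.frame(gene = rownames(rers), rers, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate per-category species counts of a phenotype vector
#'
#' Convenience check for externally supplied phenotype files, including
#' merged categories (e.g. a "vertivore" grouping counting carnivores plus
#' piscivores together).
#'
#' @param phenotype Named factor/vector, species -> category.
#' @param merge Optional named list: new category -> character vector of
#'   categories to pool.
#' @return Named integer vector of counts.
#' @export
category_counts <- function(phenotype, merge = NULL) {
  v <- as.character(phenotype)
  cnt <- table(v)
  out <- stats::setNames(as.integer(cnt), names(cnt))
  if (!is.null(merge))
    for (nm in names(merge))
      out[nm] <- sum(out[intersect(merge[[nm]], names(out))])
  out
}
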