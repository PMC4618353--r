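#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path file path.
#' @param transform scale declared for the values (`"raw"` by default).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, transform = "raw") {
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression matrix file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expected <- length(header)
  body <- fields[-1]
  bad <- which(vapply(body, length, 1L) != ncol_expected)
  if (length(bad))
    stop("ragged row in ", path, " at line ", bad[1] + 1L,
         " (expected ", ncol_expected, " fields)")
  gene_ids <- vapply(body, `[[`, "", 1L)
  vals <- vapply(body, function(f) as.numeric(f[-1]), numeric(ncol_expected - 1L))
  m <- if (is.null(dim(vals))) matrix(vals, nrow = length(gene_ids)) else t(vals)
  if (anyNA(m)) {
    row <- which(apply(m, 1, anyNA))[1]
    stop("non-numeric value in ", path, " at line ", row + 1L)
  }
  rownames(m) <- gene_ids
  colnames(m) <- header[-1]
  expression_matrix(m, transform = transform)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with enough digits for a lossless round trip
#' (15 significant digits).
#'
#' @param x an expression matrix.
#' @param path output file path.
#' @export
write_expression_matrix <- function(x, path) {
  lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE,
                                              scientific = FALSE)),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet from a tab-separated file
#'
#' @param path file path; columns `sample_id`, `species`, `stage`, `sex`,
#'   `replicate`.
#' @return a validated sample `data.frame`.
#' @export
read_sample_info <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  s$replicate <- as.integer(s$replicate)
  validate_sample_info(s)
  s
}

#' Read a gene annotation table from a tab-separated file
#'
#' @param path file path; columns `orthogroup_id`, `muller`; an optional
#'   `neo_x_species` column (constant) names the neo-X species.
#' @return an annotation `data.frame` (see [gene_annotation()]).
#' @export
read_gene_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  neo <- if ("neo_x_species" %in% names(a)) a$neo_x_species[1] else NA_character_
  gene_annotation(a$orthogroup_id, a$muller, neo_x_species = neo)
}

#' Write a generic results table as tab-separated text
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogeny and check it against the species set
#'
#' The tree must be Newick with non-negative branch lengths (substitutions
#' per site) and its tips must exactly match the species analysed.
#' Multifurcations are resolved deterministically into zero-length
#' dichotomies so that contrasts can be computed.
#'
#' @param path Newick file path.
#' @param species character vector of expected tip labels.
#' @return an [ape::read.tree()] phylogeny (class `phylo`).
#' @export
read_tree <- function(path, species) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree: ", path)
  check_tree(tree, species)
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @export
check_tree <- function(tree, species) {
  missing <- setdiff(species, tree$tip.label)
  extra <- setdiff(tree$tip.label, species)
  if (length(missing)) stop("tree is missing tips: ", paste(missing, collapse = ", "))
  if (length(extra)) stop("tree has unexpected tips: ", paste(extra, collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has a negative branch length")
  if (sum(tree$edge.length) <= 0) stop("tree has zero total length")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  tree
}
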