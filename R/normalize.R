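#' Normalize an FPKM expression matrix
#'
#' Implements the six between-sample normalization schemes compared in the
#' pipeline: no normalization, scaling to the median / 75th / 95th
#' percentile of a set of anchor genes, trimmed mean of M-values (TMM), and
#' quantile normalization. Percentile-type methods rescale each sample so
#' that the chosen percentile of the anchor genes (by default genes on the
#' autosomal Muller elements B, C and E) is identical across samples; the
#' common target is the geometric mean of the per-sample anchor
#' percentiles, which makes the operation idempotent.
#'
#' @param x raw expression matrix (genes x samples).
#' @param annotation gene annotation (used to select anchor genes).
#' @param method one of `"none"`, `"median"`, `"p75"`, `"p95"`, `"tmm"`,
#'   `"quantile"`.
#' @param anchor_elements Muller elements whose genes anchor the
#'   percentile-type methods; use `NULL` to anchor on all genes.
#' @return a raw expression matrix with an additional attribute
#'   `scale_factors` (per-sample multipliers; `NULL` for quantile).
#' @export
normalize_expression <- function(x, annotation = NULL,
                                 method = c("p75", "none", "median", "p95",
                                            "tmm", "quantile"),
                                 anchor_elements = c("B", "C", "E")) {
  method <- match.arg(method)
  if (expr_transform(x) != "raw") stop("normalization requires a raw matrix")
  if (any(colSums(x) == 0)) stop("all-zero sample in expression matrix")
  if (method == "none") {
    attr(x, "scale_factors") <- stats::setNames(rep(1, ncol(x)), colnames(x))
    return(x)
  }
  if (method %in% c("median", "p75", "p95")) {
    p <- c(median = 0.5, p75 = 0.75, p95 = 0.95)[[method]]
    anchor <- anchor_rows(x, annotation, anchor_elements)
    q <- apply(x[anchor, , drop = FALSE], 2, stats::quantile, probs = p,
               names = FALSE, type = 7)
    if (any(q <= 0)) stop("anchor percentile is zero in sample: ",
                          paste(colnames(x)[q <= 0], collapse = ", "))
    target <- exp(mean(log(q)))
    f <- target / q
  } else if (method == "tmm") {
    f <- tmm_factors(x)
  } else {                               # quantile
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out <- expression_matrix(out, "raw")
    attr(out, "scale_factors") <- NULL
    return(out)
  }
  out <- sweep(x, 2, f, `*`)
  out <- expression_matrix(out, "raw")
  attr(out, "scale_factors") <- stats::setNames(f, colnames(x))
  out
}

anchor_rows <- function(x, annotation, anchor_elements) {
  if (is.null(anchor_elements)) return(seq_len(nrow(x)))
  if (is.null(annotation)) stop("annotation required to select anchor genes")
  genes <- annotation$orthogroup_id[annotation$muller %in% anchor_elements]
  rows <- which(rownames(x) %in% genes)
  if (!length(rows)) stop("anchor element set selects zero genes")
  rows
}

# Trimmed mean of M-values against the sample whose upper quartile is
# closest to the mean upper quartile; 30% trim on M, 5% on A; factors are
# rescaled to geometric mean 1.
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  uq <- apply(x, 2, stats::quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(uq - mean(uq)))
  logf <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) return(0)
    keep <- x[, j] > 0 & x[, ref] > 0
    M <- log2(x[keep, j] / x[keep, ref])
    A <- 0.5 * log2(x[keep, j] * x[keep, ref])
    lo_m <- stats::quantile(M, trim_m, names = FALSE)
    hi_m <- stats::quantile(M, 1 - trim_m, names = FALSE)
    lo_a <- stats::quantile(A, trim_a, names = FALSE)
    hi_a <- stats::quantile(A, 1 - trim_a, names = FALSE)
    use <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
    if (!any(use)) 0 else mean(M[use])
  }, 0)
  f <- 2^(-logf)              # divide sample by its expression ratio to ref
  f / exp(mean(log(f)))
}

#' Log-transform a normalized matrix
#'
#' Replaces each value x by log10(x + 1).
#'
#' @param x raw expression matrix.
#' @return expression matrix with transform `"log10p1"`.
#' @export
log_transform <- function(x) {
  if (expr_transform(x) != "raw") stop("matrix is already log transformed")
  out <- log10(x + 1)
  attr(out, "transform") <- "log10p1"
  out
}

#' Genes expressed in at least one condition
#'
#' A condition is a (species, egg / female embryo / male embryo) cell of the
#' design. A gene is kept when its replicate-mean normalized FPKM exceeds
#' `threshold` in at least one condition of at least one species.
#'
#' @param x raw normalized expression matrix.
#' @param samples sample sheet.
#' @param threshold FPKM threshold (default 1, before log transformation).
#' @return character vector of retained gene ids (input order).
#' @export
filter_expressed <- function(x, samples, threshold = 1) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (expr_transform(x) != "raw") stop("expression filter runs on raw values")
  groups <- condition_groups(samples)
  keep <- rep(FALSE, nrow(x))
  for (ids in groups) {
    mu <- rowMeans(x[, ids, drop = FALSE])
    keep <- keep | mu > threshold
  }
  rownames(x)[keep]
}

# sample-id groups for species x (egg, female embryo, male embryo)
condition_groups <- function(samples) {
  key <- ifelse(samples$stage == "egg", "egg", paste0("embryo_", samples$sex))
  split(samples$sample_id, paste(samples$species, key, sep = "."))
}
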