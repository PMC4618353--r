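#' Brownian-motion variance of a character on a phylogeny
#'
#' Restricted-maximum-likelihood estimate of the Brownian-motion rate
#' (sigma^2, squared trait units per unit branch length) from
#' phylogenetically independent contrasts: sigma^2 = sum(c_i^2) / (n - 1)
#' over the n - 1 standardized contrasts of the pruning recursion.
#'
#' @param tip_values named numeric vector, one value per tree tip.
#' @param tree a `phylo` tree with positive total length (see
#'   [read_tree()]).
#' @return the REML rate estimate (0 when all tip values are equal).
#' @export
bm_variance <- function(tip_values, tree) {
  if (is.null(names(tip_values)))
    stop("tip values must be named by species")
  if (!all(tree$tip.label %in% names(tip_values)))
    stop("missing tip value for: ",
         paste(setdiff(tree$tip.label, names(tip_values)), collapse = ", "))
  if (anyNA(tip_values)) stop("missing tip value")
  x <- tip_values[tree$tip.label]
  pics <- ape::pic(x, tree)
  sum(pics^2) / (length(x) - 1)
}

#' Brownian-motion variance for every row of a species matrix
#'
#' @param values genes x species matrix of (log) expression levels.
#' @param tree phylogeny over the species.
#' @return numeric vector of per-gene sigma^2 estimates.
#' @export
bm_variance_profile <- function(values, tree) {
  tree <- check_tree(tree, colnames(values))
  # contrasts are a fixed linear map of tip values; build it once
  n <- ncol(values)
  basis <- diag(n); rownames(basis) <- colnames(values)
  cmat <- apply(basis, 2, function(e) ape::pic(e[tree$tip.label], tree))
  cmat <- matrix(cmat, nrow = n - 1)
  contrasts <- values[, tree$tip.label, drop = FALSE] %*% t(cmat)
  rowSums(contrasts^2) / (n - 1)
}

#' Chromosome effect on expression divergence (one-way ANOVA)
#'
#' Tests whether per-gene Brownian-motion variances differ between Muller
#' elements. Degenerate inputs with zero residual variance return p = 1.
#'
#' @param variances named numeric vector of per-gene sigma^2 (names are
#'   orthogroup ids).
#' @param annotation gene annotation.
#' @param log_scale if `TRUE`, test log10(sigma^2 + eps) instead.
#' @param eps offset used on the log scale.
#' @return list: `F`, `df`, `p.value`, `n_groups`.
#' @export
chromosome_anova <- function(variances, annotation, log_scale = FALSE,
                             eps = 1e-8) {
  mull <- annotation$muller[match(names(variances), annotation$orthogroup_id)]
  keep <- !is.na(mull)
  v <- variances[keep]; g <- factor(mull[keep])
  small <- names(table(g))[table(g) < 2]   # singleton elements carry no
  if (length(small)) {                     # within-group information
    keep2 <- !g %in% small
    v <- v[keep2]; g <- droplevels(g[keep2])
  }
  if (nlevels(g) < 2) stop("ANOVA needs at least two Muller elements")
  if (log_scale) v <- log10(v + eps)
  if (stats::var(v) == 0)
    return(list(F = NA_real_, df = c(nlevels(g) - 1, length(v) - nlevels(g)),
                p.value = 1, n_groups = nlevels(g)))
  fit <- stats::anova(stats::lm(v ~ g))
  list(F = fit$`F value`[1], df = fit$Df, p.value = fit$`Pr(>F)`[1],
       n_groups = nlevels(g))
}

#' Per-chromosome Spearman correlation between two species
#'
#' Expression divergence of a chromosome is read as 1 - rho, so lower
#' correlation means higher divergence.
#'
#' @param a,b named numeric vectors of (log) expression for the shared
#'   orthogroups of the two species.
#' @param annotation gene annotation.
#' @param min_genes minimum genes per element (smaller elements dropped).
#' @return data.frame: `muller`, `n`, `rho`.
#' @export
chromosome_correlation <- function(a, b, annotation, min_genes = 3) {
  ids <- intersect(names(a), names(b))
  if (!length(ids)) stop("no shared orthogroups")
  mull <- annotation$muller[match(ids, annotation$orthogroup_id)]
  out <- lapply(sort(unique(mull)), function(e) {
    sel <- ids[mull == e]
    if (length(sel) < min_genes) return(NULL)
    if (stats::sd(a[sel]) == 0 || stats::sd(b[sel]) == 0) return(NULL)
    data.frame(muller = e, n = length(sel),
               rho = stats::cor(a[sel], b[sel], method = "spearman"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bootstrap support for higher divergence on the X
#'
#' Genes are resampled with replacement within each Muller element B times
#' and the per-element Spearman correlation recomputed. The support for a
#' more divergent X is the fraction of replicates in which the X element's
#' correlation is lower than that of every autosomal element
#' (`comparison = "all"`, the strict reading) or lower than the median
#' autosomal correlation (`comparison = "median"`).
#'
#' @param a,b named expression vectors for one species pair and condition.
#' @param annotation gene annotation.
#' @param B number of bootstrap replicates.
#' @param seed integer seed (replicate streams are drawn element by element
#'   in alphabetical order, so results are reproducible).
#' @param x_element the X element (default Muller A).
#' @param autosome_elements elements treated as autosomes for this pair;
#'   by default all elements except `x_element`, minus Muller D when
#'   `neo_x_species` is part of the pair (set via `exclude`).
#' @param exclude elements to leave out entirely (e.g. `"D"` for a pair
#'   involving the neo-X species).
#' @param comparison `"all"` (X below every autosome) or `"median"` (X
#'   below the median autosomal correlation).
#' @param min_genes minimum genes per element.
#' @return list: `support`, `B`, `rho` (observed per element),
#'   `boot` (B x elements matrix of bootstrap correlations).
#' @export
bootstrap_support <- function(a, b, annotation, B = 10000, seed = 1,
                              x_element = "A", autosome_elements = NULL,
                              exclude = character(),
                              comparison = c("all", "median"),
                              min_genes = 100) {
  if (B < 1) stop("B must be >= 1")
  comparison <- match.arg(comparison)
  obs <- chromosome_correlation(a, b, annotation, min_genes = min_genes)
  obs <- obs[!obs$muller %in% exclude, ]
  if (is.null(autosome_elements))
    autosome_elements <- setdiff(obs$muller, x_element)
  elements <- c(x_element, autosome_elements)
  if (!all(elements %in% obs$muller))
    stop("element missing from correlation table: ",
         paste(setdiff(elements, obs$muller), collapse = ", "))
  ids <- intersect(names(a), names(b))
  mull <- annotation$muller[match(ids, annotation$orthogroup_id)]
  set.seed(seed)
  boot <- sapply(elements, function(e) {
    sel <- ids[mull == e]
    av <- a[sel]; bv <- b[sel]
    n <- length(sel)
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      stats::cor(av[idx], bv[idx], method = "spearman")
    }, 0)
  })
  boot <- matrix(boot, nrow = B, dimnames = list(NULL, elements))
  auto <- boot[, autosome_elements, drop = FALSE]
  ref <- if (comparison == "all") apply(auto, 1, min)
         else apply(auto, 1, stats::median)
  list(support = mean(boot[, x_element] < ref), B = B,
       rho = stats::setNames(obs$rho[match(elements, obs$muller)], elements),
       boot = boot)
}
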