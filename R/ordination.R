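#' Correspondence analysis of an expression matrix
#'
#' Classical correspondence analysis via singular value decomposition of
#' the standardized residuals of the relative-frequency matrix. Rows are
#' genes, columns samples. Zero-sum rows or columns are dropped with a
#' warning. Axis signs are fixed deterministically: the largest-magnitude
#' column (sample) coordinate on each axis is made positive.
#'
#' @param x non-negative matrix (genes x samples), raw scale.
#' @param n_axes maximum number of axes to keep.
#' @return object of class `"embryodiv_ca"`: `row_coords`, `col_coords`
#'   (principal coordinates), `sv` (singular values), `eig` (inertias) for
#'   the kept axes, `eig_all`/`explained_all` for the full spectrum
#'   (the latter sums to 1), `explained` (kept axes' shares of total
#'   inertia), `row_mass`, `col_mass`, `genes`, `samples`.
#' @export
correspondence_analysis <- function(x, n_axes = 4) {
  if (any(x < 0)) stop("correspondence analysis needs a non-negative matrix")
  rs <- rowSums(x); cs <- colSums(x)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " zero-sum rows dropped")
    x <- x[rs > 0, , drop = FALSE]
  }
  if (any(cs == 0)) {
    warning(sum(cs == 0), " zero-sum columns dropped")
    x <- x[, cs > 0, drop = FALSE]
  }
  N <- sum(x)
  if (N <= 0) stop("matrix has zero grand total")
  P <- x / N
  r <- rowSums(P); c <- colSums(P)
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(S)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps * 100
  keep <- which(sv$d > max(tol, 1e-12))
  keep <- utils::head(keep, n_axes)
  if (!length(keep)) {
    out <- list(row_coords = NULL, col_coords = NULL, sv = numeric(0),
                eig = numeric(0), explained = numeric(0),
                eig_all = numeric(0), explained_all = numeric(0),
                row_mass = r, col_mass = c,
                genes = rownames(x), samples = colnames(x),
                total_inertia = 0)
    class(out) <- "embryodiv_ca"
    return(out)
  }
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]; V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest |column standard coordinate| positive
  for (k in seq_along(keep)) {
    vstd <- V[, k] / sqrt(c)
    if (vstd[which.max(abs(vstd))] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  F_ <- sweep(U, 1, sqrt(r), `/`) %*% diag(d, length(d))
  G_ <- sweep(V, 1, sqrt(c), `/`) %*% diag(d, length(d))
  dimnames(F_) <- list(rownames(x), paste0("Axis", seq_along(d)))
  dimnames(G_) <- list(colnames(x), paste0("Axis", seq_along(d)))
  all_pos <- sv$d[sv$d > max(tol, 1e-12)]
  total_inertia <- sum(all_pos^2)
  out <- list(row_coords = F_, col_coords = G_, sv = d, eig = d^2,
              explained = d^2 / total_inertia,
              eig_all = all_pos^2, explained_all = all_pos^2 / total_inertia,
              row_mass = r, col_mass = c,
              genes = rownames(x), samples = colnames(x),
              total_inertia = total_inertia)
  class(out) <- "embryodiv_ca"
  out
}

#' @export
print.embryodiv_ca <- function(x, ...) {
  cat("Correspondence analysis:", length(x$genes), "genes x",
      length(x$samples), "samples\n")
  if (length(x$eig)) {
    cat("Explained inertia per axis:\n")
    print(round(x$explained, 4))
  } else cat("No axes (independence table)\n")
  invisible(x)
}

#' Project supplementary profiles onto a correspondence analysis
#'
#' Supplementary columns (e.g. pooled-embryo samples) are placed by the
#' transition formula: the profile-weighted average of the gene principal
#' coordinates, divided by each axis' singular value. Projecting an active
#' sample's own profile reproduces its coordinates.
#'
#' @param ca an `"embryodiv_ca"` object.
#' @param profiles non-negative matrix (genes x new samples) over the same
#'   genes as the active analysis (same order).
#' @return matrix of principal coordinates (new samples x axes).
#' @export
project_supplementary <- function(ca, profiles) {
  if (is.null(dim(profiles))) profiles <- cbind(profile = profiles)
  if (!length(ca$eig)) stop("analysis has no axes to project onto")
  if (nrow(profiles) != length(ca$genes) ||
      !is.null(rownames(profiles)) &&
      !identical(rownames(profiles), ca$genes))
    stop("supplementary profiles must cover the active gene set")
  if (any(profiles < 0)) stop("supplementary profiles must be non-negative")
  tot <- colSums(profiles)
  if (any(tot == 0)) stop("supplementary profile has zero total")
  h <- sweep(profiles, 2, tot, `/`)
  coords <- t(h) %*% ca$row_coords %*% diag(1 / ca$sv, length(ca$sv))
  colnames(coords) <- colnames(ca$row_coords)
  coords
}
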