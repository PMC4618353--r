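#' Plug-in residual variance from replicate scatter
#'
#' The noise model of the degradation analysis is Gaussian with a single
#' variance shared by all genes: the mean, over genes and conditions
#' (species x stage), of the within-condition replicate variance of
#' non-log expression values. Conditions with fewer than two replicates
#' carry no information and are skipped.
#'
#' @param x raw expression matrix.
#' @param samples sample sheet.
#' @param genes gene subset (typically the conserved maternal set).
#' @return `sigma2`, a positive scalar.
#' @export
estimate_noise <- function(x, samples, genes = NULL) {
  if (expr_transform(x) != "raw") stop("noise is estimated on non-log values")
  if (is.null(genes)) genes <- rownames(x)
  groups <- split(samples$sample_id, paste(samples$species, samples$stage))
  groups <- Filter(function(ids) length(ids) >= 2, groups)
  if (!length(groups)) stop("no condition has two or more replicates")
  vars <- sapply(groups, function(ids)
    apply(x[genes, ids, drop = FALSE], 1, stats::var))
  sigma2 <- mean(vars)
  if (sigma2 <= 0) stop("replicate variance is zero; set sigma2 explicitly")
  sigma2
}

#' Fit the one-step degradation rate for one species
#'
#' The kinetic model is embryo = egg * (1 - r) + epsilon. All replicates
#' are used, not their averages: the objective is the sum of squared
#' residuals over every (egg replicate, embryo replicate) pairing, whose
#' minimizer has the closed form
#' r* = 1 - (sum(egg) * sum(embryo)) / (n_embryo * sum(egg^2)),
#' clipped to `bounds`.
#'
#' @param egg,embryo numeric replicate vectors (non-log).
#' @param bounds allowed rate interval (default `c(0, 1)`).
#' @return list: `r`, `rss` (at the clipped rate), `at_boundary`.
#' @export
fit_rate <- function(egg, embryo, bounds = c(0, 1)) {
  if (!length(egg) || !length(embryo)) stop("need egg and embryo replicates")
  if (all(egg == 0)) stop("all egg values are zero; rate undefined")
  b <- sum(egg) * sum(embryo) / (length(embryo) * sum(egg^2))
  r <- 1 - b
  r_clip <- min(max(r, bounds[1]), bounds[2])
  list(r = r_clip, rss = pair_rss(egg, embryo, 1 - r_clip),
       at_boundary = r_clip != r)
}

pair_rss <- function(egg, embryo, b) {
  # sum over all egg x embryo pairings of (embryo - egg*b)^2
  n_e <- length(egg); n_m <- length(embryo)
  n_e * sum(embryo^2) - 2 * b * sum(egg) * sum(embryo) + b^2 * n_m * sum(egg^2)
}

#' Fit a species-common degradation rate
#'
#' Single rate minimizing the pooled pairing objective across species.
#'
#' @param reps named list (by species) of `list(egg =, embryo =)` replicate
#'   vectors.
#' @param bounds allowed rate interval.
#' @return list: `r`, `rss`, `at_boundary`.
#' @export
fit_shared_rate <- function(reps, bounds = c(0, 1)) {
  num <- den <- 0
  for (d in reps) {
    if (all(d$egg == 0)) stop("all egg values are zero in one species")
    num <- num + sum(d$egg) * sum(d$embryo)
    den <- den + length(d$embryo) * sum(d$egg^2)
  }
  b <- num / den
  r <- 1 - b
  r_clip <- min(max(r, bounds[1]), bounds[2])
  bc <- 1 - r_clip
  list(r = r_clip,
       rss = sum(vapply(reps, function(d) pair_rss(d$egg, d$embryo, bc), 0)),
       at_boundary = r_clip != r)
}

#' Degradation-rate model selection across species
#'
#' Fits, for every gene of the maternal set, the species-common and the
#' species-specific degradation models, computes Gaussian log-likelihoods
#' with the shared plug-in variance, and selects genes with species-specific
#' rates by a likelihood-ratio test (chi-squared with `df` degrees of
#' freedom, Benjamini-Hochberg corrected) combined with a fold-change
#' filter on the fitted rates (floored at `rate_floor` before taking
#' ratios).
#'
#' @param x raw normalized expression matrix.
#' @param samples sample sheet.
#' @param maternal_set orthogroup ids to fit (conserved maternal genes).
#' @param sigma2 plug-in residual variance; estimated via
#'   [estimate_noise()] when `NULL`.
#' @param df degrees of freedom of the LRT (4 by this pipeline's
#'   convention; note the nested models differ by 3 free parameters).
#' @param alpha BH-adjusted significance cutoff.
#' @param fold_threshold minimum max/min rate ratio between species.
#' @param bounds rate bounds.
#' @param rate_floor floor applied to rates before fold computation.
#' @return data.frame of class `"degradation_fit"`: per-gene common and
#'   per-species rates, log-likelihoods, `lrt_stat`, `p_value`, `q_value`,
#'   `fold_range`, `species_specific`.
#' @export
degradation_lrt <- function(x, samples, maternal_set, sigma2 = NULL,
                            df = 4, alpha = 0.001, fold_threshold = 2,
                            bounds = c(0, 1), rate_floor = 0.01) {
  if (df < 1) stop("df must be >= 1")
  species <- unique(samples$species)
  if (is.null(sigma2)) sigma2 <- estimate_noise(x, samples, maternal_set)
  stopifnot(sigma2 > 0)
  ids <- lapply(stats::setNames(species, species), function(sp) list(
    egg = samples$sample_id[samples$species == sp & samples$stage == "egg"],
    embryo = samples$sample_id[samples$species == sp & samples$stage == "embryo"]))
  for (sp in species)
    if (!length(ids[[sp]]$egg) || !length(ids[[sp]]$embryo))
      stop("species ", sp, " lacks egg or embryo samples")
  n_pairings <- sum(vapply(ids, function(d) length(d$egg) * length(d$embryo), 0))
  const <- -0.5 * n_pairings * log(2 * pi * sigma2)
  rows <- lapply(maternal_set, function(g) {
    reps <- lapply(ids, function(d) list(egg = x[g, d$egg], embryo = x[g, d$embryo]))
    fits <- lapply(reps, function(d) fit_rate(d$egg, d$embryo, bounds = bounds))
    common <- fit_shared_rate(reps, bounds = bounds)
    rss_s <- sum(vapply(fits, `[[`, 0, "rss"))
    ll_s <- const - rss_s / (2 * sigma2)
    ll_c <- const - common$rss / (2 * sigma2)
    r_sp <- vapply(fits, `[[`, 0, "r")
    rf <- pmax(r_sp, rate_floor)
    out <- data.frame(orthogroup_id = g, r_common = common$r,
                      loglik_common = ll_c, loglik_specific = ll_s,
                      lrt_stat = max(0, 2 * (ll_s - ll_c)),
                      fold_range = max(rf) / min(rf),
                      at_boundary = common$at_boundary ||
                        any(vapply(fits, `[[`, TRUE, "at_boundary")),
                      stringsAsFactors = FALSE)
    for (sp in species) out[[paste0("r_", sp)]] <- r_sp[[sp]]
    out
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::pchisq(out$lrt_stat, df = df, lower.tail = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$species_specific <- out$q_value <= alpha & out$fold_range > fold_threshold
  attr(out, "sigma2") <- sigma2
  attr(out, "df") <- df
  attr(out, "species") <- species
  class(out) <- c("degradation_fit", "data.frame")
  out
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat("Maternal degradation-rate fits:", nrow(x), "genes,",
      sum(x$species_specific), "with species-specific rates\n")
  cat("Plug-in residual variance:", format(attr(x, "sigma2"), digits = 4),
      "; LRT df =", attr(x, "df"), "\n")
  invisible(x)
}

#' @export
summary.degradation_fit <- function(object, ...) {
  sp <- attr(object, "species")
  cat("Genes fitted:            ", nrow(object), "\n")
  cat("Species-specific rates:  ", sum(object$species_specific),
      sprintf("(%.1f%%)\n", 100 * mean(object$species_specific)))
  cat("Common-rate quartiles:   ",
      paste(format(stats::quantile(object$r_common, c(.25, .5, .75)),
                   digits = 3), collapse = " / "), "\n")
  for (s in sp)
    cat(sprintf("  median r (%s): %.3f\n", s,
                stats::median(object[[paste0("r_", s)]])))
  invisible(object)
}

#' Rate divergence versus expression divergence
#'
#' For genes flagged with species-specific rates, correlates the
#' between-species difference in fitted degradation rate with the
#' difference in mean log10(FPKM + 1) level in embryos and in eggs,
#' per species pair and pooled over pairs (Spearman).
#'
#' @param fit a `"degradation_fit"` table.
#' @param x log-transformed expression matrix.
#' @param samples sample sheet.
#' @param min_genes minimum flagged genes required (default 10).
#' @return list: `pairs` (per-pair rho for embryo and egg) and `pooled`
#'   (rho over all pairs combined); `NULL` with a warning when fewer than
#'   `min_genes` genes are flagged.
#' @export
rate_vs_expression_divergence <- function(fit, x, samples, min_genes = 10) {
  flagged <- fit$orthogroup_id[fit$species_specific]
  if (length(flagged) < min_genes) {
    warning("fewer than ", min_genes, " flagged genes; no correlation computed")
    return(NULL)
  }
  if (expr_transform(x) != "log10p1")
    stop("expression divergence uses log10(FPKM + 1) values")
  species <- attr(fit, "species")
  means <- function(sp, stage) {
    ids <- samples$sample_id[samples$species == sp & samples$stage == stage]
    rowMeans(x[flagged, ids, drop = FALSE])
  }
  emb <- sapply(species, means, stage = "embryo")
  egg <- sapply(species, means, stage = "egg")
  rates <- sapply(species, function(sp) fit[[paste0("r_", sp)]][fit$species_specific])
  pairs <- utils::combn(species, 2, simplify = FALSE)
  per <- do.call(rbind, lapply(pairs, function(pr) {
    dr <- rates[, pr[1]] - rates[, pr[2]]
    data.frame(species_a = pr[1], species_b = pr[2], n = length(dr),
      rho_embryo = stats::cor(dr, emb[, pr[1]] - emb[, pr[2]], method = "spearman"),
      rho_egg = stats::cor(dr, egg[, pr[1]] - egg[, pr[2]], method = "spearman"),
      stringsAsFactors = FALSE)
  }))
  dr <- de <- dg <- c()
  for (pr in pairs) {
    dr <- c(dr, rates[, pr[1]] - rates[, pr[2]])
    de <- c(de, emb[, pr[1]] - emb[, pr[2]])
    dg <- c(dg, egg[, pr[1]] - egg[, pr[2]])
  }
  list(pairs = per,
       pooled = c(rho_embryo = stats::cor(dr, de, method = "spearman"),
                  rho_egg = stats::cor(dr, dg, method = "spearman"),
                  n = length(flagged)))
}
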