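#' Simulate a four-species egg/embryo expression study with ground truth
#'
#' Generates an FPKM matrix, sample sheet, annotation, phylogeny and truth
#' table emulating the structure of a single-embryo blastoderm study:
#' roughly 6,000 1:1:1:1 orthologs measured in 2-3 female embryos,
#' 2-3 male embryos and 1-2 unfertilized eggs per species, with Muller
#' elements A-F and a neo-X (Muller D X-linked in one species only).
#'
#' Generative model, per gene: an ancestral embryo level is drawn
#' log-normally and split into a maternal fraction (1 for Mat genes, 0 for
#' Zyg, intermediate for MatZyg); egg deposition and the zygotic component
#' evolve independently along the tree by Brownian motion on the log10
#' scale with a per-gene rate; the maternal embryo component is
#' egg * (1 - r) with a per-gene degradation rate that is species-specific
#' (>= 2-fold spread) for a configured fraction of maternal genes. Zygotic
#' components carry a small conserved sex effect, and X-linked genes
#' (Muller A everywhere, Muller D in the neo-X species) are split between
#' dosage-compensated (female = male) and uncompensated (male halved)
#' states. Maternal transcripts are deposited before fertilization and are
#' identical in the two sexes. Replicates receive multiplicative
#' log-normal noise whose coefficient of variation shrinks with abundance
#' (a baseline biological CV plus a counting-like term).
#'
#' @param n_genes number of orthogroups (>= 100).
#' @param species four species names; `neo_x_species` must be one of them.
#' @param neo_x_species species in which Muller D is X-linked.
#' @param tree Newick string or `phylo`; default is the four-taxon
#'   topology ((sp1,sp2),(sp3,sp4)) with unit terminal branches.
#' @param n_female,n_male,n_egg replicates per species.
#' @param class_props proportions of Mat / Zyg / MatZyg genes.
#' @param muller_props Muller element proportions (A-F).
#' @param level_log10_mean,level_log10_sd ancestral embryo level
#'   distribution (log10 FPKM); either scalars or per-class named vectors
#'   (maternally loaded genes are more abundant than nascent zygotic
#'   transcription at this stage).
#' @param sex_effect_sd spread (log2) of the conserved zygotic sex effect.
#' @param dosage_uncompensated fraction of X-linked zygotic signal without
#'   dosage compensation.
#' @param matzyg_maternal_frac range of the maternal fraction of MatZyg
#'   genes.
#' @param r_range degradation-rate range for species-common genes.
#' @param prop_specific_r fraction of maternal-containing genes with
#'   species-specific rates.
#' @param fold_range range of the max/min rate ratio for species-specific
#'   genes.
#' @param r_lo_min lower bound of the smallest species rate for
#'   species-specific genes.
#' @param bm_sigma2_range per-gene Brownian-motion rate range (log10
#'   units^2 per unit branch length), drawn log-uniformly; equal bounds fix
#'   the value.
#' @param egg_x_sigma_mult multiplier of the egg-deposition BM rate on
#'   Muller A (4 reproduces a faster-X signal restricted to eggs; 1 = none).
#' @param cv0 baseline biological CV of replicate noise.
#' @param counting_k counting-noise constant; the per-replicate standard
#'   deviation on the natural-log scale is sqrt(cv0^2 + counting_k / level).
#' @param seed integer seed; all draws flow from it.
#' @return list of class `"embryodiv_sim"`: `expression` (raw FPKM matrix),
#'   `samples`, `annotation`, `tree`, `truth`, `params`.
#' @export
simulate_dataset <- function(n_genes = 6000,
                             species = c("mel", "yak", "pse", "vir"),
                             neo_x_species = "pse",
                             tree = NULL,
                             n_female = 3, n_male = 3, n_egg = 2,
                             class_props = c(Mat = 0.45, Zyg = 0.15, MatZyg = 0.40),
                             muller_props = c(A = 0.16, B = 0.19, C = 0.21,
                                              D = 0.20, E = 0.23, F = 0.01),
                             level_log10_mean = c(Mat = 1.7, Zyg = 1.2,
                                                  MatZyg = 1.4),
                             level_log10_sd = c(Mat = 0.6, Zyg = 0.6,
                                                MatZyg = 0.7),
                             sex_effect_sd = 0.12,
                             dosage_uncompensated = 0.5,
                             matzyg_maternal_frac = c(0.05, 0.35),
                             r_range = c(0.1, 0.9),
                             prop_specific_r = 0.5,
                             fold_range = c(2, 4),
                             r_lo_min = 0.1,
                             bm_sigma2_range = c(0.005, 0.05),
                             egg_x_sigma_mult = 1,
                             cv0 = 0.03, counting_k = 1,
                             seed = 1) {
  if (n_genes < 100) stop("n_genes must be >= 100")
  if (length(species) != 4) stop("the design uses four species")
  if (!neo_x_species %in% species) stop("neo_x_species must be one of `species`")
  if (abs(sum(class_props) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (min(n_female, n_male, n_egg) < 1) stop("replicate counts must be >= 1")
  if (is.null(tree))
    tree <- sprintf("((%s:1,%s:1):0.5,(%s:1,%s:1):0.5);",
                    species[1], species[2], species[3], species[4])
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tree <- check_tree(tree, species)

  set.seed(seed)
  ids <- sprintf("og%05d", seq_len(n_genes))
  muller <- sample(names(muller_props), n_genes, TRUE, prob = muller_props)
  cls <- sample(names(class_props), n_genes, TRUE, prob = class_props)
  lv_mu <- rep_len(level_log10_mean, 3)
  lv_sd <- rep_len(level_log10_sd, 3)
  if (is.null(names(lv_mu))) names(lv_mu) <- c("Mat", "Zyg", "MatZyg")
  if (is.null(names(lv_sd))) names(lv_sd) <- c("Mat", "Zyg", "MatZyg")
  lvl <- 10^stats::rnorm(n_genes, lv_mu[cls], lv_sd[cls])
  matfrac <- ifelse(cls == "Mat", 1, ifelse(cls == "Zyg", 0,
                    stats::runif(n_genes, matzyg_maternal_frac[1],
                                 matzyg_maternal_frac[2])))
  delta <- stats::rnorm(n_genes, 0, sex_effect_sd)
  dosage <- ifelse(muller %in% c("A", "D") & matfrac < 1,
                   ifelse(stats::runif(n_genes) < dosage_uncompensated,
                          "uncompensated", "compensated"), "none")

  # degradation rates (genes with a maternal component)
  has_mat <- matfrac > 0
  r_common <- stats::runif(n_genes, r_range[1], r_range[2])
  specific <- has_mat & stats::runif(n_genes) < prop_specific_r
  R <- matrix(r_common, n_genes, 4, dimnames = list(ids, species))
  if (any(specific)) {
    idx <- which(specific)
    Ff <- stats::runif(length(idx), fold_range[1], fold_range[2])
    r_lo <- stats::runif(length(idx), r_lo_min, pmin(r_range[2] / Ff, r_range[2]))
    for (i in seq_along(idx)) {
      u <- c(0, stats::runif(2), 1)[sample.int(4)]
      R[idx[i], ] <- r_lo[i] * Ff[i]^u
    }
    r_common[idx] <- exp(rowMeans(log(R[idx, , drop = FALSE])))
  }
  R[!has_mat, ] <- NA_real_

  # Brownian motion along the tree (log10 scale)
  sig2 <- if (bm_sigma2_range[1] == bm_sigma2_range[2]) {
    rep(bm_sigma2_range[1], n_genes)
  } else exp(stats::runif(n_genes, log(bm_sigma2_range[1]),
                          log(bm_sigma2_range[2])))
  sig2_egg <- sig2 * ifelse(muller == "A", egg_x_sigma_mult, 1)
  C <- ape::vcv(tree)[species, species]
  CL <- chol(C)
  bm_draw <- function(s2) {
    z <- matrix(stats::rnorm(n_genes * 4), n_genes, 4) %*% CL
    z * sqrt(s2)
  }
  bmE <- bm_draw(sig2_egg)   # egg deposition divergence
  bmZ <- bm_draw(sig2)       # zygotic component divergence

  anc_r <- ifelse(has_mat, r_common, NA_real_)
  E0 <- ifelse(has_mat, matfrac * lvl / (1 - pmin(anc_r, 0.99)), 0)
  Z0 <- (1 - matfrac) * lvl

  sdln <- function(mu) sqrt(cv0^2 + counting_k / pmax(mu, 1e-9))
  noisy <- function(mu, n_rep) {
    # one column per replicate; zero means stay exactly zero
    vapply(seq_len(n_rep), function(j) {
      out <- mu * exp(stats::rnorm(length(mu), 0, sdln(mu)))
      out[mu == 0] <- 0
      out
    }, numeric(length(mu)))
  }

  cols <- list(); sheet <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    egg_sp <- E0 * 10^bmE[, si]
    z_sp <- Z0 * 10^bmZ[, si]
    maternal <- ifelse(has_mat, egg_sp * (1 - R[, si]), 0)
    xl <- muller == "A" | (muller == "D" & sp == neo_x_species)
    z_f <- z_sp * 2^(delta / 2)
    z_m <- z_sp * 2^(-delta / 2) *
      ifelse(xl & dosage == "uncompensated", 0.5, 1)
    blocks <- list(egg = noisy(egg_sp, n_egg),
                   female = noisy(maternal + z_f, n_female),
                   male = noisy(maternal + z_m, n_male))
    for (what in names(blocks)) {
      b <- blocks[[what]]
      n_rep <- ncol(b)
      colnames(b) <- paste(sp, what, seq_len(n_rep), sep = ".")
      cols[[length(cols) + 1]] <- b
      sheet[[length(sheet) + 1]] <- data.frame(
        sample_id = colnames(b), species = sp,
        stage = if (what == "egg") "egg" else "embryo",
        sex = if (what == "egg") "na" else what,
        replicate = seq_len(n_rep), stringsAsFactors = FALSE)
    }
  }
  expr <- do.call(cbind, cols)
  rownames(expr) <- ids
  samples <- do.call(rbind, sheet)
  validate_sample_info(samples)

  truth <- data.frame(orthogroup_id = ids, muller = muller,
                      origin_class = cls, maternal_fraction = matfrac,
                      base_level = lvl, sex_effect = delta, dosage = dosage,
                      bm_sigma2 = sig2, bm_sigma2_egg = sig2_egg,
                      r_common = ifelse(has_mat, r_common, NA_real_),
                      specific_r = specific, stringsAsFactors = FALSE)
  for (si in seq_along(species)) truth[[paste0("r_", species[si])]] <- R[, si]

  out <- list(expression = expression_matrix(expr, "raw"),
              samples = samples,
              annotation = gene_annotation(ids, muller, neo_x_species),
              tree = tree, truth = truth,
              params = list(n_genes = n_genes, species = species,
                            neo_x_species = neo_x_species,
                            n_female = n_female, n_male = n_male,
                            n_egg = n_egg, seed = seed,
                            egg_x_sigma_mult = egg_x_sigma_mult,
                            cv0 = cv0, counting_k = counting_k))
  class(out) <- "embryodiv_sim"
  out
}

#' @export
print.embryodiv_sim <- function(x, ...) {
  cat("Synthetic four-species egg/embryo dataset:",
      nrow(x$expression), "genes x", ncol(x$expression), "samples\n")
  cat("Origin classes:", paste(names(table(x$truth$origin_class)),
                               table(x$truth$origin_class), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate conserved maternal genes for degradation studies
#'
#' A focused generator for the degradation-rate machinery: per gene and
#' species an egg deposition level and embryo levels following
#' embryo = egg * (1 - r), with either multiplicative log-normal replicate
#' noise (`noise = "lognormal"`, CV `cv`) or the kinetic model's own
#' additive Gaussian noise on embryo replicates (`noise = "gaussian"`,
#' standard deviation `gaussian_sd_frac` times the mean deposition level;
#' egg replicates are then noise-free, mimicking a single precisely
#' measured deposition value).
#'
#' @param n_genes number of genes.
#' @param species species names.
#' @param n_egg,n_embryo replicates per species.
#' @param noise `"lognormal"` or `"gaussian"`.
#' @param cv log-normal replicate CV.
#' @param gaussian_sd_frac Gaussian noise scale, as a fraction of the mean
#'   deposition level.
#' @param level_log10_mean,level_log10_sd egg deposition distribution.
#' @param egg_divergence_sd between-species spread (log10) of deposition.
#' @param r_range common-rate range.
#' @param prop_specific fraction of genes with species-specific rates.
#' @param fold_range max/min rate ratio range for specific genes.
#' @param r_lo_min smallest species rate for specific genes.
#' @param seed integer seed.
#' @return list: `expression` (raw matrix), `samples`, `truth` (per-gene
#'   rates and flags), `genes`.
#' @export
simulate_maternal_genes <- function(n_genes = 1000,
                                    species = c("mel", "yak", "pse", "vir"),
                                    n_egg = 3, n_embryo = 3,
                                    noise = c("lognormal", "gaussian"),
                                    cv = 0.1, gaussian_sd_frac = 0.08,
                                    level_log10_mean = 1.3,
                                    level_log10_sd = 0.1,
                                    egg_divergence_sd = 0.045,
                                    r_range = c(0.1, 0.9),
                                    prop_specific = 0,
                                    fold_range = c(2, 4),
                                    r_lo_min = 0.2,
                                    seed = 1) {
  noise <- match.arg(noise)
  set.seed(seed)
  ids <- sprintf("mg%05d", seq_len(n_genes))
  lvl <- 10^stats::rnorm(n_genes, level_log10_mean, level_log10_sd)
  specific <- stats::runif(n_genes) < prop_specific
  R <- matrix(stats::runif(n_genes, r_range[1], r_range[2]), n_genes,
              length(species), dimnames = list(ids, species))
  if (any(specific)) {
    idx <- which(specific)
    Ff <- stats::runif(length(idx), fold_range[1], fold_range[2])
    r_lo <- stats::runif(length(idx), r_lo_min, pmin(r_range[2] / Ff, r_range[2]))
    for (i in seq_along(idx)) {
      u <- c(0, stats::runif(2), 1)[sample.int(length(species))]
      R[idx[i], ] <- r_lo[i] * Ff[i]^u
    }
  }
  E <- lvl * 10^matrix(stats::rnorm(n_genes * length(species), 0,
                                    egg_divergence_sd),
                       n_genes, length(species))
  sd0 <- gaussian_sd_frac * mean(lvl)
  cols <- list(); sheet <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    M <- E[, si] * (1 - R[, si])
    egg_b <- vapply(seq_len(n_egg), function(j)
      if (noise == "lognormal") E[, si] * exp(stats::rnorm(n_genes, 0, cv))
      else E[, si], numeric(n_genes))
    emb_b <- vapply(seq_len(n_embryo), function(j)
      if (noise == "lognormal") M * exp(stats::rnorm(n_genes, 0, cv))
      else pmax(M + stats::rnorm(n_genes, 0, sd0), 0), numeric(n_genes))
    colnames(egg_b) <- paste(sp, "egg", seq_len(n_egg), sep = ".")
    colnames(emb_b) <- paste(sp, "embryo", seq_len(n_embryo), sep = ".")
    cols <- c(cols, list(egg_b, emb_b))
    sheet[[si]] <- data.frame(
      sample_id = c(colnames(egg_b), colnames(emb_b)), species = sp,
      stage = rep(c("egg", "embryo"), c(n_egg, n_embryo)),
      sex = rep(c("na", ""), c(n_egg, n_embryo)), replicate = 1L,
      stringsAsFactors = FALSE)
    emb_rows <- sheet[[si]]$stage == "embryo"
    sheet[[si]]$sex[emb_rows] <- rep(c("female", "male"),
                                     length.out = n_embryo)
    sheet[[si]]$replicate <- c(seq_len(n_egg), seq_len(n_embryo))
  }
  expr <- do.call(cbind, cols)
  rownames(expr) <- ids
  samples <- do.call(rbind, sheet)
  validate_sample_info(samples)
  truth <- data.frame(orthogroup_id = ids, level = lvl,
                      specific_r = specific, stringsAsFactors = FALSE)
  for (si in seq_along(species)) truth[[paste0("r_", species[si])]] <- R[, si]
  list(expression = expression_matrix(expr, "raw"), samples = samples,
       truth = truth, genes = ids, noise = noise,
       sigma2_true = if (noise == "gaussian") sd0^2 else NA_real_)
}

#' Reference origin labels for a simulated dataset
#'
#' Emulates the label set inherited from a previous allele-specific study:
#' transcript-origin labels are available only for genes abundant enough
#' to have been classified there (ancestral level above `min_level`).
#'
#' @param bundle an `"embryodiv_sim"` dataset.
#' @param min_level minimum ancestral FPKM for a gene to carry a label.
#' @return named character vector (orthogroup id -> Mat/Zyg/MatZyg).
#' @export
reference_origin_labels <- function(bundle, min_level = 2) {
  tr <- bundle$truth[bundle$truth$base_level >= min_level, ]
  stats::setNames(tr$origin_class, tr$orthogroup_id)
}

#' Pooled-sample profiles as egg/embryo mixtures
#'
#' Builds supplementary expression profiles emulating pooled collections
#' that mix undeveloped eggs and staged embryos: for each mixing weight
#' lambda, profile = lambda * mean egg profile + (1 - lambda) * mean
#' embryo profile of the species.
#'
#' @param bundle an `"embryodiv_sim"` dataset (or any list with
#'   `expression` and `samples`).
#' @param species species to pool.
#' @param lambdas egg weights of the mixtures.
#' @return matrix (genes x profiles) with names `<species>.pool<lambda>`.
#' @export
simulate_pooled_profiles <- function(bundle, species, lambdas = c(0.25, 0.5, 0.75)) {
  x <- bundle$expression; s <- bundle$samples
  out <- list()
  for (sp in species) {
    egg <- rowMeans(x[, s$sample_id[s$species == sp & s$stage == "egg"],
                      drop = FALSE])
    emb <- rowMeans(x[, s$sample_id[s$species == sp & s$stage == "embryo"],
                      drop = FALSE])
    for (l in lambdas)
      out[[paste0(sp, ".pool", l)]] <- l * egg + (1 - l) * emb
  }
  do.call(cbind, out)
}
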