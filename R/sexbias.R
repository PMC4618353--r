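#' Per-gene sex ratios with a cross-species abundance floor
#'
#' Ratios are computed on non-log expression levels as
#' log2(mean female FPKM / mean male FPKM) per species. To avoid extreme
#' ratios for low-abundance transcripts, a gene is evaluated only when its
#' replicate-mean log2(FPKM) exceeds `floor_log2` for both sexes in every
#' species.
#'
#' @param x raw normalized expression matrix over all species.
#' @param samples sample sheet.
#' @param floor_log2 abundance floor on the mean log2(FPKM) scale.
#' @param genes optional subset of gene ids to evaluate.
#' @return data.frame: `orthogroup_id`, `species`, `female_mean`,
#'   `male_mean`, `log2_ratio` (NA when not evaluated), `evaluated`.
#' @export
compute_sex_ratio <- function(x, samples, floor_log2 = 0.33, genes = NULL) {
  if (expr_transform(x) != "raw") stop("sex ratios use non-log expression levels")
  if (is.null(genes)) genes <- rownames(x)
  x <- x[genes, , drop = FALSE]
  species <- unique(samples$species)
  emb <- samples[samples$stage == "embryo", ]
  means <- list(); floors <- matrix(TRUE, nrow(x), length(species),
                                    dimnames = list(genes, species))
  for (sp in species) {
    for (sx in c("female", "male")) {
      ids <- emb$sample_id[emb$species == sp & emb$sex == sx]
      if (!length(ids)) stop("no ", sx, " embryo samples for species ", sp)
      sub <- x[, ids, drop = FALSE]
      means[[paste(sp, sx)]] <- rowMeans(sub)
      floors[, sp] <- floors[, sp] &
        rowMeans(log2(sub)) > floor_log2
    }
  }
  evaluated <- rowSums(floors) == length(species)
  out <- do.call(rbind, lapply(species, function(sp) {
    f <- means[[paste(sp, "female")]]; m <- means[[paste(sp, "male")]]
    data.frame(orthogroup_id = genes, species = sp,
               female_mean = f, male_mean = m,
               log2_ratio = ifelse(evaluated, log2(f / m), NA_real_),
               evaluated = evaluated, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Rank sex ratios and classify bias
#'
#' Evaluated genes are ranked by their log2 female:male ratio (average
#' ranks for ties); the quantile rank is rank/(n+1) so ranks lie strictly
#' inside (0,1). Genes in the top `top_q` of the ranking are female-biased,
#' the bottom `bottom_q` male-biased, genes inside `unbiased_window`
#' unbiased; remaining evaluated genes are `intermediate` and genes that
#' failed the abundance floor `not_evaluated`.
#'
#' @param ratios data.frame for one species as returned by
#'   [compute_sex_ratio()] (columns `orthogroup_id`, `log2_ratio`,
#'   `evaluated`).
#' @param top_q,bottom_q biased tail fractions (default 0.20 each).
#' @param unbiased_window rank window for unbiased genes (default 0.40-0.60,
#'   inclusive).
#' @return the input with `quantile_rank` and `bias_class` columns added.
#' @export
rank_and_classify <- function(ratios, top_q = 0.20, bottom_q = 0.20,
                              unbiased_window = c(0.40, 0.60)) {
  if (top_q + bottom_q >= 1) stop("top_q + bottom_q must be < 1")
  ev <- which(ratios$evaluated)
  if (length(ev) < 10) stop("fewer than 10 evaluated genes")
  r <- rank(ratios$log2_ratio[ev], ties.method = "average")
  q <- r / (length(ev) + 1)
  rk <- rep(NA_real_, nrow(ratios)); rk[ev] <- q
  cls <- rep("not_evaluated", nrow(ratios))
  cls[ev] <- "intermediate"
  cls[ev][q >= unbiased_window[1] & q <= unbiased_window[2]] <- "unbiased"
  cls[ev][q >= 1 - top_q] <- "female"
  cls[ev][q <= bottom_q] <- "male"
  ratios$quantile_rank <- rk
  ratios$bias_class <- cls
  ratios
}

#' Cross-species sex-bias sets
#'
#' From per-species classified tables over the same orthogroups, builds:
#' genes biased in the same direction in all four species; genes with no
#' female (resp. male) bias in any species, defined by ranks in the bottom
#' (resp. top) `nonbiased_q` of every species' distribution; and
#' species-specific sets of genes biased in exactly one species and
#' unbiased (middle window) in the other three. Genes not evaluated in any
#' species are excluded from every set.
#'
#' @param tables named list (by species) of [rank_and_classify()] outputs.
#' @param nonbiased_q one-sided rank cutoff for the "no bias" sets
#'   (default 0.60).
#' @return list with elements `biased_all_female`, `biased_all_male`,
#'   `nonbiased_all_female_side`, `nonbiased_all_male_side` and
#'   `specific[[species]][[sex]]` (character vectors of orthogroup ids).
#' @export
cross_species_sets <- function(tables, nonbiased_q = 0.60) {
  species <- names(tables)
  if (length(species) < 2) stop("need tables for at least two species")
  ids <- tables[[1]]$orthogroup_id
  for (tb in tables) if (!identical(tb$orthogroup_id, ids))
    stop("species tables must cover the same orthogroups in the same order")
  cls <- sapply(tables, function(tb) tb$bias_class)
  rk <- sapply(tables, function(tb) tb$quantile_rank)
  ok <- rowSums(cls == "not_evaluated") == 0
  all_f <- ok & rowSums(cls == "female") == length(species)
  all_m <- ok & rowSums(cls == "male") == length(species)
  no_f <- ok & rowSums(rk <= nonbiased_q) == length(species)
  no_m <- ok & rowSums(rk >= 1 - nonbiased_q) == length(species)
  specific <- lapply(stats::setNames(species, species), function(sp) {
    others <- setdiff(species, sp)
    lapply(c(female = "female", male = "male"), function(sx) {
      hit <- ok & cls[, sp] == sx &
        rowSums(cls[, others, drop = FALSE] == "unbiased") == length(others)
      ids[hit]
    })
  })
  list(biased_all_female = ids[all_f],
       biased_all_male = ids[all_m],
       nonbiased_all_female_side = ids[no_f],
       nonbiased_all_male_side = ids[no_m],
       specific = specific)
}

#' Chromosomal enrichment of a gene set
#'
#' Compares the observed Muller-element distribution of a gene set with the
#' expectation proportional to the number of (background) genes on each
#' element. Reports the global chi-squared test over elements and, because
#' individual elements are of interest, a 1-df element-versus-rest
#' chi-squared per element. Elements with fewer than `min_element_genes`
#' background genes are dropped (chi-squared validity).
#'
#' @param gene_set character vector of orthogroup ids.
#' @param annotation gene annotation.
#' @param background orthogroup ids defining the expected distribution
#'   (default: all annotated genes).
#' @param min_element_genes minimum background genes per element.
#' @return list with `table` (per-element observed/expected/chi-squared/p)
#'   and `global` (statistic, df, p.value).
#' @export
chromosome_enrichment <- function(gene_set, annotation, background = NULL,
                                  min_element_genes = 20) {
  if (!length(gene_set)) stop("empty gene set")
  if (is.null(background)) background <- annotation$orthogroup_id
  ann <- annotation[annotation$orthogroup_id %in% background, ]
  sizes <- table(ann$muller)
  elements <- names(sizes)[sizes >= min_element_genes]
  ann <- ann[ann$muller %in% elements, ]
  set <- intersect(gene_set, ann$orthogroup_id)
  obs <- table(factor(ann$muller[ann$orthogroup_id %in% set], levels = elements))
  prop <- as.numeric(sizes[elements]) / sum(sizes[elements])
  expd <- length(set) * prop
  chi_g <- sum((as.numeric(obs) - expd)^2 / expd)
  per <- data.frame(muller = elements,
                    n_background = as.numeric(sizes[elements]),
                    observed = as.numeric(obs),
                    expected = expd, stringsAsFactors = FALSE)
  n <- length(set)
  per$chisq <- (per$observed - per$expected)^2 / per$expected +
    ((n - per$observed) - (n - per$expected))^2 / (n - per$expected)
  per$p.value <- stats::pchisq(per$chisq, df = 1, lower.tail = FALSE)
  list(table = per,
       global = list(statistic = chi_g, df = length(elements) - 1,
                     p.value = stats::pchisq(chi_g, length(elements) - 1,
                                             lower.tail = FALSE)))
}

#' Chromosomal distribution of the most sex-biased genes
#'
#' Orders evaluated genes by absolute log2 ratio (ties at the k-th position
#' broken by orthogroup id) and reports, per Muller element, the proportion
#' of the element's genes that are female- and male-biased among the top k.
#'
#' @param ratios classified table for one species.
#' @param annotation gene annotation.
#' @param k number of top genes (default 200).
#' @return data.frame per element: `n_genes`, `n_top_female`, `n_top_male`,
#'   `prop_female`, `prop_male`.
#' @export
top_k_distribution <- function(ratios, annotation, k = 200) {
  ev <- ratios[ratios$evaluated, ]
  if (k > nrow(ev)) stop("k exceeds the number of evaluated genes")
  ord <- order(-abs(ev$log2_ratio), ev$orthogroup_id)
  top <- ev[ord[seq_len(k)], ]
  mull <- annotation$muller[match(ev$orthogroup_id, annotation$orthogroup_id)]
  mull_top <- annotation$muller[match(top$orthogroup_id, annotation$orthogroup_id)]
  elements <- sort(unique(mull))
  out <- data.frame(muller = elements,
                    n_genes = as.numeric(table(factor(mull, elements))),
                    n_top_female = as.integer(table(factor(mull_top[top$log2_ratio > 0], elements))),
                    n_top_male = as.integer(table(factor(mull_top[top$log2_ratio < 0], elements))),
                    stringsAsFactors = FALSE)
  out$prop_female <- out$n_top_female / out$n_genes
  out$prop_male <- out$n_top_male / out$n_genes
  out
}

#' Attribute species-specific sex-bias to a change in females or males
#'
#' For genes biased in a single species s, asks whether the bias arose by a
#' change of female or of male expression relative to a comparison species
#' t. Each sex is examined marginally (the two changes are confounded by
#' shared expression divergence, so they are not forced into a single
#' exclusive call): for a female-biased gene the bias-creating directions
#' are a female increase (F_s > F_t) and a male decrease (M_s < M_t);
#' mirror directions apply for male-biased genes. Each proportion is
#' tested against the null of 0.5 (a gene is equally likely to gain bias
#' through either sex) by a two-sided exact binomial sign test.
#'
#' @param specific_ids orthogroup ids biased only in species `sp`.
#' @param sex `"female"` or `"male"` (direction of the bias in `sp`).
#' @param sp,comparison species names.
#' @param sex_means data.frame from [compute_sex_ratio()] (uses
#'   `female_mean` / `male_mean` per species).
#' @return list: `n`, `n_female_driven`, `n_male_driven` (counts of genes
#'   whose female resp. male expression moved in the bias-creating
#'   direction), `p_female`, `p_male` (binomial sign tests), and the
#'   per-gene logical vectors; `NULL` when the set is empty.
#' @export
attribute_bias_direction <- function(specific_ids, sex, sp, comparison,
                                     sex_means) {
  if (!length(specific_ids)) return(NULL)
  get <- function(species, col) {
    sub <- sex_means[sex_means$species == species, ]
    sub[[col]][match(specific_ids, sub$orthogroup_id)]
  }
  dF <- log2(get(sp, "female_mean") / get(comparison, "female_mean"))
  dM <- log2(get(sp, "male_mean") / get(comparison, "male_mean"))
  female_driven <- if (sex == "female") dF > 0 else dF < 0
  male_driven <- if (sex == "female") dM < 0 else dM > 0
  n <- length(specific_ids)
  list(species = sp, comparison = comparison, sex = sex, n = n,
       n_female_driven = sum(female_driven),
       n_male_driven = sum(male_driven),
       p_female = stats::binom.test(sum(female_driven), n, 0.5)$p.value,
       p_male = stats::binom.test(sum(male_driven), n, 0.5)$p.value,
       female_driven = stats::setNames(female_driven, specific_ids),
       male_driven = stats::setNames(male_driven, specific_ids))
}
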