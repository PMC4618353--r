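#' Run the full comparative pipeline
#'
#' Orchestrates every stage on a consistent input bundle: normalization and
#' log transform, the expression filter, per-species sex-bias
#' classification with cross-species sets, chromosomal enrichment, top-k
#' distribution and bias-direction attribution, per-condition
#' Brownian-motion divergence with chromosome ANOVA (and optional
#' bootstrap correlations), correspondence analysis with supplementary
#' pool projection, transcript-origin classification transferred from a
#' labelled reference species, and the maternal degradation analysis.
#' Results are deterministic given `config$seed`.
#'
#' @param expression raw FPKM expression matrix.
#' @param samples sample sheet.
#' @param annotation gene annotation.
#' @param tree phylogeny over the species (class `phylo`).
#' @param origin_labels named character vector (orthogroup id ->
#'   Mat/Zyg/MatZyg) for the reference species; `NULL` skips the origin and
#'   degradation stages.
#' @param reference_species species the labels belong to (default: first
#'   species in the sample sheet).
#' @param pools optional supplementary profiles (genes x samples) to
#'   project onto the correspondence analysis.
#' @param config an [analysis_config()].
#' @param run_bootstrap compute bootstrap faster-X support for every
#'   species pair and condition (costly at B = 10,000).
#' @param outdir optional directory; stage tables are written as TSV with a
#'   `manifest.txt` of the applied parameters.
#' @return list with one element per stage plus `log` (character vector of
#'   applied thresholds) and `genes` (the filtered gene set).
#' @export
run_pipeline <- function(expression, samples, annotation, tree,
                         origin_labels = NULL, reference_species = NULL,
                         pools = NULL, config = analysis_config(),
                         run_bootstrap = FALSE, outdir = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  species <- unique(samples$species)
  neo_x <- attr(annotation, "neo_x_species")
  set.seed(config$seed)

  ## 1. normalization -------------------------------------------------
  norm <- normalize_expression(expression, annotation,
                               method = config$normalization,
                               anchor_elements = config$anchor_elements)
  note("normalization=", config$normalization, " anchors=",
       paste(config$anchor_elements, collapse = ","))
  logm <- log_transform(norm)

  ## 2. expression filter ---------------------------------------------
  genes <- filter_expressed(norm, samples, config$expression_threshold)
  note("expression_threshold=", config$expression_threshold,
       " genes_kept=", length(genes))

  ## 3. sex bias ------------------------------------------------------
  ratios <- compute_sex_ratio(norm, samples, floor_log2 = config$floor_log2,
                              genes = genes)
  note("floor_log2=", config$floor_log2)
  tables <- lapply(stats::setNames(species, species), function(sp)
    rank_and_classify(ratios[ratios$species == sp, ],
                      top_q = config$top_q, bottom_q = config$bottom_q,
                      unbiased_window = config$unbiased_window))
  note("top_q=", config$top_q, " bottom_q=", config$bottom_q,
       " unbiased=", paste(config$unbiased_window, collapse = "-"))
  sets <- cross_species_sets(tables, nonbiased_q = config$nonbiased_q)
  evaluated <- tables[[1]]$orthogroup_id[tables[[1]]$evaluated]
  enrich <- list(
    biased_all_female = chromosome_enrichment(
      sets$biased_all_female, annotation, background = evaluated,
      min_element_genes = config$min_element_genes),
    nonbiased_all_male_side = chromosome_enrichment(
      sets$nonbiased_all_male_side, annotation, background = evaluated,
      min_element_genes = config$min_element_genes))
  if (!is.na(neo_x) && length(sets$specific[[neo_x]]$female))
    enrich$specific_neo_x_female <- chromosome_enrichment(
      sets$specific[[neo_x]]$female, annotation, background = evaluated,
      min_element_genes = config$min_element_genes)
  topk <- lapply(tables, top_k_distribution, annotation = annotation,
                 k = min(config$top_k, length(evaluated)))
  attribution <- list()
  for (sp in species) for (sx in c("female", "male")) {
    ids_set <- sets$specific[[sp]][[sx]]
    if (!length(ids_set)) next
    for (cmp in setdiff(species, sp))
      attribution[[paste(sp, sx, "vs", cmp, sep = ".")]] <-
        attribute_bias_direction(ids_set, sx, sp, cmp, ratios)
  }

  ## 4. divergence ----------------------------------------------------
  cond_profiles <- function(stage, sex = NULL) {
    sapply(species, function(sp) {
      sel <- samples$species == sp & samples$stage == stage
      if (!is.null(sex)) sel <- sel & samples$sex == sex
      rowMeans(logm[genes, samples$sample_id[sel], drop = FALSE])
    })
  }
  has_eggs <- any(samples$stage == "egg")
  conditions <- list(female = cond_profiles("embryo", "female"),
                     male = cond_profiles("embryo", "male"))
  if (has_eggs) conditions$egg <- cond_profiles("egg")
  divergence <- lapply(conditions, function(prof) {
    v <- bm_variance_profile(prof, tree)
    names(v) <- genes
    list(bm_variance = v,
         anova = chromosome_anova(v, annotation))
  })
  if (run_bootstrap) {
    note("bootstrap_B=", config$bootstrap_B)
    for (cond in names(conditions)) {
      prof <- conditions[[cond]]
      boots <- list()
      for (pr in utils::combn(species, 2, simplify = FALSE)) {
        excl <- if (!is.na(neo_x) && neo_x %in% pr) "D" else character()
        a <- stats::setNames(prof[, pr[1]], genes)
        b <- stats::setNames(prof[, pr[2]], genes)
        boots[[paste(pr, collapse = ".")]] <- bootstrap_support(
          a, b, annotation, B = config$bootstrap_B,
          seed = config$seed + length(boots), exclude = excl,
          min_genes = config$min_bootstrap_genes)
      }
      divergence[[cond]]$bootstrap <- boots
    }
  }

  ## 5. ordination ----------------------------------------------------
  singles <- samples$sample_id
  ca <- correspondence_analysis(norm[genes, singles, drop = FALSE])
  projection <- NULL
  if (!is.null(pools))
    projection <- project_supplementary(ca, pools[genes, , drop = FALSE])

  ## 6. transcript origin ----------------------------------------------
  origin <- degradation <- NULL
  if (!is.null(origin_labels) && !has_eggs) {
    warning("no egg samples; origin and degradation stages skipped")
    note("origin/degradation skipped: no egg samples")
  }
  if (!is.null(origin_labels) && has_eggs) {
    if (is.null(reference_species)) reference_species <- species[1]
    feats <- lapply(stats::setNames(species, species), function(sp)
      origin_features(logm, samples, sp, genes = genes))
    lab_ids <- intersect(names(origin_labels), genes)
    classifier <- train_origin_classifier(
      feats[[reference_species]][lab_ids, , drop = FALSE],
      origin_labels[lab_ids],
      gamma = config$svm_gamma, cost = config$svm_cost,
      seed = config$seed, holdout = TRUE)
    note("svm gamma=", config$svm_gamma, " cost=", config$svm_cost,
         " thresholds=", paste(config$origin_thresholds, collapse = "/"))
    calls <- lapply(feats, function(f)
      classify_origin(classifier, f, thresholds = config$origin_thresholds))
    origin <- list(classifier = classifier, calls = calls,
                   conservation = origin_conservation(calls),
                   maternal_set = conserved_maternal_set(calls))

    ## 7. degradation --------------------------------------------------
    if (length(origin$maternal_set)) {
      fit <- degradation_lrt(norm, samples, origin$maternal_set,
                             df = config$lrt_df, alpha = config$bh_alpha,
                             fold_threshold = config$fold_threshold,
                             bounds = config$rate_bounds,
                             rate_floor = config$rate_floor)
      note("lrt_df=", config$lrt_df, " bh_alpha=", config$bh_alpha,
           " fold_threshold=", config$fold_threshold)
      corr <- tryCatch(rate_vs_expression_divergence(fit, logm, samples),
                       warning = function(w) { note("divergence correlation: ",
                                                    conditionMessage(w)); NULL })
      degradation <- list(fit = fit, correlation = corr)
    }
  }

  result <- list(normalized = norm, log_expression = logm, genes = genes,
                 sex_bias = list(ratios = ratios, tables = tables,
                                 sets = sets, enrichment = enrich,
                                 top_k = topk, attribution = attribution),
                 divergence = divergence,
                 ordination = list(ca = ca, projection = projection),
                 origin = origin, degradation = degradation,
                 log = log, config = config)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(result$normalized,
                          file.path(outdir, "normalized_fpkm.tsv"))
  bias <- do.call(rbind, result$sex_bias$tables)
  write_table_tsv(bias, file.path(outdir, "sex_bias.tsv"))
  for (nm in names(result$sex_bias$enrichment))
    write_table_tsv(result$sex_bias$enrichment[[nm]]$table,
                    file.path(outdir, paste0("enrichment_", nm, ".tsv")))
  div <- do.call(rbind, lapply(names(result$divergence), function(cond)
    data.frame(orthogroup_id = names(result$divergence[[cond]]$bm_variance),
               condition = cond,
               bm_variance = result$divergence[[cond]]$bm_variance,
               row.names = NULL)))
  write_table_tsv(div, file.path(outdir, "bm_variance.tsv"))
  if (!is.null(result$origin)) {
    calls <- do.call(rbind, lapply(names(result$origin$calls), function(sp)
      cbind(species = sp, result$origin$calls[[sp]])))
    write_table_tsv(calls, file.path(outdir, "origin_calls.tsv"))
  }
  if (!is.null(result$degradation))
    write_table_tsv(as.data.frame(result$degradation$fit),
                    file.path(outdir, "degradation_fits.tsv"))
  writeLines(result$log, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}
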