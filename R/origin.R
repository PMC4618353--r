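#' Egg/embryo feature matrix for origin classification
#'
#' Features are the per-gene mean log10(FPKM + 1) level in eggs and in
#' embryos (all embryo replicates, sexes pooled) of one species.
#'
#' @param x log-transformed expression matrix.
#' @param samples sample sheet.
#' @param species species name.
#' @param genes optional gene subset.
#' @return matrix with columns `egg` and `embryo`.
#' @export
origin_features <- function(x, samples, species, genes = NULL) {
  if (expr_transform(x) != "log10p1")
    stop("origin features are computed on log10(FPKM + 1) values")
  if (is.null(genes)) genes <- rownames(x)
  egg_ids <- samples$sample_id[samples$species == species & samples$stage == "egg"]
  emb_ids <- samples$sample_id[samples$species == species & samples$stage == "embryo"]
  if (!length(egg_ids)) stop("no egg samples for species ", species)
  if (!length(emb_ids)) stop("no embryo samples for species ", species)
  cbind(egg = rowMeans(x[genes, egg_ids, drop = FALSE]),
        embryo = rowMeans(x[genes, emb_ids, drop = FALSE]))
}

#' Train the transcript-origin classifier
#'
#' A radial-basis support vector machine (C-classification, probability
#' estimates) learns the three transcript-origin classes Mat (maternal
#' only), Zyg (zygotic only) and MatZyg from the 2-D egg/embryo feature
#' space of a labelled reference species.
#'
#' @param features numeric matrix from [origin_features()].
#' @param labels factor or character with levels among Mat/Zyg/MatZyg.
#' @param gamma,cost radial-kernel width and soft-margin cost.
#' @param seed integer seed (probability calibration is stochastic).
#' @param holdout if `TRUE`, fit on a stratified 2/3 sample and report the
#'   1/3 holdout confusion before refitting on all genes.
#' @return object of class `"origin_classifier"`: the fitted `svm` model,
#'   the training fingerprint, and (optionally) `holdout` with `confusion`,
#'   `class_accuracy` and the holdout calls.
#' @export
train_origin_classifier <- function(features, labels, gamma = 0.01, cost = 10,
                                    seed = 1, holdout = FALSE) {
  labels <- factor(as.character(labels), levels = c("Mat", "Zyg", "MatZyg"))
  labels <- droplevels(labels)
  if (anyNA(labels)) stop("labels must be Mat, Zyg or MatZyg")
  if (nlevels(labels) < 2) stop("need at least two classes to train")
  if (!all(is.finite(features))) stop("non-finite features")
  fit_svm <- function(xx, yy) {
    set.seed(seed)
    e1071::svm(x = xx, y = yy, kernel = "radial", type = "C-classification",
               gamma = gamma, cost = cost, probability = TRUE)
  }
  out <- list(gamma = gamma, cost = cost, seed = seed,
              feature_names = colnames(features))
  if (holdout) {
    set.seed(seed)
    idx_tr <- unlist(lapply(split(seq_along(labels), labels), function(i)
      sample(i, round(2 / 3 * length(i)))))
    m <- fit_svm(features[idx_tr, , drop = FALSE], labels[idx_tr])
    pred <- predict_origin_prob(m, features[-idx_tr, , drop = FALSE])
    truth <- labels[-idx_tr]
    call <- factor(colnames(pred)[max.col(pred)], levels = levels(labels))
    conf <- table(truth = truth, predicted = call)
    out$holdout <- list(
      confusion = conf,
      class_accuracy = diag(prop.table(conf, 1)),
      probabilities = pred, truth = truth)
  }
  out$model <- fit_svm(features, labels)
  class(out) <- "origin_classifier"
  out
}

predict_origin_prob <- function(model, features) {
  pr <- attr(stats::predict(model, features, probability = TRUE),
             "probabilities")
  pr[, intersect(c("Mat", "Zyg", "MatZyg"), colnames(pr)), drop = FALSE]
}

#' @export
print.origin_classifier <- function(x, ...) {
  cat("Transcript-origin SVM (radial kernel, gamma =", x$gamma,
      ", cost =", x$cost, ")\n")
  if (!is.null(x$holdout)) {
    cat("Holdout class accuracy:\n")
    print(round(x$holdout$class_accuracy, 3))
  }
  invisible(x)
}

#' Classify transcript origin in a target species
#'
#' Applies a trained classifier; the call is the class with the highest
#' probability and is flagged high-confidence when that probability meets
#' the class-specific threshold.
#'
#' @param classifier an `"origin_classifier"`.
#' @param features feature matrix for the target species (same
#'   normalization as training, see [origin_features()]).
#' @param thresholds named per-class probability thresholds.
#' @return data.frame: `orthogroup_id`, `origin_class`, `probability`,
#'   `confidence` (`"high"`/`"low"`), plus the three class probabilities.
#' @export
classify_origin <- function(classifier, features,
                            thresholds = c(Mat = 0.8, Zyg = 0.7, MatZyg = 0.8)) {
  if (!identical(colnames(features), classifier$feature_names))
    stop("feature columns do not match the trained model")
  pr <- predict_origin_prob(classifier$model, features)
  if (any(abs(rowSums(pr) - 1) > 1e-6))
    stop("internal error: class probabilities do not sum to 1")
  cls <- colnames(pr)[max.col(pr, ties.method = "first")]
  p <- pr[cbind(seq_len(nrow(pr)), max.col(pr, ties.method = "first"))]
  data.frame(orthogroup_id = rownames(features),
             origin_class = cls, probability = p,
             confidence = ifelse(p >= thresholds[cls], "high", "low"),
             pr, row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-species conservation of transcript origin
#'
#' For every species pair, counts genes with conserved origin
#' (Mat-Mat, Zyg-Zyg, MatZyg-MatZyg), genes switching between maternal and
#' zygotic origin with high confidence in both species (Mat-Zyg), and
#' everything else (`other`: any low-confidence switch or MatZyg
#' involvement in a switch).
#'
#' @param calls named list (by species) of [classify_origin()] tables over
#'   the same orthogroups.
#' @return data.frame with one row per species pair.
#' @export
origin_conservation <- function(calls) {
  species <- names(calls)
  if (length(species) < 2) stop("need calls for at least two species")
  ids <- calls[[1]]$orthogroup_id
  pairs <- utils::combn(species, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- calls[[pr[1]]]; b <- calls[[pr[2]]]
    stopifnot(identical(a$orthogroup_id, ids), identical(b$orthogroup_id, ids))
    same <- a$origin_class == b$origin_class
    switch_mz <- ((a$origin_class == "Mat" & b$origin_class == "Zyg") |
                  (a$origin_class == "Zyg" & b$origin_class == "Mat")) &
                 a$confidence == "high" & b$confidence == "high"
    data.frame(species_a = pr[1], species_b = pr[2],
               mat_mat = sum(same & a$origin_class == "Mat"),
               zyg_zyg = sum(same & a$origin_class == "Zyg"),
               matzyg_matzyg = sum(same & a$origin_class == "MatZyg"),
               mat_zyg = sum(switch_mz),
               other = sum(!same & !switch_mz),
               stringsAsFactors = FALSE)
  }))
}

#' Genes maternal with high confidence in every species
#'
#' The conserved maternal set that feeds the degradation analysis.
#'
#' @param calls named list (by species) of [classify_origin()] tables.
#' @return character vector of orthogroup ids.
#' @export
conserved_maternal_set <- function(calls) {
  if (length(calls) < 1) stop("no origin calls supplied")
  ids <- calls[[1]]$orthogroup_id
  hit <- Reduce(`&`, lapply(calls, function(tb) {
    stopifnot(identical(tb$orthogroup_id, ids))
    tb$origin_class == "Mat" & tb$confidence == "high"
  }))
  ids[hit]
}
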