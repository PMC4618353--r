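#' Construct an expression matrix
#'
#' An expression matrix is a numeric matrix of non-negative abundances
#' (FPKM) or log-transformed values, with unique gene identifiers as row
#' names, unique sample identifiers as column names and a `transform`
#' attribute recording the scale (`"raw"` or `"log10p1"`).
#'
#' @param values numeric matrix with row and column names.
#' @param transform `"raw"` (FPKM) or `"log10p1"` (log10(FPKM + 1)).
#' @return the validated matrix with its `transform` attribute set.
#' @export
expression_matrix <- function(values, transform = c("raw", "log10p1")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix must not contain missing values")
  if (transform == "raw" && any(values < 0))
    stop("raw expression matrix must be non-negative")
  attr(values, "transform") <- transform
  values
}

#' Scale of an expression matrix
#'
#' @param x an expression matrix created by [expression_matrix()].
#' @return `"raw"` or `"log10p1"`; matrices without the attribute are
#'   treated as raw.
#' @export
expr_transform <- function(x) {
  tr <- attr(x, "transform")
  if (is.null(tr)) "raw" else tr
}

#' Construct and validate a sample sheet
#'
#' @param sample_id,species,stage,sex,replicate vectors of equal length.
#'   `stage` is `"egg"` or `"embryo"`; `sex` is `"female"`, `"male"` or
#'   `"na"` (eggs are deposited before fertilization and carry no sex).
#' @return a `data.frame` with one row per sample.
#' @export
sample_info <- function(sample_id, species, stage, sex, replicate) {
  s <- data.frame(sample_id = as.character(sample_id),
                  species = as.character(species),
                  stage = as.character(stage),
                  sex = as.character(sex),
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  validate_sample_info(s)
  s
}

validate_sample_info <- function(samples) {
  need <- c("sample_id", "species", "stage", "sex", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample id in sample sheet")
  if (!all(samples$stage %in% c("egg", "embryo")))
    stop("stage must be 'egg' or 'embryo'")
  if (!all(samples$sex %in% c("female", "male", "na")))
    stop("sex must be 'female', 'male' or 'na'")
  if (any(samples$stage == "egg" & samples$sex != "na"))
    stop("egg samples must have sex = 'na'")
  if (any(samples$stage == "embryo" & samples$sex == "na"))
    stop("embryo samples must be sexed")
  if (any(samples$replicate < 1)) stop("replicate indices must be >= 1")
  invisible(samples)
}

#' Construct and validate a gene annotation table
#'
#' One record per 1:1:1:1 orthogroup carrying the Muller element (A-F).
#' X linkage is derived: Muller A is the ancestral X in every species, and
#' Muller D is additionally X-linked in the neo-X species.
#'
#' @param orthogroup_id character vector of unique orthogroup ids.
#' @param muller Muller element, one of `"A"`..`"F"`, per orthogroup.
#' @param neo_x_species name of the species in which Muller D is fused to
#'   the X (`NA` for none).
#' @return a `data.frame` with attribute `neo_x_species`.
#' @export
gene_annotation <- function(orthogroup_id, muller, neo_x_species = NA_character_) {
  if (anyDuplicated(orthogroup_id)) stop("duplicated orthogroup id")
  if (!all(muller %in% c("A", "B", "C", "D", "E", "F")))
    stop("muller element must be one of A-F")
  ann <- data.frame(orthogroup_id = as.character(orthogroup_id),
                    muller = as.character(muller),
                    stringsAsFactors = FALSE)
  attr(ann, "neo_x_species") <- neo_x_species
  ann
}

#' X-linked Muller elements for a species
#'
#' @param species species name.
#' @param neo_x_species species in which Muller D is X-linked.
#' @return character vector of X-linked elements.
#' @export
x_linked_elements <- function(species, neo_x_species = NA_character_) {
  if (!is.na(neo_x_species) && identical(species, neo_x_species)) c("A", "D") else "A"
}

#' Default analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one list:
#' normalization method and anchor elements, the expression filter,
#' sex-bias quantile cutoffs and abundance floor, bootstrap settings,
#' SVM hyperparameters with per-class confidence thresholds, and the
#' degradation-model options.
#'
#' @param ... named overrides of the defaults.
#' @return a list of class `"embryodiv_config"`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    normalization = "p75",           # none|median|p75|p95|tmm|quantile
    anchor_elements = c("B", "C", "E"),
    expression_threshold = 1,        # FPKM, before log transform
    top_q = 0.20,
    bottom_q = 0.20,
    unbiased_window = c(0.40, 0.60),
    nonbiased_q = 0.60,              # one-sided "no bias" rank window
    floor_log2 = 0.33,               # mean log2(FPKM) floor, all species
    top_k = 200,
    bootstrap_B = 10000,
    min_element_genes = 20,          # enrichment tests
    min_bootstrap_genes = 100,       # bootstrap / per-element correlations
    svm_gamma = 0.01,
    svm_cost = 10,
    origin_thresholds = c(Mat = 0.8, Zyg = 0.7, MatZyg = 0.8),
    rate_bounds = c(0, 1),
    lrt_df = 4,
    bh_alpha = 0.001,
    fold_threshold = 2,
    rate_floor = 0.01,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$top_q > 0, cfg$top_q < 0.5, cfg$bottom_q > 0, cfg$bottom_q < 0.5,
            cfg$top_q + cfg$bottom_q < 1,
            cfg$unbiased_window[1] > 0, cfg$unbiased_window[2] < 1,
            cfg$unbiased_window[1] < cfg$unbiased_window[2],
            cfg$bootstrap_B >= 1,
            all(cfg$origin_thresholds > 0), all(cfg$origin_thresholds < 1))
  class(cfg) <- "embryodiv_config"
  cfg
}
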