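ratio_stub <- function(ratios, evaluated = rep(TRUE, length(ratios))) {
  data.frame(orthogroup_id = sprintf("g%03d", seq_along(ratios)),
             species = "x", female_mean = NA_real_, male_mean = NA_real_,
             log2_ratio = ifelse(evaluated, ratios, NA_real_),
             evaluated = evaluated, stringsAsFactors = FALSE)
}

test_that("rank classification matches the brute-force oracle", {
  # ten genes, ratios 1..10: top two female, bottom two male, middle two unbiased
  tb <- rank_and_classify(ratio_stub(1:10))
  expect_identical(tb$bias_class[9:10], rep("female", 2))
  expect_identical(tb$bias_class[1:2], rep("male", 2))
  expect_identical(tb$bias_class[5:6], rep("unbiased", 2))
  expect_identical(tb$bias_class[c(3, 4, 7, 8)], rep("intermediate", 4))
  # all-tied ratios: every rank 0.5, all unbiased
  tb2 <- rank_and_classify(ratio_stub(rep(1.3, 12)))
  expect_true(all(tb2$quantile_rank == 0.5))
  expect_true(all(tb2$bias_class == "unbiased"))
  # random vector against an independent sort-based oracle
  set.seed(5)
  r <- rnorm(1000)
  tb3 <- rank_and_classify(ratio_stub(r))
  ord <- order(r)
  oracle <- rep("intermediate", 1000)
  q <- (1:1000) / 1001
  oracle[ord[q <= 0.2]] <- "male"
  oracle[ord[q >= 0.8]] <- "female"
  oracle[ord[q >= 0.4 & q <= 0.6]] <- "unbiased"
  expect_identical(tb3$bias_class, oracle)
  # class counts near round(q * n)
  expect_lte(abs(sum(tb3$bias_class == "female") - 200), 1)
  expect_lte(abs(sum(tb3$bias_class == "male") - 200), 1)
  # invariance under strictly monotone transforms
  tb4 <- rank_and_classify(ratio_stub(exp(r)))
  expect_identical(tb4$bias_class, tb3$bias_class)
})

test_that("class partition covers all orthogroups", {
  set.seed(6)
  ev <- runif(500) > 0.2
  tb <- rank_and_classify(ratio_stub(rnorm(500), ev))
  counts <- table(factor(tb$bias_class,
                         c("female", "male", "unbiased", "intermediate",
                           "not_evaluated")))
  expect_identical(sum(counts), 500L)
  expect_identical(unname(counts[["not_evaluated"]]), sum(!ev))
})

test_that("the abundance floor marks genes not evaluated before any ratio", {
  sheet <- do.call(rbind, lapply(c("mel", "yak", "pse", "vir"), function(sp)
    data.frame(sample_id = paste(sp, c("f1", "f2", "m1", "m2"), sep = "."),
               species = sp, stage = "embryo",
               sex = c("female", "female", "male", "male"), replicate = c(1, 2, 1, 2))))
  x <- matrix(8, 3, nrow(sheet),
              dimnames = list(c("g1", "g2", "g3"), sheet$sample_id))
  x["g2", "vir.m1"] <- 0                     # zero male replicate in one species
  x["g3", sheet$sex == "female"] <- 8        # female mean 8, male mean 2
  x["g3", sheet$sex == "male"] <- 2
  rt <- compute_sex_ratio(expression_matrix(x, "raw"), sheet)
  g1 <- rt[rt$orthogroup_id == "g1", ]
  expect_true(all(g1$evaluated))
  expect_equal(g1$log2_ratio, rep(0, 4))
  expect_false(any(rt$evaluated[rt$orthogroup_id == "g2"]))
  expect_true(all(is.na(rt$log2_ratio[rt$orthogroup_id == "g2"])))
  expect_equal(rt$log2_ratio[rt$orthogroup_id == "g3"], rep(2, 4))
})

test_that("cross-species sets follow the strict definitions", {
  ids <- paste0("g", 1:6)
  mk <- function(cls, rk) {
    tb <- bias_table_stub(ids, cls, rk)
    tb
  }
  # g1 female everywhere; g2 female in pse only, unbiased elsewhere;
  # g3 female in pse, intermediate in one; g4 unbiased everywhere;
  # g5 not evaluated in one species; g6 male everywhere
  tables <- list(
    mel = mk(c("female", "unbiased", "female", "unbiased", "female", "male"),
             c(.9, .5, .85, .45, .95, .05)),
    yak = mk(c("female", "unbiased", "unbiased", "unbiased", "female", "male"),
             c(.9, .55, .5, .5, .9, .1)),
    pse = mk(c("female", "female", "female", "unbiased", "female", "male"),
             c(.95, .9, .9, .52, .9, .02)),
    vir = mk(c("female", "unbiased", "intermediate", "unbiased",
               "not_evaluated", "male"),
             c(.85, .41, .7, .6, NA, .15)))
  sets <- cross_species_sets(tables)
  expect_identical(sets$biased_all_female, "g1")
  expect_identical(sets$biased_all_male, "g6")
  expect_identical(sets$specific$pse$female, "g2")
  expect_false("g3" %in% unlist(sets$specific))
  expect_true("g4" %in% sets$nonbiased_all_female_side)
  expect_false("g5" %in% unlist(sets[c("biased_all_female",
                                       "nonbiased_all_female_side")]))
  # one-sided windows: male-biased genes have no female bias
  expect_true("g6" %in% sets$nonbiased_all_female_side)
})

test_that("chromosome enrichment matches closed-form arithmetic", {
  ids <- sprintf("g%03d", 1:100)
  ann <- toy_annotation(ids, rep(c("A", "B"), each = 50))
  res <- chromosome_enrichment(ids[c(1:20, 51:60)], ann)
  expect_equal(res$table$expected, c(15, 15))
  expect_equal(res$global$statistic, 10 / 3)
  expect_equal(res$global$df, 1)
  expect_equal(sum(res$table$expected), 30)
  # uniform draw gives a flat distribution
  set.seed(7)
  unif <- sample(ids, 40)
  res2 <- chromosome_enrichment(unif, ann)
  expect_equal(sum(res2$table$expected), 40)
  expect_gt(res2$global$p.value, 0.001)
  # tiny elements are dropped
  ann3 <- toy_annotation(ids, c(rep("A", 49), "F", rep("B", 50)))
  res3 <- chromosome_enrichment(ids[1:30], ann3, min_element_genes = 20)
  expect_false("F" %in% res3$table$muller)
})

test_that("top-k distribution equals a brute-force sort oracle", {
  set.seed(8)
  n <- 120
  rt <- ratio_stub(rnorm(n))
  ann <- toy_annotation(rt$orthogroup_id, sample(c("A", "B", "C"), n, TRUE))
  k <- 30
  res <- top_k_distribution(rt, ann, k = k)
  ord <- order(-abs(rt$log2_ratio), rt$orthogroup_id)
  top <- rt[ord[1:k], ]
  for (e in res$muller) {
    on_e <- ann$orthogroup_id[ann$muller == e]
    expect_identical(res$n_top_female[res$muller == e],
                     sum(top$orthogroup_id %in% on_e & top$log2_ratio > 0))
    expect_equal(res$prop_female[res$muller == e],
                 sum(top$orthogroup_id %in% on_e & top$log2_ratio > 0) /
                   length(on_e))
  }
  # k = n reproduces the full-set proportions
  res_all <- top_k_distribution(rt, ann, k = n)
  expect_equal(sum(res_all$n_top_female + res_all$n_top_male), n)
  expect_error(top_k_distribution(rt, ann, k = n + 1), "exceeds")
})

test_that("bias-direction attribution uses exact binomial sign tests", {
  ids <- paste0("g", 1:8)
  # all eight genes: male expression lower in pse, female unchanged
  sm <- rbind(
    data.frame(orthogroup_id = ids, species = "pse", female_mean = 10,
               male_mean = 4, log2_ratio = NA, evaluated = TRUE),
    data.frame(orthogroup_id = ids, species = "mel", female_mean = 10,
               male_mean = 8, log2_ratio = NA, evaluated = TRUE))
  res <- attribute_bias_direction(ids, "female", "pse", "mel", sm)
  expect_identical(res$n_male_driven, 8L)
  expect_equal(res$p_male, 2 * 0.5^8)
  # a 4/4 split is the symmetric null
  sm2 <- sm
  sm2$male_mean[sm2$species == "pse"] <- c(rep(2, 4), rep(16, 4))
  res2 <- attribute_bias_direction(ids, "female", "pse", "mel", sm2)
  expect_identical(res2$n_male_driven, 4L)
  expect_equal(res2$p_male, 1)
  # empty set yields no test
  expect_null(attribute_bias_direction(character(), "female", "pse", "mel", sm))
})
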