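test_that("simulation is deterministic given the seed", {
  a <- simulate_dataset(n_genes = 300, seed = 11)
  b <- simulate_dataset(n_genes = 300, seed = 11)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(n_genes = 300, seed = 12)
  expect_false(identical(unclass(a$expression), unclass(c$expression)))
})

test_that("noise-free kinetics are exact", {
  sim <- simulate_dataset(n_genes = 200, seed = 13, cv0 = 0, counting_k = 0,
                          bm_sigma2_range = c(0, 0), prop_specific_r = 0)
  s <- sim$samples
  mat <- sim$truth$origin_class == "Mat"
  for (sp in c("mel", "vir")) {
    egg <- sim$expression[mat, s$sample_id[s$species == sp & s$stage == "egg"][1]]
    emb <- sim$expression[mat, s$sample_id[s$species == sp & s$sex == "female"]]
    r <- sim$truth[[paste0("r_", sp)]][mat]
    expect_equal(unname(emb[, 1]), unname(egg * (1 - r)), tolerance = 1e-12)
    expect_equal(emb[, 1], emb[, 2], tolerance = 1e-12)  # replicates identical
  }
})

test_that("the generated bundle satisfies its structural invariants", {
  sim <- simulate_dataset(n_genes = 500, seed = 14)
  expect_true(all(sim$expression >= 0))
  expect_identical(nrow(sim$truth), 500L)
  expect_identical(sort(sim$truth$orthogroup_id),
                   sort(rownames(sim$expression)))
  # class counts in the matrix equal truth-table tallies
  expect_identical(table(sim$truth$origin_class),
                   table(sim$truth$origin_class[
                     match(rownames(sim$expression),
                           sim$truth$orthogroup_id)]))
  # purely zygotic genes are absent from eggs
  zyg <- sim$truth$orthogroup_id[sim$truth$origin_class == "Zyg"]
  eggs <- sim$samples$sample_id[sim$samples$stage == "egg"]
  expect_true(all(sim$expression[zyg, eggs] == 0))
  # eggs are sexless in the sheet
  expect_true(all(sim$samples$sex[sim$samples$stage == "egg"] == "na"))
  # species-specific rates spread at least the configured fold
  sp_cols <- paste0("r_", c("mel", "yak", "pse", "vir"))
  R <- as.matrix(sim$truth[sim$truth$specific_r, sp_cols])
  expect_true(all(apply(R, 1, max) / apply(R, 1, min) >= 2 - 1e-9))
  # dosage states only on X-linked zygotic-containing genes
  expect_true(all(sim$truth$muller[sim$truth$dosage != "none"] %in% c("A", "D")))
  expect_error(simulate_dataset(n_genes = 50), "n_genes")
  expect_error(simulate_dataset(class_props = c(Mat = .5, Zyg = .1,
                                                MatZyg = .1)), "sum to 1")
})

test_that("uncompensated X-linked zygotic genes are female-biased", {
  sim <- simulate_dataset(n_genes = 2000, seed = 15)
  s <- sim$samples
  f <- rowMeans(sim$expression[, s$sample_id[s$species == "mel" &
                                             s$sex == "female"]])
  m <- rowMeans(sim$expression[, s$sample_id[s$species == "mel" &
                                             s$sex == "male"]])
  tr <- sim$truth
  unc <- tr$muller == "A" & tr$dosage == "uncompensated" &
    tr$origin_class == "Zyg"
  aut <- tr$muller %in% c("B", "C", "E") & tr$origin_class == "Zyg"
  expect_gt(median(log2(f / m)[unc]), 0.8)     # close to a full doubling
  expect_lt(abs(median(log2(f / m)[aut])), 0.15)
  # neo-X: Muller D males halved only in the neo-X species
  pse_m <- rowMeans(sim$expression[, s$sample_id[s$species == "pse" &
                                                 s$sex == "male"]])
  pse_f <- rowMeans(sim$expression[, s$sample_id[s$species == "pse" &
                                                 s$sex == "female"]])
  uncD <- tr$muller == "D" & tr$dosage == "uncompensated" &
    tr$origin_class == "Zyg"
  expect_gt(median(log2(pse_f / pse_m)[uncD]), 0.8)
  expect_lt(abs(median(log2(f / m)[uncD])), 0.15)
})

test_that("pooled profiles are exact egg/embryo mixtures", {
  sim <- simulate_dataset(n_genes = 200, seed = 16)
  pools <- simulate_pooled_profiles(sim, "mel", lambdas = 0.5)
  s <- sim$samples
  egg <- rowMeans(sim$expression[, s$sample_id[s$species == "mel" &
                                               s$stage == "egg"]])
  emb <- rowMeans(sim$expression[, s$sample_id[s$species == "mel" &
                                               s$stage == "embryo"]])
  expect_equal(pools[, 1], 0.5 * egg + 0.5 * emb)
})

test_that("reference labels cover only sufficiently expressed genes", {
  sim <- simulate_dataset(n_genes = 400, seed = 17)
  lab <- reference_origin_labels(sim, min_level = 2)
  expect_true(all(sim$truth$base_level[match(names(lab),
                                             sim$truth$orthogroup_id)] >= 2))
  expect_lt(length(lab), 400)
})
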