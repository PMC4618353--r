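test_that("noise estimation is the mean within-condition replicate variance", {
  sheet <- data.frame(
    sample_id = c("m.e1", "m.e2", "m.f1", "m.f2"),
    species = "mel", stage = c("egg", "egg", "embryo", "embryo"),
    sex = c("na", "na", "female", "male"), replicate = c(1, 2, 1, 1))
  x <- matrix(c(9, 11, 5, 5), 1, 4,
              dimnames = list("g1", sheet$sample_id))
  expect_equal(estimate_noise(expression_matrix(x, "raw"), sheet),
               mean(c(var(c(9, 11)), var(c(5, 5)))))
  xc <- matrix(rep(3, 4), 1, 4, dimnames = dimnames(x))
  expect_error(estimate_noise(expression_matrix(xc, "raw"), sheet), "zero")
  # random fixture against a two-pass oracle
  set.seed(19)
  x2 <- matrix(rexp(40), 10, 4, dimnames = list(paste0("g", 1:10),
                                                sheet$sample_id))
  oracle <- mean(c(apply(x2[, 1:2], 1, var), apply(x2[, 3:4], 1, var)))
  expect_equal(estimate_noise(expression_matrix(x2, "raw"), sheet), oracle)
})

test_that("rate fits recover exact kinetics and match a grid search", {
  expect_equal(fit_rate(rep(10, 3), rep(5, 3))$r, 0.5)
  expect_equal(fit_rate(c(5, 5), c(5, 5))$r, 0)
  expect_error(fit_rate(c(0, 0), c(1, 2)), "zero")
  set.seed(20)
  for (i in 1:20) {
    egg <- rexp(3, 0.1) + 1
    emb <- mean(egg) * (1 - runif(1, 0.05, 0.95)) * exp(rnorm(3, 0, 0.2))
    fit <- fit_rate(egg, emb)
    obj <- function(r) sum(outer(egg * (1 - r), emb, function(p, m) (m - p)^2))
    # coarse-to-fine 1e-6 grid around the optimum keeps the oracle cheap
    coarse <- seq(0, 1, by = 1e-3)
    r0 <- coarse[which.min(vapply(coarse, obj, 0))]
    fine <- seq(max(0, r0 - 2e-3), min(1, r0 + 2e-3), by = 1e-6)
    r_star <- fine[which.min(vapply(fine, obj, 0))]
    expect_equal(fit$r, r_star, tolerance = 1e-5)
  }
})

test_that("shared-rate fits pool the objective across species", {
  reps <- list(a = list(egg = rep(10, 2), embryo = rep(8, 2)),
               b = list(egg = rep(10, 2), embryo = rep(2, 2)))
  expect_equal(fit_shared_rate(reps)$r, 0.5)          # rates 0.2 and 0.8
  same <- list(a = list(egg = c(9, 11), embryo = c(5, 6)),
               b = list(egg = c(9, 11), embryo = c(5, 6)))
  expect_equal(fit_shared_rate(same)$r, fit_rate(c(9, 11), c(5, 6))$r)
  # pooled objective at the common rate is the sum of per-species objectives
  fits <- lapply(reps, function(d) fit_rate(d$egg, d$embryo))
  common <- fit_shared_rate(reps)
  expect_gte(common$rss + 1e-9, sum(vapply(fits, `[[`, 0, "rss")))
})

test_that("the LRT table obeys nested-model dominance and BH arithmetic", {
  d <- simulate_maternal_genes(60, seed = 21, prop_specific = 0.5)
  fit <- degradation_lrt(d$expression, d$samples, d$genes)
  expect_true(all(fit$loglik_specific >= fit$loglik_common - 1e-9))
  expect_true(all(fit$lrt_stat >= 0))
  expect_equal(fit$q_value, p.adjust(fit$p_value, "BH"))
  expect_true(all(fit$species_specific ==
                  (fit$q_value <= 0.001 & fit$fold_range > 2)))
  # hand-computed BH on a fixed p-vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # flagging is monotone in alpha and anti-monotone in the fold threshold
  fit_loose <- degradation_lrt(d$expression, d$samples, d$genes, alpha = 0.05)
  expect_true(all(fit$species_specific <= fit_loose$species_specific))
  fit_fold <- degradation_lrt(d$expression, d$samples, d$genes,
                              fold_threshold = 3)
  expect_true(all(fit_fold$species_specific <= fit$species_specific))
})

test_that("identical data across species produce no significant LRT", {
  set.seed(22)
  sheet <- do.call(rbind, lapply(c("mel", "yak", "pse", "vir"), function(sp)
    data.frame(sample_id = paste(sp, c("e1", "f1", "m1"), sep = "."),
               species = sp, stage = c("egg", "embryo", "embryo"),
               sex = c("na", "female", "male"), replicate = 1)))
  egg <- rexp(30, 0.05) + 5
  emb <- egg * 0.6
  x <- matrix(0, 30, nrow(sheet), dimnames = list(paste0("g", 1:30),
                                                  sheet$sample_id))
  x[, grepl("e1", colnames(x))] <- egg
  x[, !grepl("e1", colnames(x))] <- emb
  fit <- degradation_lrt(expression_matrix(x, "raw"), sheet,
                         paste0("g", 1:30), sigma2 = 1)
  expect_true(all(fit$lrt_stat < 1e-8))
  expect_true(all(abs(fit$r_common - 0.4) < 1e-12))
  expect_false(any(fit$species_specific))
})

test_that("rate/expression divergence correlations match a rank oracle", {
  d <- simulate_maternal_genes(300, n_egg = 1, noise = "gaussian",
                               prop_specific = 0.6, seed = 23)
  fit <- degradation_lrt(d$expression, d$samples, d$genes)
  res <- rate_vs_expression_divergence(fit, log_transform(d$expression),
                                       d$samples)
  expect_lt(res$pooled[["rho_embryo"]], -0.5)
  # oracle for one pair
  fl <- fit$orthogroup_id[fit$species_specific]
  dr <- fit$r_mel[fit$species_specific] - fit$r_yak[fit$species_specific]
  lg <- log_transform(d$expression)
  emb_m <- rowMeans(lg[fl, grepl("^mel.embryo", colnames(lg)), drop = FALSE])
  emb_y <- rowMeans(lg[fl, grepl("^yak.embryo", colnames(lg)), drop = FALSE])
  oracle <- cor(rank(dr), rank(emb_m - emb_y))
  row <- res$pairs[res$pairs$species_a == "mel" & res$pairs$species_b == "yak", ]
  expect_equal(row$rho_embryo, oracle)
  # no flagged genes -> warning and NULL
  fit0 <- degradation_lrt(d$expression, d$samples, d$genes, alpha = 1e-12,
                          fold_threshold = 1e6)
  expect_warning(res0 <- rate_vs_expression_divergence(
    fit0, log_transform(d$expression), d$samples), "fewer than")
  expect_null(res0)
})
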