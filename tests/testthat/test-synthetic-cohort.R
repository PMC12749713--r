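test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$bundle, b$bundle)
  expect_identical(a$truth, b$truth)
})

test_that("default block sizes give the designed multimodal feature counts", {
  cfg <- cohort_config(n_participants = 60,
                       n_phenotypes_per_family = c(behavior = 5,
                                                   diagnosis = 5,
                                                   medication = 5))
  sim <- generate_cohort(cfg)
  blocks <- attr(sim$bundle$brain, "blocks")
  expect_equal(sum(blocks == "GMV"), 139)
  expect_equal(sum(blocks == "FA"), 48)
  expect_equal(sum(blocks == "FC"), 210)
  expect_equal(ncol(sim$bundle$brain), 139 + 48 + 210)
})

test_that("the FC block follows the component-pair formula", {
  for (fc in c(2, 4, 7)) {
    cfg <- tiny_config(block_sizes = list(gmv = 5, fa = 3,
                                          fc_components = fc))
    sim <- generate_cohort(cfg)
    expect_equal(sum(attr(sim$bundle$brain, "blocks") == "FC"),
                 fc * (fc - 1) / 2)
  }
})

test_that("planted latent-target correlation hits its configured strength", {
  # Monte-Carlo over seeds at the planted-mode study size
  r <- vapply(1:20, function(s) {
    sim <- generate_cohort(planted_config(seed = s))
    abs(cor(sim$truth$latent_scores[, 1], sim$truth$target))
  }, 0)
  expect_lt(abs(mean(r) - 0.3), 0.05)
  # and the class balance is respected
  sim <- generate_cohort(planted_config(seed = 99))
  expect_lt(abs(mean(sim$truth$target == 1) - planted_config()$target_balance),
            0.04)
})

test_that("with no noise and no leakage the feature matrix has low rank", {
  cfg <- tiny_config(noise_sd = 0, n_background = 0,
                     covariate_spec = list(n_sites = 2, leakage_sd = 0,
                                           sleep_vars = "sleep_duration"))
  sim <- generate_cohort(cfg)
  expect_lte(qr(sim$bundle$brain)$rank, cfg$n_modes)
  expect_equal(unname(sqrt(colSums(sim$truth$true_loadings^2))),
               rep(1, cfg$n_modes), tolerance = 1e-12)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(cohort_config(n_participants = 1), "at least 2")
  expect_error(tiny_config(mode_strengths = c(0.3, 1.2)), "\\[0, 1\\)")
  expect_error(tiny_config(mode_strengths = c(0.2, 0.3)), "non-increasing")
  expect_error(tiny_config(loading_sparsity = 0), "sparsity")
  expect_error(tiny_config(noise_sd = -1), "noise_sd")
  expect_error(tiny_config(mode_strengths = c(0.9, 0.9),
                           target_balance = 0.05), "infeasible")
  expect_error(tiny_config(mode_blocks = list("gmv")), "one entry per mode")
})

test_that("external cohort is GMV-only and shares the planted GMV loadings", {
  src <- generate_cohort(tiny_config(seed = 7))
  ecfg <- external_cohort_config(tiny_config(seed = 7),
                                 n_participants = 150)
  ext <- generate_external_cohort(ecfg, src$truth)
  expect_true(all(attr(ext$bundle$brain, "blocks") == "GMV"))
  gmv <- attr(src$bundle$brain, "blocks") == "GMV"
  for (j in 1:2)
    expect_gte(abs(cor(src$truth$true_loadings[gmv, j],
                       ext$truth$true_loadings[, j])), 0.99)
  expect_true(all(ext$bundle$participants$age >= 107 &
                    ext$bundle$participants$age <= 133))
})

test_that("external cohort reverses the age-latent association sign", {
  signs <- vapply(1:10, function(s) {
    src_cfg <- tiny_config(seed = s, n = 600)
    src <- generate_cohort(src_cfg)
    ext <- generate_external_cohort(
      external_cohort_config(src_cfg, n_participants = 600), src$truth)
    r_src <- cor(src$bundle$participants$age, src$truth$latent_scores[, 1])
    r_ext <- cor(ext$bundle$participants$age, ext$truth$latent_scores[, 1])
    sign(r_src) * sign(r_ext)
  }, 0)
  expect_true(all(signs == -1))
})

test_that("external generation rejects incompatible ground truth", {
  src <- generate_cohort(tiny_config(seed = 1))
  bad <- external_cohort_config(tiny_config(seed = 1))
  bad$block_sizes$gmv <- 99
  expect_error(generate_external_cohort(bad, src$truth), "must match")
})

test_that("pure-noise phenome columns have uniform association p-values", {
  pvals <- unlist(lapply(1:50, function(s) {
    sim <- generate_cohort(tiny_config(seed = 1000 + s, n = 250))
    noise_cols <- setdiff(colnames(sim$bundle$phenome$behavior),
                          sim$truth$phenotype_effect_map$phenotype)
    tab <- association_scan(sim$truth$latent_scores[, 1, drop = FALSE],
                            sim$bundle$phenome$behavior[, noise_cols,
                                                        drop = FALSE],
                            family = "behavior")
    tab$p
  }))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
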