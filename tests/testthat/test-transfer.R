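test_that("full-subset projection reproduces the training transform", {
  d <- random_xy(seed = 1, n = 90, p = 12)
  fit <- chronopls(d$x, d$y, k = 3)
  proj <- build_projection(fit, "all")
  # training rows with the cohort's own statistics = training scores
  sc <- project_cohort(proj, d$x)
  expect_lt(max(abs(sc - fit$T)), 1e-8)
  # and it agrees with predict() on held-out data
  set.seed(2)
  xnew <- matrix(rnorm(7 * 12), 7, 12, dimnames = list(NULL, fit$features))
  sc2 <- project_cohort(proj, xnew, center = proj$x_center,
                        scale = proj$x_scale)
  expect_lt(max(abs(sc2 - predict(fit, xnew))), 1e-8)
})

test_that("k = 1 projection reduces to the scalar closed form", {
  d <- random_xy(seed = 3, n = 60, p = 8)
  fit <- chronopls(d$x, d$y, k = 1)
  sub <- fit$features[1:4]
  proj <- build_projection(fit, sub)
  w <- fit$W[1:4, 1]; p <- fit$P[1:4, 1]
  expect_equal(unname(proj$rotation[, 1]), unname(w / sum(p * w)),
               tolerance = 1e-12)
})

test_that("projection matches the explicit solve-then-multiply oracle", {
  d <- random_xy(seed = 4, n = 80, p = 10)
  fit <- chronopls(d$x, d$y, k = 3)
  sub <- fit$features[c(2, 3, 5, 7, 8, 9)]
  proj <- build_projection(fit, sub)
  set.seed(5)
  xe <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, sub))
  got <- project_cohort(proj, xe)
  # oracle: center/scale externally, then solve (P'W) z = row of (x W)
  mu <- colMeans(xe); sdv <- apply(xe, 2, sd)
  Xs <- sweep(sweep(xe, 2, mu, "-"), 2, sdv, "/")
  PtW <- crossprod(fit$P[sub, ], fit$W[sub, ])
  want <- t(apply(Xs %*% fit$W[sub, ], 1, function(v)
    solve(t(PtW), v)))
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("projection is linear and centering sends the center to zero", {
  d <- random_xy(seed = 6, n = 70, p = 9)
  fit <- chronopls(d$x, d$y, k = 2)
  proj <- build_projection(fit, fit$features[1:5])
  set.seed(7)
  x1 <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, proj$feature_subset))
  x2 <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, proj$feature_subset))
  a <- 1.7; b <- -0.4
  s12 <- project_cohort(proj, a * x1 + b * x2, center = FALSE,
                        scale = FALSE)
  s1 <- project_cohort(proj, x1, center = FALSE, scale = FALSE)
  s2 <- project_cohort(proj, x2, center = FALSE, scale = FALSE)
  expect_lt(max(abs(s12 - (a * s1 + b * s2))), 1e-10)
  # a single row equal to the applied center scores exactly zero
  ctr <- matrix(proj$x_center, 1, dimnames = list(NULL,
                                                  proj$feature_subset))
  expect_lt(max(abs(project_cohort(proj, ctr, center = proj$x_center,
                                   scale = proj$x_scale))), 1e-12)
})

test_that("degenerate subsets and column mismatches are rejected", {
  d <- random_xy(seed = 8, n = 60, p = 8)
  fit <- chronopls(d$x, d$y, k = 3)
  # one feature cannot carry three components: P_sub'W_sub is singular
  expect_error(build_projection(fit, fit$features[1]), "singular")
  expect_error(build_projection(fit, c("nope")), "not in the model")
  proj <- build_projection(fit, fit$features[1:5])
  xe <- matrix(rnorm(10), 2, 5,
               dimnames = list(NULL, c(proj$feature_subset[-1], "zzz")))
  expect_error(project_cohort(proj, xe), "expects")
  expect_error(project_cohort(proj, matrix(1, 2, 3)), "columns")
})

test_that("GMV-only projection recovers the planted external mode", {
  # scaled-down spot check (10-seed study in the acceptance suite)
  cfg <- tiny_config(seed = 31, n = 800, mode_strengths = 0.3, n_modes = 1,
                     mode_blocks = list("gmv"),
                     block_sizes = list(gmv = 30, fa = 6, fc_components = 4))
  sim <- generate_cohort(cfg)
  prep <- preprocess_cohort(sim$bundle)
  fit <- chronopls(prep$x, prep$y, k = 1)
  ext <- generate_external_cohort(
    external_cohort_config(cfg, n_participants = 500), sim$truth)
  eprep <- preprocess_cohort(ext$bundle)
  proj <- build_projection(fit, "GMV")
  sc <- project_cohort(proj, eprep$x)
  expect_gt(abs(cor(sc[, 1], ext$truth$latent_scores[eprep$ids, 1])), 0.8)
})

test_that("age bracket summaries match a group-by oracle", {
  set.seed(9)
  n <- 300
  scores <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("c1", "c2")))
  ages <- runif(n, 40, 70)
  summ <- age_bracket_summary(scores, ages)
  br <- age_brackets_ukb()
  expect_equal(attr(br, "unit"), "years")
  expect_equal(length(br) - 1, 5)        # five adult brackets, 40-70
  expect_equal(nrow(summ), 5 * 2)
  bin <- findInterval(ages, br, rightmost.closed = TRUE)
  for (i in seq_len(nrow(summ))) {
    sel <- bin == match(summ$bracket[i], unique(summ$bracket))
    s <- scores[sel, summ$component[i]]
    expect_equal(summ$n[i], length(s))
    expect_equal(summ$mean[i], mean(s), tolerance = 1e-12)
    expect_equal(summ$sd[i], sd(s), tolerance = 1e-12)
  }
  expect_equal(attr(summ, "n_outside"), 0)
})

test_that("bracket boundaries are left-closed, right-open, last closed", {
  scores <- matrix(1:6, 6, 1)
  ages <- c(39.9, 40, 50, 55, 70, 70.1)
  summ <- age_bracket_summary(scores, ages)
  expect_equal(attr(summ, "n_outside"), 2)   # 39.9 and 70.1
  expect_equal(summ$n[summ$bracket == "[40,50)"], 1)   # age 40
  expect_equal(summ$n[summ$bracket == "[50,55)"], 1)   # 50 goes up, not down
  expect_equal(summ$n[summ$bracket == "[55,60)"], 1)
  expect_equal(summ$n[summ$bracket == "[65,70]"], 1)   # 70 included
})

test_that("sparse and empty brackets are flagged rather than dropped", {
  scores <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  ages <- c(45, 52, 57, 62, 67)
  summ <- age_bracket_summary(scores, ages)       # one participant each
  expect_true(all(summ$n == 1))
  expect_equal(summ$mean, c(1, 2, 3, 4, 5))
  expect_true(all(is.na(summ$sd)))                # sd undefined at n = 1
  summ2 <- age_bracket_summary(scores[1:2, , drop = FALSE], c(45, 46))
  empty <- summ2[summ2$n == 0, ]
  expect_equal(nrow(empty), 4)
  expect_true(all(is.na(empty$mean)))
  expect_error(age_bracket_summary(scores, ages, brackets = c(50, 40)),
               "increasing")
})
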