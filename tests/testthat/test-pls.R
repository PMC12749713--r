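test_that("a feature equal to the target dominates the first component", {
  set.seed(1)
  y <- rep(c(-1, 1), each = 40)
  x <- cbind(sig = y, noise = rnorm(80))
  fit <- chronopls(x, y, k = 1)
  expect_gt(abs(cor(fit$T[, 1], y)), 0.99)
})

test_that("the first weight vector is the cross-covariance direction", {
  d <- random_xy(seed = 2, n = 120, p = 15)
  fit <- chronopls(d$x, d$y, k = 3)
  Xc <- scale(d$x)
  w_oracle <- crossprod(Xc, d$y - mean(d$y))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  cosine <- abs(sum(w_oracle * fit$W[, 1]))
  expect_gt(cosine, 1 - 1e-10)
})

test_that("rotation identity and score orthogonality hold on every fit", {
  for (s in 1:3) {
    d <- random_xy(seed = s, n = 60 + 10 * s, p = 8 + s)
    fit <- chronopls(d$x, d$y, k = 4)
    Xc <- sweep(sweep(d$x, 2, fit$x_center, "-"), 2, fit$x_scale, "/")
    Tr <- Xc %*% fit$W %*% solve(crossprod(fit$P, fit$W))
    expect_lt(max(abs(Tr - fit$T)), 1e-8)
    G <- crossprod(fit$T)
    off <- max(abs(G[upper.tri(G)])) / max(diag(G))
    expect_lt(off, 1e-8)
  }
})

test_that("the sign convention makes the largest weight entry positive", {
  d <- random_xy(seed = 9, n = 100, p = 12)
  fit <- chronopls(d$x, d$y, k = 5)
  for (j in 1:5)
    expect_gt(fit$W[which.max(abs(fit$W[, j])), j], 0)
})

test_that("prediction reproduces training scores and the rotation oracle", {
  d <- random_xy(seed = 3, n = 90, p = 11)
  fit <- chronopls(d$x, d$y, k = 3)
  # training identity
  expect_lt(max(abs(predict(fit, d$x) - fit$T)), 1e-8)
  # a row at the training mean scores zero
  mu <- matrix(fit$x_center, 1, dimnames = list(NULL, fit$features))
  expect_lt(max(abs(predict(fit, mu))), 1e-12)
  # held-out rows against an explicit per-column linear-solve oracle
  set.seed(33)
  xnew <- matrix(rnorm(5 * 11), 5, 11,
                 dimnames = list(NULL, colnames(d$x)))
  Xs <- sweep(sweep(xnew, 2, fit$x_center, "-"), 2, fit$x_scale, "/")
  PtW <- crossprod(fit$P, fit$W)
  k <- ncol(fit$W)
  R_oracle <- sapply(seq_len(k), function(j)
    fit$W %*% solve(PtW, diag(k)[, j]))
  expect_lt(max(abs(predict(fit, xnew) - Xs %*% R_oracle)), 1e-10)
  # column mismatch is rejected naming the first offender
  bad <- xnew
  colnames(bad)[2] <- "wrong"
  expect_error(predict(fit, bad), "wrong")
})

test_that("latent correlations match the textbook Pearson formula", {
  d <- random_xy(seed = 4, n = 70, p = 9)
  fit <- chronopls(d$x, d$y, k = 3)
  rho <- latent_correlation(fit)
  for (j in 1:3)
    expect_equal(rho[j], pearson_oracle(fit$T[, j], d$y), tolerance = 1e-12)
  # perfectly aligned / anti-aligned score columns
  fit$T[, 1] <- d$y
  fit$T[, 2] <- -d$y
  rho2 <- latent_correlation(fit)
  expect_equal(rho2[1], 1)
  expect_equal(rho2[2], -1)
  fit$T[, 3] <- 0
  expect_error(latent_correlation(fit), "zero-variance")
})

test_that("group t-test matches the pooled-variance oracle", {
  set.seed(8)
  s <- rnorm(60)
  g <- rep(c(-1, 1), c(25, 35))
  got <- group_ttest(s, g)
  want <- pooled_t_oracle(s[g == 1], s[g == -1])
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$df, want$df)
  expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
  # degrees of freedom for the full-cohort group sizes
  g2 <- rep(c(-1, 1), c(17995, 9035))
  expect_equal(group_ttest(rnorm(27030), g2)$df, 27028)
  # identical groups give t = 0, p = 1
  same <- c(1, 2, 3, 1, 2, 3)
  got0 <- group_ttest(same, rep(c(-1, 1), each = 3))
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p.value, 1)
  expect_error(group_ttest(1:3, c(-1, 1, 1)), "at least two")
})

test_that("jointly permuting participant rows leaves the model invariant", {
  d <- random_xy(seed = 12, n = 80, p = 10)
  fit <- chronopls(d$x, d$y, k = 3)
  set.seed(99)
  ord <- sample(80)
  fit2 <- chronopls(d$x[ord, ], d$y[ord], k = 3)
  expect_lt(max(abs(fit$W - fit2$W)), 1e-10)
  expect_lt(max(abs(fit$P - fit2$P)), 1e-10)
  expect_lt(max(abs(fit$rho - fit2$rho)), 1e-10)
})

test_that("invalid fits are rejected", {
  d <- random_xy(seed = 13, n = 40, p = 6)
  expect_error(chronopls(d$x, rep(1, 40), k = 1), "single target class")
  expect_error(chronopls(d$x, d$y, k = 0), "k must satisfy")
  expect_error(chronopls(d$x, d$y, k = 7), "k must satisfy")
  # k above the effective rank (rank-1 x) is caught during extraction
  x1 <- tcrossprod(rnorm(40), rnorm(6))
  expect_error(chronopls(x1, d$y, k = 3, scale = FALSE), "effective rank")
  xna <- d$x; xna[1, 1] <- NA
  expect_error(chronopls(xna, d$y, k = 1), "complete")
  xc <- d$x; xc[, 2] <- 5
  expect_error(chronopls(xc, d$y, k = 1), "constant")
})

test_that("fitted, residuals, coef and summary are coherent", {
  d <- random_xy(seed = 14, n = 60, p = 8)
  fit <- chronopls(d$x, d$y, k = 2)
  expect_equal(fitted(fit) + residuals(fit), d$y, tolerance = 1e-12)
  expect_identical(coef(fit), fit$P)
  expect_identical(coef(fit, "weights"), fit$W)
  R <- coef(fit, "rotation")
  expect_lt(max(abs(crossprod(fit$P, R) - diag(2))), 1e-10)
  sm <- summary(fit)
  expect_equal(sm$table$rho, fit$rho)
  expect_true(all(sm$table$x_var_explained > 0 &
                    sm$table$x_var_explained < 1))
  expect_equal(sm$table$df, rep(58, 2))
})

test_that("planted loadings are recovered on the raw feature scale", {
  # scaled-down spot check of the recovery property (full study in the
  # acceptance suite)
  rec <- vapply(1:3, function(s) {
    sim <- generate_cohort(planted_config(seed = 400 + s))
    prep <- preprocess_cohort(sim$bundle)
    fit <- chronopls(prep$x, prep$y, k = 1)
    abs(cor(fit$P[, 1] * fit$x_scale, sim$truth$true_loadings[, 1]))
  }, 0)
  expect_true(all(rec >= 0.9))
})
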