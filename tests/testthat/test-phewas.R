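test_that("correlations match the direct formula and a self-match is a hit", {
  set.seed(1)
  n <- 200
  scores <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("c1", "c2")))
  phe <- cbind(self = scores[, 1], other = rnorm(n),
               binv = as.numeric(runif(n) < 0.3))
  tab <- association_scan(scores, phe, family = "behavior")
  self_row <- tab[tab$component == "c1" & tab$phenotype == "self", ]
  expect_equal(self_row$r, 1)
  expect_true(self_row$significant)
  expect_true(is.finite(self_row$neglog10p))
  for (i in seq_len(nrow(tab))) {
    comp <- match(tab$component[i], colnames(scores))
    expect_equal(tab$r[i],
                 pearson_oracle(scores[, comp], phe[, tab$phenotype[i]]),
                 tolerance = 1e-12)
  }
  # p from the t-transform of r
  row <- tab[tab$component == "c2" & tab$phenotype == "other", ]
  tt <- row$r * sqrt((n - 2) / (1 - row$r^2))
  expect_equal(row$p, 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
  expect_equal(row$neglog10p, -log10(row$p), tolerance = 1e-12)
})

test_that("the Bonferroni threshold divides alpha by the family size", {
  set.seed(2)
  scores <- matrix(rnorm(100), 100, 1)
  phe <- matrix(rnorm(100 * 977), 100, 977)
  tab <- association_scan(scores, phe, family = "behavior")
  expect_equal(unique(tab$threshold), 0.05 / 977)
  expect_identical(unname(tab$significant[tab$status == "ok"]),
                   unname(tab$p[tab$status == "ok"] < 0.05 / 977))
})

test_that("missing data are handled pairwise and locally", {
  set.seed(3)
  n <- 120
  scores <- matrix(rnorm(n), n, 1)
  phe <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("p", 1:4)))
  phe2 <- phe
  phe2[1:30, 2] <- NA
  t1 <- association_scan(scores, phe, family = "behavior")
  t2 <- association_scan(scores, phe2, family = "behavior")
  # only phenotype 2 changes
  expect_equal(t2$r[t2$phenotype != "p2"], t1$r[t1$phenotype != "p2"])
  expect_equal(t2$n_used[t2$phenotype == "p2"], n - 30)
  expect_equal(t2$r[t2$phenotype == "p2"],
               pearson_oracle(scores[-(1:30), 1], phe2[-(1:30), 2]),
               tolerance = 1e-12)
})

test_that("degenerate and under-observed phenotypes are flagged, not dropped", {
  set.seed(4)
  n <- 100
  scores <- matrix(rnorm(n), n, 1)
  phe <- cbind(konst = rep(2, n), sparse = c(rnorm(20), rep(NA, 80)),
               fine = rnorm(n))
  tab <- association_scan(scores, phe, family = "diagnosis", min_n = 50)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$status[tab$phenotype == "konst"], "zero_variance")
  expect_equal(tab$status[tab$phenotype == "sparse"], "untested")
  expect_true(is.na(tab$r[tab$phenotype == "konst"]))
  expect_true(is.na(tab$significant[tab$phenotype == "sparse"]))
  # family size counts only tested phenotypes
  expect_equal(unique(tab$threshold), 0.05 / 1)
  # the 80%-missingness pre-filter
  tab2 <- association_scan(scores, phe, family = "diagnosis", min_n = 5,
                           max_missing = 0.5)
  expect_equal(tab2$status[tab2$phenotype == "sparse"], "untested")
})

test_that("hits are ranked by p with deterministic tie-breaking", {
  set.seed(5)
  tab <- data.frame(
    component = "comp1", family = "behavior",
    phenotype = c("a", "b", "c", "d"),
    category = c("x", "x", "x", "y"),
    r = c(0.5, -0.7, 0.2, 0.4), n_used = 100,
    p = c(1e-4, 1e-4, 0.5, 1e-3),
    neglog10p = -log10(c(1e-4, 1e-4, 0.5, 1e-3)),
    threshold = 0.01,
    significant = c(TRUE, TRUE, FALSE, TRUE),
    status = "ok", stringsAsFactors = FALSE)
  class(tab) <- c("association_table", "data.frame")
  hits <- summarize_hits(tab)
  # ties on p broken by |r| descending: b before a
  expect_equal(hits$phenotype[hits$category == "x"], c("b", "a"))
  expect_equal(hits$rank[hits$category == "x"], 1:2)
  expect_equal(hits$rank[hits$category == "y"], 1)
  # no significant rows -> empty result
  tab$significant <- FALSE
  expect_equal(nrow(summarize_hits(tab)), 0)
  expect_error(summarize_hits(tab[0, ]), "empty")
})

test_that("a planted strong association ranks first in its family", {
  set.seed(6)
  n <- 500
  z <- rnorm(n)
  phe <- cbind(strong = 0.8 * z + 0.6 * rnorm(n),
               matrix(rnorm(n * 30), n,
                      dimnames = list(NULL, sprintf("noise%02d", 1:30))))
  tab <- association_scan(matrix(z, n, 1), phe, family = "behavior")
  hits <- summarize_hits(tab)
  expect_equal(hits$phenotype[1], "strong")
  expect_equal(hits$rank[1], 1)
})
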