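#' Permutation test of the latent correlations
#'
#' Builds an empirical null distribution for the per-component latent
#' correlations by holding the brain features fixed, randomly shuffling the
#' target across participants, and refitting the full PLS model with the
#' same `k` at each iteration. Comparison is component-wise by extraction
#' order and on the correlation magnitude `|rho|` (component signs are
#' arbitrary under the model's sign convention, so a signed one-sided test
#' would be ill-defined). The empirical p-value for component `j` is
#' \deqn{p_j = \frac{1 + \#\{b : |\rho^{null}_{bj}| \ge |\rho_j|\}}{1 + B},}
#' so the smallest attainable p is `1/(1+B)`; at `B = 1000` a component with
#' `p < 0.001` is one whose observed association exceeds the model strength
#' in every null model.
#'
#' @param x Feature matrix (or `residualized_features`), as for
#'   [chronopls()].
#' @param y Encoded -1/+1 target.
#' @param k Number of components.
#' @param n_permutations Number of target shuffles `B`.
#' @param seed Optional integer seed for the shuffle stream.
#' @param center,scale Passed to the model fit (defaults as [chronopls()]).
#' @param refit_budget Soft cap on `B * k`; a configuration above it warns
#'   (but still runs).
#' @return Object of class `chronopls_perm`: `observed_rho` (signed),
#'   `null_rho` (B x k matrix of null `|rho|` draws), `p_values`, `B`,
#'   `seed`.
#' @export
permutation_test <- function(x, y, k, n_permutations = 1000, seed = NULL,
                             center = TRUE, scale = TRUE,
                             refit_budget = 50000) {
  if (inherits(x, "residualized_features")) x <- x$x
  x <- as.matrix(x)
  y <- as.numeric(y)
  B <- as.integer(n_permutations)
  if (B < 1L) stop("n_permutations must be at least 1", call. = FALSE)
  if (B * k > refit_budget)
    warning("permutation test requires ", B * k,
            " component refits, above the configured budget of ",
            refit_budget, call. = FALSE)
  fit <- chronopls(x, y, k = k, center = center, scale = scale)
  # refits only need the prepared matrix; reuse the stored scaling
  Xc <- sweep(sweep(x, 2, fit$x_center, "-"), 2, fit$x_scale, "/")
  yc <- y - fit$y_center
  if (!is.null(seed)) set.seed(seed)
  null_rho <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    yp <- sample(yc)
    core <- pls1_core(Xc, yp, k)
    null_rho[b, ] <- abs(drop(stats::cor(core$T, yp)))
  }
  p_values <- (1 + colSums(null_rho >=
                             matrix(abs(fit$rho), B, k, byrow = TRUE))) /
    (1 + B)
  structure(list(observed_rho = fit$rho, null_rho = null_rho,
                 p_values = p_values, B = B, k = k, seed = seed),
            class = "chronopls_perm")
}

#' @export
print.chronopls_perm <- function(x, digits = 4, ...) {
  cat("Permutation test of latent correlations (B =", x$B, "shuffles)\n")
  tab <- data.frame(component = seq_len(x$k),
                    rho = x$observed_rho,
                    null_mean = colMeans(x$null_rho),
                    null_max = apply(x$null_rho, 2, max),
                    p = x$p_values)
  print(format(tab, digits = digits), row.names = FALSE)
  cat("minimum attainable p:", format(1 / (1 + x$B), digits = digits), "\n")
  invisible(x)
}

#' Bootstrap distributions of the brain loadings
#'
#' Quantifies the robustness of each feature's x-loading on each component
#' by resampling participants with replacement, refitting the full PLS
#' model, matching the refit components to the reference model's order and
#' sign with the Hungarian algorithm on the loading correlation similarity
#' matrix (see [match_components()]), and recording the aligned loadings.
#' A loading is flagged robust when its two-sided 5-95% percentile interval
#' excludes zero. Resamples that lose one of the two target classes are
#' redrawn (and counted).
#'
#' @inheritParams permutation_test
#' @param n_bootstraps Number of bootstrap resamples `B` (>= 2).
#' @param probs Lower/upper percentile bounds of the confidence interval.
#' @param max_redraws Cap on single-class redraws across the whole run.
#' @return Object of class `chronopls_boot`: `loading_draws` (B x p x k
#'   array, matched and sign-aligned), `ci_low`/`ci_high` (p x k percentile
#'   bounds), `significant` (p x k logical mask, `TRUE` iff the interval
#'   excludes zero), `reference` (the reference fit), `n_redraws`, `B`,
#'   `probs`, `seed`.
#' @export
bootstrap_loadings <- function(x, y, k, n_bootstraps = 1000, seed = NULL,
                               center = TRUE, scale = TRUE,
                               probs = c(0.05, 0.95), max_redraws = 1000) {
  if (inherits(x, "residualized_features")) x <- x$x
  x <- as.matrix(x)
  y <- as.numeric(y)
  B <- as.integer(n_bootstraps)
  if (B < 2L) stop("n_bootstraps must be at least 2", call. = FALSE)
  stopifnot(length(probs) == 2L, probs[1] < probs[2])
  ref <- chronopls(x, y, k = k, center = center, scale = scale)
  n <- nrow(x); p <- ncol(x)
  if (!is.null(seed)) set.seed(seed)
  draws <- array(NA_real_, c(B, p, k),
                 dimnames = list(NULL, ref$features, colnames(ref$P)))
  n_redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) >= 2L) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws)
        stop("exceeded ", max_redraws, " single-class redraws; the target ",
             "is too imbalanced to bootstrap", call. = FALSE)
    }
    fit_b <- chronopls(x[idx, , drop = FALSE], y[idx], k = k,
                       center = center, scale = scale)
    m <- match_components(fit_b$P, ref$P)
    draws[b, , ] <- sweep(fit_b$P[, m$permutation, drop = FALSE], 2,
                          m$signs, "*")
  }
  ci <- apply(draws, c(2, 3), stats::quantile, probs = probs, names = FALSE)
  ci_low <- ci[1, , ]; ci_high <- ci[2, , ]
  dim(ci_low) <- dim(ci_high) <- c(p, k)
  dimnames(ci_low) <- dimnames(ci_high) <- dimnames(ref$P)
  significant <- ci_low > 0 | ci_high < 0
  structure(list(loading_draws = draws, ci_low = ci_low, ci_high = ci_high,
                 significant = significant, reference = ref,
                 n_redraws = n_redraws, B = B, probs = probs, seed = seed),
            class = "chronopls_boot")
}

#' @export
print.chronopls_boot <- function(x, ...) {
  cat("Bootstrap loading inference (B =", x$B, "resamples,",
      sprintf("%g-%g%% percentile interval)\n",
              100 * x$probs[1], 100 * x$probs[2]))
  cat("  robust loadings per component:",
      paste(colSums(x$significant), collapse = ", "), "of",
      nrow(x$significant), "features\n")
  if (x$n_redraws > 0)
    cat("  single-class resamples redrawn:", x$n_redraws, "\n")
  invisible(x)
}
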