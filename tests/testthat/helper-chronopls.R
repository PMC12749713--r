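# Shared fixtures and independent oracles. Fixtures are always built in
# code; nothing is read from disk.

# small cohort: 24 features (12 GMV, 6 FA, 6 FC), two planted modes
tiny_config <- function(seed = 1, n = 300, ...) {
  args <- list(
    n_participants = n,
    block_sizes = list(gmv = 12, fa = 6, fc_components = 4),
    mode_strengths = c(0.3, 0.2),
    n_phenotypes_per_family = c(behavior = 12, diagnosis = 8,
                                medication = 5),
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# the planted-mode study conditions: n = 2000, default feature blocks,
# one mode at latent-target correlation 0.3
planted_config <- function(seed = 1, ...) {
  cohort_config(
    n_participants = 2000,
    mode_strengths = 0.3,
    n_phenotypes_per_family = c(behavior = 10, diagnosis = 5,
                                medication = 5),
    seed = seed, ...)
}

# plain random regression fixture
random_xy <- function(seed = 1, n = 80, p = 10) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  y <- ifelse(rnorm(n) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(x = x, y = y)
}

# all permutations of a vector (exhaustive assignment oracle, k <= 6)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# exhaustive matching oracle: maximal total |corr| over all permutations
brute_force_match <- function(l_boot, l_ref) {
  k <- ncol(l_ref)
  sim <- abs(cor(l_boot, l_ref))
  best <- -Inf; best_p <- NULL
  for (p in all_perms(seq_len(k))) {
    tot <- sum(sim[cbind(p, seq_len(k))])
    if (tot > best) { best <- tot; best_p <- p }
  }
  list(total = best, permutation = best_p)
}

# textbook Pearson correlation
pearson_oracle <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# closed-form pooled-variance two-sample t
pooled_t_oracle <- function(s1, s0) {
  n1 <- length(s1); n0 <- length(s0)
  sp2 <- ((n1 - 1) * var(s1) + (n0 - 1) * var(s0)) / (n1 + n0 - 2)
  tt <- (mean(s1) - mean(s0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(statistic = tt, df = n1 + n0 - 2,
       p.value = 2 * pt(-abs(tt), n1 + n0 - 2))
}

# sort-based type-7 quantile, written independently of stats::quantile
quantile7_oracle <- function(x, prob) {
  xs <- sort(x)
  h <- (length(xs) - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# normal-equations residualization oracle
residualize_oracle <- function(x, design) {
  D <- cbind(1, design)
  x - D %*% solve(crossprod(D), crossprod(D, x))
}
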