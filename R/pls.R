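#' Fit a PLS1 latent-variable model of a binary trait on brain features
#'
#' Extracts `k` successive latent components of the feature matrix that
#' maximally covary with a single (typically -1/+1 encoded) response, by
#' PLS1 regression with X-deflation. Each component consists of a weight
#' vector `w` (unit norm), x-scores `t = X w` ("brain scores"), x-loadings
#' `p = X't / t't`, and a y-loading `q = y't / t't`; after each extraction
#' `X` is deflated by `t p'` and `y` by `q t`, so score columns are mutually
#' orthogonal. With a single response the weight direction has the closed
#' form `w = X'y / ||X'y||`, i.e. the NIPALS inner iteration converges in
#' one pass; fitting is fully deterministic.
#'
#' A fixed sign convention makes components reproducible: the
#' largest-magnitude entry of each weight vector is positive (the weight,
#' score, x-loading and y-loading of the component are flipped together, so
#' all model identities are preserved). The orientation of a component with
#' respect to morningness/eveningness is therefore read off its latent
#' correlation or group t-test, not off an arbitrary algebraic sign.
#'
#' @param x Numeric feature matrix (participants x features), or a
#'   `residualized_features` object. A `blocks` attribute (feature block
#'   tags) is carried into the model.
#' @param y Numeric response; the intended use is the -1/+1 encoded
#'   chronotype. Must contain at least two distinct values.
#' @param k Number of components to extract (`1 <= k <= min(n-1, p)` and at
#'   most the effective rank of the centered/scaled `x`).
#' @param center,scale Center each feature to mean zero / scale to unit
#'   standard deviation before fitting (both default `TRUE`; the feature
#'   blocks live on incommensurate scales, and PLS covariance maximisation
#'   is scale-sensitive). The centering/scaling parameters are stored in the
#'   model, so [predict.chronopls()] and [build_projection()] are
#'   self-contained.
#' @param tol Degeneracy tolerance: extraction stops with an error if the
#'   residual cross-covariance or score norm falls below it (the requested
#'   `k` exceeds the effective rank).
#' @return Object of class `chronopls` with elements `W` (p x k weights),
#'   `P` (p x k x-loadings), `T` (n x k x-scores), `y_loadings` (k),
#'   `x_center`, `x_scale`, `y_center`, `y_scale`, `rho` (per-component
#'   latent correlations with `y`), `k`, `blocks`, `features`, `y`, `n`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' y <- sign(x[, 1] + rnorm(100, sd = 0.5))
#' fit <- chronopls(x, y, k = 2)
#' fit$rho
#' @export
chronopls <- function(x, y, k = 10, center = TRUE, scale = TRUE,
                      tol = 1e-10) {
  if (inherits(x, "residualized_features")) x <- x$x
  x <- as.matrix(x)
  blocks <- attr(x, "blocks")
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y must be row-aligned", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("x and y must be complete (no missing values)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("y has a single target class; a chronotype model needs both ",
         "early birds and night owls", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p))
    stop("k must satisfy 1 <= k <= min(n - 1, p)", call. = FALSE)

  x_center <- if (center) colMeans(x) else rep(0, p)
  Xc <- sweep(x, 2, x_center, "-")
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- sqrt(colSums(Xc^2) / (n - 1))
    if (any(x_scale < tol))
      stop("constant feature column(s): ",
           paste(colnames(x)[x_scale < tol], collapse = ", "),
           call. = FALSE)
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  y_center <- mean(y)
  y_scale <- 1
  yc <- y - y_center

  x_total_ss <- sum(Xc^2)
  core <- pls1_core(Xc, yc, k, tol)
  rho <- drop(stats::cor(core$T, y))

  features <- colnames(x)
  if (is.null(features)) features <- sprintf("x%03d", seq_len(p))
  dimnames(core$W) <- dimnames(core$P) <-
    list(features, paste0("comp", seq_len(k)))
  dimnames(core$T) <- list(rownames(x), paste0("comp", seq_len(k)))

  structure(list(W = core$W, P = core$P, T = core$T,
                 y_loadings = core$q,
                 x_center = stats::setNames(x_center, features),
                 x_scale = stats::setNames(x_scale, features),
                 y_center = y_center, y_scale = y_scale,
                 rho = rho, k = k, n = n, x_total_ss = x_total_ss,
                 features = features, blocks = blocks,
                 y = y, call = match.call()),
            class = "chronopls")
}

# PLS1 core on a centered (and scaled) matrix and centered response.
# Deterministic; no per-component iteration is needed for a single response.
pls1_core <- function(X, y, k, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, k); P <- matrix(0, p, k); Tm <- matrix(0, n, k)
  q <- numeric(k)
  for (h in seq_len(k)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w * w))
    if (nw < tol)
      stop("component ", h, " is degenerate: k exceeds the effective rank ",
           "of x", call. = FALSE)
    w <- w / nw
    t_h <- X %*% w
    tt <- sum(t_h * t_h)
    if (tt < tol)
      stop("component ", h, " has a zero-variance score; k exceeds the ",
           "effective rank of x", call. = FALSE)
    p_h <- crossprod(X, t_h) / tt
    q_h <- sum(y * t_h) / tt
    if (w[which.max(abs(w))] < 0) {        # sign convention
      w <- -w; t_h <- -t_h; p_h <- -p_h; q_h <- -q_h
    }
    X <- X - tcrossprod(t_h, p_h)
    y <- y - q_h * t_h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; q[h] <- q_h
  }
  list(W = W, P = P, T = Tm, q = q)
}

# rotation R = W (P'W)^{-1} via linear solve (no explicit inverse)
pls_rotation <- function(W, P) {
  PtW <- crossprod(P, W)
  t(solve(t(PtW), t(W)))
}

#' Latent correlations between model scores and the encoded target
#'
#' Pearson correlation of each x-score column with the response; the
#' "latent factor correlation" whose significance the permutation test
#' assesses.
#'
#' @param model A `chronopls` fit.
#' @param y Response vector row-aligned with the training data; defaults to
#'   the training target stored in the model.
#' @return Numeric vector of length `k`.
#' @export
latent_correlation <- function(model, y = model$y) {
  stopifnot(inherits(model, "chronopls"))
  if (length(y) != nrow(model$T))
    stop("y must be row-aligned with the model scores", call. = FALSE)
  sds <- apply(model$T, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance score column", call. = FALSE)
  as.vector(stats::cor(model$T, as.numeric(y)))
}

#' Two-sample pooled-variance t-test of scores between target groups
#'
#' Compares mean brain scores between the two target groups (e.g. night
#' owls, +1, vs early birds, -1) with a Student t-test assuming equal
#' variances, so the degrees of freedom are `n1 + n2 - 2`. Used to label
#' the morning/evening orientation of each fitted component.
#'
#' @param scores Numeric vector of per-participant scores.
#' @param group Vector with exactly two distinct values (conventionally -1
#'   and +1); the test contrasts the higher level minus the lower.
#' @return List with `statistic`, `df`, `p.value`, and the group means.
#' @export
group_ttest <- function(scores, group) {
  scores <- as.numeric(scores)
  g <- sort(unique(group))
  if (length(g) != 2L)
    stop("group must take exactly two values", call. = FALSE)
  s1 <- scores[group == g[2]]; s0 <- scores[group == g[1]]
  if (length(s1) < 2L || length(s0) < 2L)
    stop("each group needs at least two members", call. = FALSE)
  ht <- stats::t.test(s1, s0, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value,
       means = stats::setNames(c(mean(s0), mean(s1)), as.character(g)))
}

#' @export
print.chronopls <- function(x, digits = 3, ...) {
  cat("PLS1 chronotype model:", x$k, "component(s),", x$n,
      "participants,", length(x$features), "features\n")
  if (!is.null(x$blocks)) {
    tb <- table(x$blocks)
    cat("  blocks:", paste(sprintf("%s=%d", names(tb), tb),
                           collapse = ", "), "\n")
  }
  cat("  latent correlations (rho):",
      paste(format(x$rho, digits = digits), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn chronopls Per-component summary: latent correlation, variance
#'   explained in the (centered/scaled) features, and — when the response is
#'   two-valued — the pooled two-sample t-test contrasting the +1 against
#'   the -1 group.
#' @param object,... Method arguments.
#' @export
summary.chronopls <- function(object, ...) {
  # scores are orthogonal, so component h explains ||t_h||^2 ||p_h||^2 of
  # the total SS of the centered/scaled feature matrix
  expl <- colSums(object$T^2) * colSums(object$P^2)
  tab <- data.frame(component = seq_len(object$k),
                    rho = object$rho,
                    y_loading = object$y_loadings,
                    x_var_explained = expl / object$x_total_ss)
  if (length(unique(object$y)) == 2L) {
    tests <- lapply(seq_len(object$k), function(j)
      group_ttest(object$T[, j], object$y))
    tab$t <- vapply(tests, `[[`, 0, "statistic")
    tab$df <- vapply(tests, `[[`, 0, "df")
    tab$p <- vapply(tests, `[[`, 0, "p.value")
    tab$orientation <- ifelse(tab$t > 0, "eveningness", "morningness")
  }
  structure(list(table = tab, n = object$n, p = length(object$features)),
            class = "summary.chronopls")
}

#' @export
print.summary.chronopls <- function(x, digits = 3, ...) {
  cat("PLS1 chronotype model on", x$n, "participants x", x$p, "features\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @describeIn chronopls Model coefficients: x-loadings (`"loadings"`, the
#'   interpreted brain loadings, default), weights (`"weights"`), or the
#'   rotation `W (P'W)^{-1}` (`"rotation"`).
#' @param type Which coefficient matrix to return.
#' @export
coef.chronopls <- function(object,
                           type = c("loadings", "weights", "rotation"),
                           ...) {
  type <- match.arg(type)
  switch(type,
         loadings = object$P,
         weights = object$W,
         rotation = {
           R <- pls_rotation(object$W, object$P)
           dimnames(R) <- dimnames(object$W)
           R
         })
}

#' @describeIn chronopls Project new participants into the latent space
#'   (`type = "scores"`, the transform `X_c W (P'W)^{-1}` after applying the
#'   stored centering/scaling) or predict the response (`type =
#'   "response"`). Columns of `newdata` must match the training features in
#'   name and order.
#' @param newdata Feature matrix over the model's features; defaults to
#'   returning the training scores.
#' @export
predict.chronopls <- function(object, newdata = NULL,
                              type = c("scores", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    scores <- object$T
  } else {
    if (inherits(newdata, "residualized_features")) newdata <- newdata$x
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object$features))
      stop("newdata has ", ncol(newdata), " columns; the model expects ",
           length(object$features), call. = FALSE)
    if (!is.null(colnames(newdata))) {
      mismatch <- which(colnames(newdata) != object$features)
      if (length(mismatch))
        stop("newdata column ", mismatch[1], " is ",
             sQuote(colnames(newdata)[mismatch[1]]), " but the model ",
             "expects ", sQuote(object$features[mismatch[1]]),
             call. = FALSE)
    }
    Xs <- sweep(sweep(newdata, 2, object$x_center, "-"), 2,
                object$x_scale, "/")
    scores <- Xs %*% pls_rotation(object$W, object$P)
    colnames(scores) <- colnames(object$T)
  }
  if (type == "scores") return(scores)
  drop(scores %*% object$y_loadings) * object$y_scale + object$y_center
}

#' @describeIn chronopls Fitted response values on the training data.
#' @export
fitted.chronopls <- function(object, ...) {
  drop(object$T %*% object$y_loadings) * object$y_scale + object$y_center
}

#' @describeIn chronopls Training-response residuals.
#' @export
residuals.chronopls <- function(object, ...) {
  object$y - fitted(object)
}

#' @describeIn chronopls Scree-style bar plot of the per-component latent
#'   correlation magnitudes.
#' @param x,y A `chronopls` object (plot method; `y` ignored).
#' @export
plot.chronopls <- function(x, y = NULL, ...) {
  graphics::barplot(abs(x$rho), names.arg = seq_len(x$k),
                    xlab = "component", ylab = "|latent correlation|", ...)
  invisible(x)
}
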