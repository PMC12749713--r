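#' Restrict a trained model to a feature subset for cross-cohort projection
#'
#' An external cohort measured only on a subset of the training features
#' (typically the grey-matter volume block) can still be placed in the
#' trained latent space: the weight and x-loading rows are restricted to the
#' subset and the rotation
#' \deqn{R_{sub} = W_{sub} (P_{sub}^\top W_{sub})^{-1}}
#' is computed by linear solve (never an explicit inverse). A numerically
#' singular `P_sub' W_sub` (condition number above `max_condition`) is a
#' hard failure rather than a silent pseudo-inverse, because the projection
#' formula presumes invertibility.
#'
#' @param model A fitted [chronopls()] model.
#' @param subset Either a block tag (`"GMV"`, `"FA"`, `"FC"`,
#'   case-insensitive, requires the model to carry block tags), `"all"`, or
#'   a character vector of feature names (order preserved from the model).
#' @param max_condition Condition-number threshold for rejecting the
#'   restricted rotation.
#' @return Object of class `chronopls_projection`: `feature_subset`,
#'   `W_sub`, `P_sub`, `rotation`, `x_center`/`x_scale` (the training
#'   statistics for the subset, for optional reuse), `condition_number`,
#'   `k`.
#' @export
build_projection <- function(model, subset = "GMV", max_condition = 1e12) {
  stopifnot(inherits(model, "chronopls"))
  if (length(subset) == 1L &&
      toupper(subset) %in% c("GMV", "FA", "FC", "ALL")) {
    if (toupper(subset) == "ALL") {
      keep <- model$features
    } else {
      if (is.null(model$blocks))
        stop("model carries no feature block tags; pass feature names",
             call. = FALSE)
      keep <- model$features[model$blocks == toupper(subset)]
    }
  } else {
    missing_feats <- setdiff(subset, model$features)
    if (length(missing_feats))
      stop("subset feature(s) not in the model: ",
           paste(utils::head(missing_feats, 3), collapse = ", "),
           call. = FALSE)
    keep <- model$features[model$features %in% subset]  # model order
  }
  if (!length(keep)) stop("empty feature subset", call. = FALSE)
  idx <- match(keep, model$features)
  W_sub <- model$W[idx, , drop = FALSE]
  P_sub <- model$P[idx, , drop = FALSE]
  PtW <- crossprod(P_sub, W_sub)
  cond <- kappa(PtW, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition)
    stop("restricted rotation is numerically singular: condition number ",
         "of P_sub' W_sub is ", format(cond, digits = 3),
         " (> ", format(max_condition), "); the subset carries too little ",
         "of the model's component structure", call. = FALSE)
  rotation <- t(solve(t(PtW), t(W_sub)))
  dimnames(rotation) <- dimnames(W_sub)
  structure(list(feature_subset = keep, W_sub = W_sub, P_sub = P_sub,
                 rotation = rotation,
                 x_center = model$x_center[idx],
                 x_scale = model$x_scale[idx],
                 condition_number = cond, k = model$k),
            class = "chronopls_projection")
}

#' @export
print.chronopls_projection <- function(x, ...) {
  cat("Latent-space projection:", length(x$feature_subset),
      "features ->", x$k, "components; condition number",
      format(x$condition_number, digits = 4), "\n")
  invisible(x)
}

#' Project an external cohort into the trained latent space
#'
#' Applies the restricted rotation of [build_projection()] to an external
#' feature matrix: `scores = X_sub %*% R_sub` after centering/scaling.
#' By default the external cohort is centered and scaled with its *own*
#' statistics (acquisition scales differ across cohorts and the external
#' data are preprocessed independently); pass the projection's stored
#' `x_center`/`x_scale` — or any numeric vectors — to reuse the training
#' statistics instead. External features should be residualized against the
#' external cohort's own nuisance covariates upstream (see [residualize()]).
#'
#' @param projection A `chronopls_projection`.
#' @param x_ext External feature matrix whose columns match
#'   `projection$feature_subset` in name and order.
#' @param center,scale `TRUE` (use the external cohort's own statistics),
#'   `FALSE`, or numeric vectors of per-feature values.
#' @return n x k score matrix.
#' @export
project_cohort <- function(projection, x_ext, center = TRUE, scale = TRUE) {
  stopifnot(inherits(projection, "chronopls_projection"))
  if (inherits(x_ext, "residualized_features")) x_ext <- x_ext$x
  x_ext <- as.matrix(x_ext)
  p_sub <- length(projection$feature_subset)
  if (ncol(x_ext) != p_sub)
    stop("x_ext has ", ncol(x_ext), " columns; the projection expects ",
         p_sub, call. = FALSE)
  if (!is.null(colnames(x_ext))) {
    mismatch <- which(colnames(x_ext) != projection$feature_subset)
    if (length(mismatch))
      stop("x_ext column ", mismatch[1], " is ",
           sQuote(colnames(x_ext)[mismatch[1]]), " but the projection ",
           "expects ", sQuote(projection$feature_subset[mismatch[1]]),
           call. = FALSE)
  }
  ctr <- if (isTRUE(center)) colMeans(x_ext) else
    if (isFALSE(center)) rep(0, p_sub) else as.numeric(center)
  Xs <- sweep(x_ext, 2, ctr, "-")
  if (isTRUE(scale)) {
    scl <- sqrt(colSums(sweep(x_ext, 2, colMeans(x_ext), "-")^2) /
                  (nrow(x_ext) - 1))
    if (any(scl == 0))
      stop("constant external feature column(s)", call. = FALSE)
    Xs <- sweep(Xs, 2, scl, "/")
  } else if (!isFALSE(scale)) {
    Xs <- sweep(Xs, 2, as.numeric(scale), "/")
  }
  scores <- Xs %*% projection$rotation
  colnames(scores) <- colnames(projection$rotation)
  rownames(scores) <- rownames(x_ext)
  scores
}

#' Age brackets used for adult and developmental cohorts
#'
#' Breakpoints of the standard stratification brackets: five adult brackets
#' spanning 40-70 years (40-50, 50-55, 55-60, 60-65, 65-70) and four
#' developmental brackets spanning 100-140 months. Brackets are
#' left-closed, right-open `[a, b)`, with the final bracket right-closed —
#' the printed bracket lists share endpoints, so a deterministic boundary
#' convention is required.
#'
#' @return Numeric breakpoint vector with a `unit` attribute.
#' @export
age_brackets_ukb <- function() {
  structure(c(40, 50, 55, 60, 65, 70), unit = "years")
}

#' @rdname age_brackets_ukb
#' @export
age_brackets_abcd <- function() {
  structure(c(100, 110, 120, 130, 140), unit = "months")
}

#' Mean and spread of brain scores within age brackets
#'
#' Summarises per-participant subtype expressions by age: within each
#' bracket and component, the mean score, the sample standard deviation
#' (denominator `n - 1`; undefined and reported `NA` when `n < 2`), and the
#' participant count. Participants falling outside every bracket are
#' counted in the `n_outside` attribute. Bracket boundaries follow the
#' [age_brackets_ukb()] convention (left-closed, right-open, last bracket
#' closed).
#'
#' @param scores n x k score matrix.
#' @param ages Numeric vector of ages, row-aligned with `scores`, in the
#'   brackets' unit.
#' @param brackets Breakpoint vector (length = number of brackets + 1),
#'   e.g. [age_brackets_ukb()].
#' @return Data frame of class `age_bracket_summary` with columns
#'   `bracket`, `lower`, `upper`, `component`, `n`, `mean`, `sd`; attribute
#'   `n_outside` counts participants outside all brackets.
#' @export
age_bracket_summary <- function(scores, ages, brackets = age_brackets_ukb()) {
  scores <- as.matrix(scores)
  ages <- as.numeric(ages)
  if (length(ages) != nrow(scores))
    stop("scores and ages must be row-aligned", call. = FALSE)
  br <- as.numeric(brackets)
  if (length(br) < 2L || is.unsorted(br, strictly = TRUE))
    stop("brackets must be strictly increasing breakpoints", call. = FALSE)
  nb <- length(br) - 1L
  comp_names <- colnames(scores)
  if (is.null(comp_names)) comp_names <- paste0("comp", seq_len(ncol(scores)))
  # [a, b) everywhere except the final bracket, which is [a, b]
  bin <- findInterval(ages, br, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= nb
  rows <- expand.grid(bracket = seq_len(nb),
                      component = comp_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$lower <- br[rows$bracket]
  rows$upper <- br[rows$bracket + 1L]
  stat <- mapply(function(bk, cp) {
    s <- scores[inside & bin == bk, match(cp, comp_names)]
    c(n = length(s),
      mean = if (length(s)) mean(s) else NA_real_,
      sd = if (length(s) >= 2L) stats::sd(s) else NA_real_)
  }, rows$bracket, rows$component)
  rows$n <- as.integer(stat["n", ])
  rows$mean <- stat["mean", ]
  rows$sd <- stat["sd", ]
  rows$bracket <- sprintf("[%g,%g%s", rows$lower, rows$upper,
                          ifelse(rows$upper == br[nb + 1L], "]", ")"))
  out <- rows[, c("bracket", "lower", "upper", "component", "n", "mean",
                  "sd")]
  attr(out, "n_outside") <- sum(!inside)
  attr(out, "unit") <- attr(brackets, "unit")
  class(out) <- c("age_bracket_summary", "data.frame")
  out
}
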