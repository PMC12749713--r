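#' Encode six-level chronotype responses as a -1/+1 target
#'
#' Maps "definitely a morning person" and "more a morning than an evening
#' person" to -1 (early bird), "more an evening than a morning person" and
#' "definitely an evening person" to +1 (night owl). Participants answering
#' "do not know" or "prefer not to answer" are dropped. Any other label is
#' an error naming the offending value.
#'
#' @param raw Character or factor vector of responses.
#' @param ids Participant identifiers aligned with `raw`; defaults to
#'   `names(raw)` or, failing that, `seq_along(raw)`.
#' @return An object of class `encoded_target`: list with `values` (named
#'   numeric vector over \{-1, +1\}) and `kept_ids`.
#' @export
encode_chronotype <- function(raw, ids = NULL) {
  raw <- as.character(raw)
  if (is.null(ids)) ids <- if (!is.null(names(raw))) names(raw) else
    as.character(seq_along(raw))
  stopifnot(length(ids) == length(raw))
  lev <- chronotype_levels()
  bad <- setdiff(unique(raw), lev)
  if (length(bad))
    stop("unrecognized chronotype response: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  code <- c(-1, -1, 1, 1, NA, NA)[match(raw, lev)]
  keep <- !is.na(code)
  out <- list(values = stats::setNames(code[keep], ids[keep]),
              kept_ids = ids[keep])
  class(out) <- "encoded_target"
  out
}

#' @export
print.encoded_target <- function(x, ...) {
  cat("Encoded chronotype target:", length(x$values), "participants (",
      sum(x$values == -1), "early birds,", sum(x$values == 1),
      "night owls )\n")
  invisible(x)
}

#' Apply participant exclusions
#'
#' Drops participants with a history of shift work and participants whose
#' chronotype answers at the two visits disagree once both are codable as
#' -1/+1 (non-codable answers at either visit do not count as a disparity).
#' Order is preserved and no id is duplicated.
#'
#' @param participants Data frame with columns `id`, `shift_work_flag`,
#'   `chronotype_raw` and optionally `chronotype_raw_followup`.
#' @return List of class `exclusion_report`: `kept_ids` (character, in input
#'   order) and `excluded` (data frame with `id` and `reason`).
#' @export
apply_exclusions <- function(participants) {
  need <- c("id", "shift_work_flag", "chronotype_raw")
  miss <- setdiff(need, names(participants))
  if (length(miss))
    stop("participant table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lev <- chronotype_levels()
  code_of <- function(v) c(-1, -1, 1, 1, NA, NA)[match(as.character(v), lev)]
  shift <- as.logical(participants$shift_work_flag)
  incons <- rep(FALSE, nrow(participants))
  if ("chronotype_raw_followup" %in% names(participants)) {
    c0 <- code_of(participants$chronotype_raw)
    c2 <- code_of(participants$chronotype_raw_followup)
    incons <- !is.na(c0) & !is.na(c2) & c0 != c2
  }
  drop <- shift | incons
  reason <- ifelse(shift, "shift_work", "chronotype_disparity")
  out <- list(
    kept_ids = as.character(participants$id[!drop]),
    excluded = data.frame(id = as.character(participants$id[drop]),
                          reason = reason[drop], stringsAsFactors = FALSE))
  class(out) <- "exclusion_report"
  out
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusions:", nrow(x$excluded), "dropped (",
      sum(x$excluded$reason == "shift_work"), "shift work,",
      sum(x$excluded$reason == "chronotype_disparity"),
      "chronotype disparity );", length(x$kept_ids), "kept\n")
  invisible(x)
}

# expand a covariate data frame into a full-rank numeric design (no
# intercept column; categorical variables one-hot with the first level
# dropped)
build_covariate_design <- function(covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(matrix(numeric(0), nrow = NROW(covariates), ncol = 0))
  covariates <- as.data.frame(covariates)
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v) || is.logical(v)) {
      m <- matrix(as.numeric(v), ncol = 1,
                  dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2)
        return(NULL)
      m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
      m
    }
  })
  do.call(cbind, cols[!vapply(cols, is.null, TRUE)])
}

#' Regress nuisance covariates out of a feature matrix
#'
#' Fits, per feature column, an ordinary least-squares regression on the
#' nuisance covariates (plus intercept) and returns the residuals.
#' Categorical covariates are one-hot encoded with a reference level
#' dropped; rows with missing covariate values are dropped from the fit and
#' reported. Residual columns have mean zero and are orthogonal to every
#' covariate column used. Age and sex should *not* be passed here when they
#' are variables of scientific interest.
#'
#' @param x Numeric feature matrix (rows = participants). A `blocks`
#'   attribute, if present, is carried through.
#' @param covariates Data frame (or matrix) of nuisance covariates,
#'   row-aligned with `x`. May be `NULL` or have zero columns, in which case
#'   only the intercept is removed (column centering).
#' @return Object of class `residualized_features`: `x` (residual matrix),
#'   `coefficients` ((1+q) x p matrix including the intercept row),
#'   `covariate_names`, and `dropped_ids` (rows lost to missing covariates).
#' @export
residualize <- function(x, covariates = NULL) {
  x <- as.matrix(x)
  C <- build_covariate_design(covariates)
  if (NROW(C) && nrow(C) != nrow(x))
    stop("x and covariates must be row-aligned", call. = FALSE)
  complete <- if (ncol(C)) stats::complete.cases(C) else rep(TRUE, nrow(x))
  dropped <- rownames(x)[!complete]
  if (is.null(dropped)) dropped <- which(!complete)
  xc <- x[complete, , drop = FALSE]
  D <- if (ncol(C))
    cbind("(Intercept)" = 1, C[complete, , drop = FALSE]) else
    matrix(1, nrow(xc), 1, dimnames = list(NULL, "(Intercept)"))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrD, xc)
  res <- xc - D %*% beta
  dimnames(res) <- dimnames(xc)
  attr(res, "blocks") <- attr(x, "blocks")
  out <- list(x = res, coefficients = beta,
              covariate_names = colnames(C),
              dropped_ids = as.character(dropped))
  class(out) <- "residualized_features"
  out
}

#' @export
print.residualized_features <- function(x, ...) {
  cat("Residualized features:", nrow(x$x), "x", ncol(x$x),
      "( covariates:", length(x$covariate_names), ";",
      length(x$dropped_ids), "row(s) dropped for missing covariates )\n")
  invisible(x)
}

#' One-step preparation of a cohort bundle for model fitting
#'
#' Encodes the chronotype target, applies the shift-work and visit-disparity
#' exclusions, subsets all tables to the surviving participants, and
#' residualizes the brain features on the nuisance covariates (site, motion
#' and the sleep battery — never age or sex). Feature scaling to unit
#' variance is left to [chronopls()].
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()] or
#'   [read_cohort()].
#' @param nuisance Character vector of participant-table columns to regress
#'   out. Defaults to site, motion and every column named in the bundle's
#'   sleep battery.
#' @return List of class `prepared_cohort`: `x` (residualized brain matrix
#'   with `blocks` attribute), `y` (named -1/+1 vector), `ids`,
#'   `participants` (subset table), `phenome` (row-subset family matrices),
#'   and `report` (exclusion/encoding counts).
#' @export
preprocess_cohort <- function(bundle,
                              nuisance = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  pt <- bundle$participants
  if (is.null(nuisance)) {
    fixed <- c("id", "age", "sex", "chronotype_raw",
               "chronotype_raw_followup", "shift_work_flag")
    nuisance <- setdiff(names(pt), fixed)
  }
  excl <- apply_exclusions(pt)
  enc <- encode_chronotype(pt$chronotype_raw, ids = pt$id)
  ids <- intersect(excl$kept_ids, enc$kept_ids)
  rows <- match(ids, pt$id)
  y <- enc$values[ids]
  xb <- bundle$brain[rows, , drop = FALSE]
  attr(xb, "blocks") <- attr(bundle$brain, "blocks")
  res <- residualize(xb, pt[rows, nuisance, drop = FALSE])
  if (length(res$dropped_ids)) {
    keep <- setdiff(ids, res$dropped_ids)
    y <- y[keep]
    rows <- match(keep, pt$id)
    ids <- keep
  }
  out <- list(
    x = res$x, y = y, ids = ids,
    participants = pt[rows, , drop = FALSE],
    phenome = lapply(bundle$phenome, function(m) {
      out <- m[rows, , drop = FALSE]
      for (a in c("family", "type", "category"))
        attr(out, a) <- attr(m, a)
      out
    }),
    report = list(n_input = nrow(pt),
                  n_excluded_shift =
                    sum(excl$excluded$reason == "shift_work"),
                  n_excluded_disparity =
                    sum(excl$excluded$reason == "chronotype_disparity"),
                  n_noncodable = nrow(pt) - length(enc$kept_ids),
                  n_missing_covariates = length(res$dropped_ids),
                  n_analyzed = length(ids)))
  class(out) <- "prepared_cohort"
  out
}

#' @export
print.prepared_cohort <- function(x, ...) {
  r <- x$report
  cat("Prepared cohort:", r$n_analyzed, "of", r$n_input,
      "participants analyzed\n")
  cat("  excluded:", r$n_excluded_shift, "shift work,",
      r$n_excluded_disparity, "visit disparity,", r$n_noncodable,
      "non-codable chronotype,", r$n_missing_covariates,
      "missing covariates\n")
  invisible(x)
}
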