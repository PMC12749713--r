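#' Mass-univariate association scan of brain scores against a phenome family
#'
#' Computes, for every (component, phenotype) pair, the Pearson correlation
#' between per-participant brain scores and the phenotype on
#' pairwise-complete rows (binary phenotypes enter as 0/1 numerics, so the
#' correlation is point-biserial), the two-sided p-value from the
#' t-transform of `r` with `n_used - 2` degrees of freedom, the negative
#' base-10 log p, and a Bonferroni significance flag at `alpha / m` where
#' `m` is the number of phenotypes tested in the family (families are never
#' pooled). Phenotypes with fewer than `min_n` complete pairs are flagged
#' `untested`; phenotypes with zero variance after missing-data removal are
#' flagged `zero_variance` — both are emitted, not dropped. A p-value
#' underflowing to zero is capped at the smallest positive representable
#' value so its negative log stays finite.
#'
#' @param scores n x k matrix of brain scores (e.g. `fit$T` or
#'   [predict.chronopls()] output).
#' @param phenome n x m phenotype matrix, row-aligned with `scores`;
#'   optional column attributes `category` and `type` are carried through.
#' @param family Family label (`"behavior"`, `"diagnosis"`,
#'   `"medication"`, ...); defaults to the matrix's `family` attribute.
#' @param alpha Family-wise error level before Bonferroni division.
#' @param min_n Minimum pairwise-complete observations per phenotype.
#' @param max_missing Optional pre-filter: phenotypes missing in more than
#'   this fraction of participants are flagged untested (e.g. `0.8`);
#'   `NULL` disables the filter.
#' @return A data frame of class `association_table` with one row per
#'   (component, phenotype): `component`, `family`, `phenotype`,
#'   `category`, `r`, `n_used`, `p`, `neglog10p`, `threshold`,
#'   `significant`, `status`.
#' @export
association_scan <- function(scores, phenome, family = NULL, alpha = 0.05,
                             min_n = 50, max_missing = NULL) {
  scores <- as.matrix(scores)
  phenome <- as.matrix(phenome)
  if (nrow(scores) != nrow(phenome))
    stop("scores and phenome must be row-aligned", call. = FALSE)
  if (is.null(family)) family <- attr(phenome, "family")
  if (is.null(family)) family <- "phenome"
  k <- ncol(scores); m <- ncol(phenome)
  comp_names <- colnames(scores)
  if (is.null(comp_names)) comp_names <- paste0("comp", seq_len(k))
  phe_names <- colnames(phenome)
  if (is.null(phe_names)) phe_names <- sprintf("phe_%04d", seq_len(m))
  category <- attr(phenome, "category")
  if (is.null(category)) category <- rep("unclassified", m)

  n_nonmiss <- colSums(!is.na(phenome))
  status <- rep("ok", m)
  if (!is.null(max_missing))
    status[1 - n_nonmiss / nrow(phenome) > max_missing] <- "untested"
  status[n_nonmiss < min_n] <- "untested"

  rows <- vector("list", m * k)
  r_mat <- matrix(NA_real_, m, k)
  n_mat <- matrix(NA_integer_, m, k)
  complete_cols <- n_nonmiss == nrow(phenome)
  # fast path: all-complete phenotypes in one call
  idx_fast <- which(complete_cols & status == "ok")
  if (length(idx_fast)) {
    sds <- apply(phenome[, idx_fast, drop = FALSE], 2, stats::sd)
    nz <- sds > 0
    status[idx_fast[!nz]] <- "zero_variance"
    if (any(nz)) {
      r_mat[idx_fast[nz], ] <-
        stats::cor(phenome[, idx_fast[nz], drop = FALSE], scores)
      n_mat[idx_fast[nz], ] <- nrow(phenome)
    }
  }
  for (i in which(!complete_cols & status == "ok")) {
    v <- phenome[, i]
    use <- !is.na(v)
    if (stats::sd(v[use]) == 0) { status[i] <- "zero_variance"; next }
    r_mat[i, ] <- stats::cor(v[use], scores[use, , drop = FALSE])
    n_mat[i, ] <- sum(use)
  }
  m_family <- sum(status == "ok")
  threshold <- if (m_family > 0) alpha / m_family else NA_real_

  r_vec <- as.vector(r_mat)                       # phenotype-major per comp
  n_vec <- as.vector(n_mat)
  df <- n_vec - 2
  tstat <- r_vec * sqrt(df / pmax(1 - r_vec^2, 0))
  p_vec <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df), 0)
  p_vec[!is.na(r_vec) & abs(r_vec) >= 1] <- 0
  p_vec[!is.na(p_vec) & p_vec == 0] <- .Machine$double.xmin
  p_vec[is.na(r_vec)] <- NA_real_

  out <- data.frame(
    component = rep(comp_names, each = m),
    family = family,
    phenotype = rep(phe_names, k),
    category = rep(category, k),
    r = r_vec,
    n_used = n_vec,
    p = p_vec,
    neglog10p = -log10(p_vec),
    threshold = threshold,
    significant = !is.na(p_vec) & p_vec < threshold,
    status = rep(status, k),
    stringsAsFactors = FALSE)
  out$significant[out$status != "ok"] <- NA
  class(out) <- c("association_table", "data.frame")
  out
}

#' Ranked significant hits per component and category
#'
#' Filters an association table to its Bonferroni-significant rows and
#' ranks them within each (component, category) group by decreasing
#' `neglog10p`, breaking ties by decreasing `|r|` and then by phenotype
#' name, so the ordering is fully deterministic.
#'
#' @param table An `association_table` from [association_scan()].
#' @return Data frame of significant hits with a `rank` column (1 = top hit
#'   within its component and category); empty (zero rows) when nothing is
#'   significant.
#' @export
summarize_hits <- function(table) {
  stopifnot(inherits(table, "data.frame"))
  if (!nrow(table)) stop("association table is empty", call. = FALSE)
  hits <- table[!is.na(table$significant) & table$significant, ,
                drop = FALSE]
  if (!nrow(hits)) {
    hits$rank <- integer(0)
    rownames(hits) <- NULL
    return(as.data.frame(hits))
  }
  ord <- order(hits$component, hits$category, -hits$neglog10p,
               -abs(hits$r), hits$phenotype)
  hits <- hits[ord, , drop = FALSE]
  grp <- paste(hits$component, hits$category, sep = "\r")
  hits$rank <- stats::ave(seq_len(nrow(hits)), grp,
                          FUN = seq_along)
  rownames(hits) <- NULL
  as.data.frame(hits)
}
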