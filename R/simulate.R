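#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the full parameter set for [generate_cohort()]. The
#' defaults emulate the design of a large adult population-imaging cohort:
#' 139 regional grey-matter volumes, fractional anisotropy of 48 white-matter
#' tracts, and 210 functional-connectivity link strengths between 21 network
#' components (210 = 21*20/2), with roughly one third of participants
#' reporting an evening chronotype.
#'
#' Brain features are generated as
#' \deqn{X = Z \,\mathrm{diag}(a)\, L^\top + B + C\Gamma + \sigma E}
#' where `Z` (n x k) holds standard-normal latent subtype scores, `L` (p x k)
#' sparse unit-norm planted loadings scaled by `mode_amplitudes`, `B` a dense
#' low-rank background (`n_background` shared variance components at
#' per-feature standard deviation `background_sd`) that mimics the strong
#' autocorrelation of real imaging-derived phenotypes, `C\Gamma` leakage of
#' nuisance covariates into the features, and `E` i.i.d. Gaussian noise.
#' The binary target is obtained by thresholding a noisy weighted combination
#' of the latent scores (a liability-threshold construction), calibrated so
#' that the point-biserial correlation between latent column `j` and the
#' -1/+1 target equals `mode_strengths[j]` and the fraction of +1
#' (evening-type) participants equals `target_balance`.
#'
#' @param n_participants Number of participants.
#' @param block_sizes Named list with `gmv`, `fa` and `fc_components` counts.
#'   The functional-connectivity block has `fc_components*(fc_components-1)/2`
#'   feature columns.
#' @param mode_strengths Target point-biserial correlations, one per planted
#'   mode, in `[0, 1)` and sorted non-increasing.
#' @param n_modes Number of planted modes; defaults to
#'   `length(mode_strengths)`. If `mode_strengths` has length 1 it is
#'   recycled.
#' @param mode_amplitudes Signal amplitude of each planted mode (recycled to
#'   `n_modes`). The true loadings are unit-norm, so this sets the standard
#'   deviation of the planted signal in feature space.
#' @param loading_sparsity Fraction of features per block carrying a nonzero
#'   loading for each mode, in `(0, 1]`.
#' @param mode_blocks Optional list (length `n_modes`) of character vectors
#'   restricting each mode's support to a subset of `c("gmv","fa","fc")`.
#'   `NULL` means every mode loads on every block.
#' @param noise_sd Standard deviation of the i.i.d. feature noise (>= 0).
#' @param n_background Number of dense background (shared-variance)
#'   components; set to 0 for white feature noise.
#' @param background_sd Per-feature standard deviation contributed by the
#'   background components jointly.
#' @param target_balance Fraction of +1 (evening chronotype) participants.
#' @param n_phenotypes_per_family Named integer vector: number of phenotype
#'   columns per family (`behavior`, `diagnosis`, `medication`).
#' @param n_assoc_per_mode Number of phenotypes per family associated with
#'   each planted mode; the remainder are pure noise.
#' @param phenotype_effects Association strength(s) between latent scores and
#'   the associated phenotypes (recycled per mode).
#' @param binary_prevalence Prevalence of the positive class for binary
#'   (diagnosis/medication) phenotypes.
#' @param covariate_spec List with `n_sites` (categorical acquisition site),
#'   `leakage_sd` (per-feature SD of each covariate's leakage into the brain
#'   features) and `sleep_vars` (names of the continuous sleep battery).
#' @param age_range Two-element numeric range of ages (uniformly sampled).
#' @param age_unit `"years"` or `"months"`.
#' @param age_effects Per-mode correlation between age and the latent scores
#'   (recycled/padded to `n_modes`). Default: 0.2 for mode 1, 0 elsewhere.
#' @param sex_ratio Fraction of female participants.
#' @param noncodable_rate Fraction of participants answering "do not know" or
#'   "prefer not to answer" to the chronotype question.
#' @param shift_work_rate Fraction of participants flagged for shift work.
#' @param inconsistency_rate Fraction of codable participants whose follow-up
#'   chronotype answer contradicts the first one.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   cohort byte-identically.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [external_cohort_config()]
#' @export
cohort_config <- function(n_participants = 27030,
                          block_sizes = list(gmv = 139, fa = 48,
                                             fc_components = 21),
                          mode_strengths = c(0.30, 0.25, 0.20, 0.15, 0.10),
                          n_modes = length(mode_strengths),
                          mode_amplitudes = 8,
                          loading_sparsity = 0.1,
                          mode_blocks = NULL,
                          noise_sd = 1,
                          n_background = 20,
                          background_sd = 1,
                          target_balance = 9035 / 27030,
                          n_phenotypes_per_family = c(behavior = 977,
                                                      diagnosis = 1396,
                                                      medication = 133),
                          n_assoc_per_mode = 2,
                          phenotype_effects = 0.15,
                          binary_prevalence = 0.10,
                          covariate_spec = list(
                            n_sites = 3, leakage_sd = 0.2,
                            sleep_vars = c("sleep_duration", "daytime_napping",
                                           "insomnia", "snoring",
                                           "daytime_dozing")),
                          age_range = c(40, 70),
                          age_unit = c("years", "months"),
                          age_effects = NULL,
                          sex_ratio = 0.5444,
                          noncodable_rate = 0.02,
                          shift_work_rate = 0.02,
                          inconsistency_rate = 0.01,
                          seed = 1L) {
  age_unit <- match.arg(age_unit)
  if (length(mode_strengths) == 1L && n_modes > 1L)
    mode_strengths <- rep(mode_strengths, n_modes)
  if (is.null(age_effects)) {
    age_effects <- rep(0, n_modes)
    if (n_modes >= 1L) age_effects[1L] <- 0.2
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    block_sizes = block_sizes,
    mode_strengths = as.numeric(mode_strengths),
    n_modes = as.integer(n_modes),
    mode_amplitudes = rep_len(as.numeric(mode_amplitudes), n_modes),
    loading_sparsity = loading_sparsity,
    mode_blocks = mode_blocks,
    noise_sd = noise_sd,
    n_background = as.integer(n_background),
    background_sd = background_sd,
    target_balance = target_balance,
    n_phenotypes_per_family = n_phenotypes_per_family,
    n_assoc_per_mode = as.integer(n_assoc_per_mode),
    phenotype_effects = rep_len(as.numeric(phenotype_effects), n_modes),
    binary_prevalence = binary_prevalence,
    covariate_spec = covariate_spec,
    age_range = as.numeric(age_range),
    age_unit = age_unit,
    age_effects = rep_len(as.numeric(age_effects), n_modes),
    sex_ratio = sex_ratio,
    noncodable_rate = noncodable_rate,
    shift_work_rate = shift_work_rate,
    inconsistency_rate = inconsistency_rate,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Configuration for a GMV-only external (developmental) cohort
#'
#' Derives a generator configuration for an external cohort measured on
#' grey-matter volume only, sharing the planted GMV loading structure of a
#' source cohort (see [generate_external_cohort()]). By default the cohort is
#' a child sample with ages in months, and the age association of every
#' planted mode has its sign reversed relative to the source configuration,
#' so that age trends of subtype expression run in opposite directions in
#' the two cohorts.
#'
#' @param source_config The `cohort_config` the training cohort was drawn
#'   from.
#' @param n_participants Number of external participants.
#' @param age_range,age_unit Age range of the external cohort (months).
#' @param seed Seed for the external cohort.
#' @param ... Further overrides passed to [cohort_config()].
#' @return A `cohort_config` with an empty FA and FC block.
#' @export
external_cohort_config <- function(source_config,
                                   n_participants = 10550,
                                   age_range = c(107, 133),
                                   age_unit = "months",
                                   seed = source_config$seed + 1L,
                                   ...) {
  stopifnot(inherits(source_config, "cohort_config"))
  cohort_config(
    n_participants = n_participants,
    block_sizes = list(gmv = source_config$block_sizes$gmv, fa = 0,
                       fc_components = 0),
    mode_strengths = source_config$mode_strengths,
    n_modes = source_config$n_modes,
    mode_amplitudes = source_config$mode_amplitudes,
    loading_sparsity = source_config$loading_sparsity,
    noise_sd = source_config$noise_sd,
    n_background = source_config$n_background,
    background_sd = source_config$background_sd,
    target_balance = 0.5,
    n_phenotypes_per_family = source_config$n_phenotypes_per_family,
    n_assoc_per_mode = source_config$n_assoc_per_mode,
    phenotype_effects = source_config$phenotype_effects,
    binary_prevalence = source_config$binary_prevalence,
    covariate_spec = source_config$covariate_spec,
    age_range = age_range,
    age_unit = age_unit,
    age_effects = -source_config$age_effects,
    sex_ratio = 0.5,
    noncodable_rate = source_config$noncodable_rate,
    shift_work_rate = source_config$shift_work_rate,
    inconsistency_rate = source_config$inconsistency_rate,
    seed = seed,
    ...)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 2L)
    stop("n_participants must be at least 2", call. = FALSE)
  bs <- cfg$block_sizes
  if (!all(c("gmv", "fa", "fc_components") %in% names(bs)))
    stop("block_sizes needs elements gmv, fa and fc_components",
         call. = FALSE)
  if (any(unlist(bs) < 0))
    stop("block sizes must be non-negative", call. = FALSE)
  if (sum(block_feature_counts(bs)) < 1L)
    stop("at least one brain feature column is required", call. = FALSE)
  s <- cfg$mode_strengths
  if (cfg$n_modes < 1L || length(s) != cfg$n_modes)
    stop("mode_strengths must have one entry per mode", call. = FALSE)
  if (any(s < 0 | s >= 1))
    stop("mode_strengths must lie in [0, 1)", call. = FALSE)
  if (is.unsorted(rev(s)))
    stop("mode_strengths must be sorted non-increasing", call. = FALSE)
  if (cfg$loading_sparsity <= 0 || cfg$loading_sparsity > 1)
    stop("loading_sparsity must lie in (0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (cfg$target_balance <= 0 || cfg$target_balance >= 1)
    stop("target_balance must lie in (0, 1)", call. = FALSE)
  r <- liability_weights(s, cfg$target_balance)
  if (sum(r^2) >= 1)
    stop("mode_strengths are jointly infeasible at this target_balance: ",
         "the implied liability weights have squared norm ",
         format(sum(r^2), digits = 4), " >= 1", call. = FALSE)
  if (!is.null(cfg$mode_blocks)) {
    if (length(cfg$mode_blocks) != cfg$n_modes)
      stop("mode_blocks must have one entry per mode", call. = FALSE)
    bad <- setdiff(unlist(cfg$mode_blocks), c("gmv", "fa", "fc"))
    if (length(bad))
      stop("unknown block in mode_blocks: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  invisible(cfg)
}

# feature counts per block; fc pair formula
block_feature_counts <- function(block_sizes) {
  fc <- block_sizes$fc_components
  c(gmv = as.integer(block_sizes$gmv),
    fa = as.integer(block_sizes$fa),
    fc = as.integer(fc * (fc - 1) / 2))
}

# liability weights r_j giving point-biserial corr(z_j, y) = s_j when the
# -1/+1 target is 1{liability > qnorm(1 - balance)}
liability_weights <- function(strengths, balance) {
  thr <- stats::qnorm(1 - balance)
  strengths * sqrt(balance * (1 - balance)) / stats::dnorm(thr)
}

chronotype_levels <- function() {
  c("definitely a morning person",
    "more a morning than an evening person",
    "more an evening than a morning person",
    "definitely an evening person",
    "do not know",
    "prefer not to answer")
}

feature_names_for <- function(block_sizes) {
  counts <- block_feature_counts(block_sizes)
  fc <- block_sizes$fc_components
  fc_names <- character(0)
  if (fc >= 2) {
    pairs <- utils::combn(fc, 2)
    fc_names <- sprintf("fc_c%02d_c%02d", pairs[1, ], pairs[2, ])
  }
  list(names = c(sprintf("gmv_%03d", seq_len(counts["gmv"])),
                 sprintf("fa_%02d", seq_len(counts["fa"])),
                 fc_names),
       blocks = c(rep("GMV", counts["gmv"]), rep("FA", counts["fa"]),
                  rep("FC", counts["fc"])))
}

# sparse unit-norm planted loadings, block-restricted support
make_true_loadings <- function(cfg, feat) {
  p <- length(feat$names)
  k <- cfg$n_modes
  tag_of <- c(gmv = "GMV", fa = "FA", fc = "FC")
  L <- matrix(0, p, k, dimnames = list(feat$names, paste0("mode", seq_len(k))))
  for (j in seq_len(k)) {
    allowed <- if (is.null(cfg$mode_blocks)) c("gmv", "fa", "fc") else
      cfg$mode_blocks[[j]]
    for (b in allowed) {
      idx <- which(feat$blocks == tag_of[[b]])
      if (!length(idx)) next
      nnz <- max(1L, round(cfg$loading_sparsity * length(idx)))
      sel <- sample(idx, nnz)
      L[sel, j] <- stats::rnorm(nnz)
    }
    nrm <- sqrt(sum(L[, j]^2))
    if (nrm == 0)
      stop("mode ", j, " received no support; check mode_blocks/block_sizes",
           call. = FALSE)
    L[, j] <- L[, j] / nrm
  }
  L
}

make_phenome_family <- function(family, m, Z, cfg) {
  n <- nrow(Z)
  k <- ncol(Z)
  type <- if (family == "behavior") "continuous" else "binary"
  prefix <- c(behavior = "beh", diagnosis = "dia", medication = "med")[[family]]
  cats <- switch(family,
                 behavior = c("cognition", "lifestyle", "physical", "mood"),
                 diagnosis = c("circulatory", "endocrine", "mental",
                               "digestive"),
                 medication = c("cardiovascular", "nervous_system",
                                "alimentary"))
  X <- matrix(NA_real_, n, m,
              dimnames = list(NULL, sprintf("%s_%04d", prefix, seq_len(m))))
  effect_map <- NULL
  n_assoc_total <- min(m, cfg$n_assoc_per_mode * k)
  assoc_mode <- rep(seq_len(k), each = cfg$n_assoc_per_mode)[
    seq_len(n_assoc_total)]
  for (i in seq_len(m)) {
    if (i <= n_assoc_total) {
      mode <- assoc_mode[i]
      eff <- cfg$phenotype_effects[mode]
      liab <- eff * Z[, mode] + sqrt(1 - eff^2) * stats::rnorm(n)
    } else {
      mode <- NA_integer_
      eff <- 0
      liab <- stats::rnorm(n)
    }
    X[, i] <- if (type == "binary")
      as.numeric(liab > stats::qnorm(1 - cfg$binary_prevalence)) else liab
    if (!is.na(mode))
      effect_map <- rbind(effect_map,
                          data.frame(family = family,
                                     phenotype = colnames(X)[i],
                                     mode = mode, effect = eff,
                                     stringsAsFactors = FALSE))
  }
  attr(X, "family") <- family
  attr(X, "type") <- rep(type, m)
  attr(X, "category") <- rep_len(cats, m)
  list(x = X, effect_map = effect_map)
}

#' Generate a synthetic cohort with planted brain-target covariance modes
#'
#' Draws a complete cohort bundle — participant table (demographics,
#' six-level chronotype responses at two visits, shift-work flag, site,
#' motion and sleep covariates), block-annotated brain feature matrix, and a
#' phenome with known latent associations — together with the ground truth
#' used to plant it. See [cohort_config()] for the generative model.
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements `bundle` (class `cohort_bundle`: elements
#'   `participants`, `brain` with a `blocks` attribute, `phenome`) and
#'   `truth` (class `cohort_truth`: `latent_scores`, `true_loadings` with
#'   unit-norm columns, `true_target_correlations`, `phenotype_effect_map`,
#'   `target`, and the generating `config`).
#' @examples
#' sim <- generate_cohort(cohort_config(n_participants = 200, seed = 7,
#'   block_sizes = list(gmv = 12, fa = 5, fc_components = 4),
#'   mode_strengths = 0.3, n_phenotypes_per_family = c(behavior = 10,
#'   diagnosis = 8, medication = 5)))
#' table(attr(sim$bundle$brain, "blocks"))
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  generate_cohort_impl(config, loadings_override = NULL)
}

generate_cohort_impl <- function(cfg, loadings_override = NULL) {
  set.seed(cfg$seed)
  n <- cfg$n_participants
  k <- cfg$n_modes
  feat <- feature_names_for(cfg$block_sizes)
  p <- length(feat$names)

  ids <- sprintf("sub-%06d", seq_len(n))
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "female", "male")
  site <- paste0("site", sample.int(cfg$covariate_spec$n_sites, n,
                                    replace = TRUE))
  motion <- stats::rnorm(n)
  sleep_vars <- cfg$covariate_spec$sleep_vars
  sleep <- matrix(stats::rnorm(n * length(sleep_vars)), n,
                  dimnames = list(NULL, sleep_vars))

  # latent subtype scores, optionally tilted toward age
  Z <- matrix(stats::rnorm(n * k), n, k)
  age_std <- as.numeric(scale(age))
  for (j in seq_len(k)) {
    aj <- cfg$age_effects[j]
    if (aj != 0) Z[, j] <- aj * age_std + sqrt(1 - aj^2) * Z[, j]
  }

  # liability-threshold target calibrated to the requested point-biserial
  # correlations and class balance
  r <- liability_weights(cfg$mode_strengths, cfg$target_balance)
  thr <- stats::qnorm(1 - cfg$target_balance)
  liability <- drop(Z %*% r) + sqrt(1 - sum(r^2)) * stats::rnorm(n)
  y <- ifelse(liability > thr, 1, -1)

  L <- if (is.null(loadings_override)) make_true_loadings(cfg, feat) else
    loadings_override
  X <- Z %*% (t(L) * cfg$mode_amplitudes)
  if (cfg$n_background > 0) {
    G <- matrix(stats::rnorm(p * cfg$n_background), p)
    G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
    b_amp <- cfg$background_sd * sqrt(p / cfg$n_background)
    X <- X + tcrossprod(matrix(stats::rnorm(n * cfg$n_background), n),
                        G) * b_amp
  }
  if (cfg$noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n)

  # nuisance leakage into the features
  leak_sd <- cfg$covariate_spec$leakage_sd
  if (is.null(leak_sd)) leak_sd <- 0
  site_mat <- stats::model.matrix(~ site - 1)
  Cmat <- cbind(scale(site_mat, scale = FALSE), motion = motion, sleep)
  if (leak_sd > 0)
    X <- X + Cmat %*% matrix(stats::rnorm(ncol(Cmat) * p, sd = leak_sd),
                             ncol(Cmat))
  dimnames(X) <- list(ids, feat$names)
  attr(X, "blocks") <- feat$blocks

  # six-level chronotype responses at two visits
  lev <- chronotype_levels()
  raw <- ifelse(y < 0,
                ifelse(stats::runif(n) < 0.6, lev[1], lev[2]),
                ifelse(stats::runif(n) < 0.6, lev[4], lev[3]))
  noncod <- stats::runif(n) < cfg$noncodable_rate
  raw[noncod] <- sample(lev[5:6], sum(noncod), replace = TRUE)
  raw_follow <- raw
  flip <- !noncod & stats::runif(n) < cfg$inconsistency_rate
  raw_follow[flip] <- ifelse(y[flip] < 0, lev[4], lev[1])
  shift_work <- stats::runif(n) < cfg$shift_work_rate

  participants <- data.frame(
    id = ids, age = age, sex = sex,
    chronotype_raw = raw, chronotype_raw_followup = raw_follow,
    shift_work_flag = shift_work, site = site, motion = motion,
    stringsAsFactors = FALSE)
  participants <- cbind(participants, as.data.frame(sleep))

  fams <- names(cfg$n_phenotypes_per_family)
  phenome <- list()
  effect_map <- NULL
  for (f in fams) {
    made <- make_phenome_family(f, cfg$n_phenotypes_per_family[[f]], Z, cfg)
    rownames(made$x) <- ids
    phenome[[f]] <- made$x
    effect_map <- rbind(effect_map, made$effect_map)
  }

  rownames(Z) <- ids
  colnames(Z) <- paste0("mode", seq_len(k))
  bundle <- structure(list(participants = participants, brain = X,
                           phenome = phenome),
                      class = "cohort_bundle")
  truth <- structure(list(latent_scores = Z, true_loadings = L,
                          true_target_correlations = cfg$mode_strengths,
                          phenotype_effect_map = effect_map,
                          target = stats::setNames(y, ids),
                          config = cfg),
                     class = "cohort_truth")
  list(bundle = bundle, truth = truth)
}

#' Generate an external GMV-only cohort sharing planted loading structure
#'
#' Emulates applying an adult-trained model to an independent developmental
#' cohort in which only grey-matter volume is available: the external
#' cohort's GMV features are generated from the *same* planted GMV loading
#' vectors as the source cohort (restricted to GMV and renormalised to unit
#' norm), while ages, covariates, background structure and noise are drawn
#' afresh. Use [external_cohort_config()] to derive a configuration whose
#' age-latent associations are sign-reversed relative to the source.
#'
#' @param config A `cohort_config` whose FA and FC blocks are empty (see
#'   [external_cohort_config()]).
#' @param truth The `cohort_truth` returned by [generate_cohort()] for the
#'   source cohort.
#' @return As [generate_cohort()]: a list with `bundle` and `truth`.
#' @export
generate_external_cohort <- function(config, truth) {
  validate_cohort_config(config)
  stopifnot(inherits(truth, "cohort_truth"))
  src_blocks <- attr(truth$true_loadings, "blocks")
  if (is.null(src_blocks))
    src_blocks <- feature_names_for(truth$config$block_sizes)$blocks
  gmv_rows <- src_blocks == "GMV"
  if (!any(gmv_rows))
    stop("source ground truth has no GMV loadings", call. = FALSE)
  if (config$block_sizes$gmv != sum(gmv_rows))
    stop("external GMV block size must match the source cohort (",
         sum(gmv_rows), " features)", call. = FALSE)
  if (config$block_sizes$fa != 0 || config$block_sizes$fc_components != 0)
    stop("external cohort must be GMV-only", call. = FALSE)
  if (config$n_modes != ncol(truth$true_loadings))
    stop("external n_modes must match the source ground truth", call. = FALSE)
  L <- truth$true_loadings[gmv_rows, , drop = FALSE]
  nrm <- sqrt(colSums(L^2))
  if (any(nrm == 0))
    stop("a planted mode has no GMV support; cannot build an external ",
         "cohort from it", call. = FALSE)
  L <- sweep(L, 2, nrm, "/")
  rownames(L) <- feature_names_for(config$block_sizes)$names
  generate_cohort_impl(config, loadings_override = L)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  blocks <- attr(x$brain, "blocks")
  cat("Synthetic cohort bundle\n")
  cat("  participants:", nrow(x$participants), "\n")
  cat("  brain features:", ncol(x$brain), "(",
      paste(sprintf("%s=%d", names(table(blocks)[unique(blocks)]),
                    table(blocks)[unique(blocks)]), collapse = ", "), ")\n")
  cat("  phenome families:",
      paste(sprintf("%s=%d", names(x$phenome),
                    vapply(x$phenome, ncol, 0L)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("Cohort ground truth:", ncol(x$latent_scores), "planted mode(s);",
      "target correlations",
      paste(format(x$true_target_correlations, digits = 3),
            collapse = ", "), "\n")
  invisible(x)
}
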