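#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles every knob of [run_pipeline()]: the synthetic cohort (or a
#' directory of previously written cohort tables), model order, resampling
#' depths, significance levels, the transfer feature subset, age brackets,
#' and a single global seed from which every stage derives its own stream
#' (`stage seed = seed + 97 * stage index`, all below 2^31).
#'
#' @param cohort A [cohort_config()] describing the cohort to simulate, or
#'   a directory path holding tables written by [write_cohort()].
#' @param external Optional [external_cohort_config()] for the projection
#'   stage; `NULL` skips simulating an external cohort unless the transfer
#'   stage finds `external/` tables in the output directory.
#' @param k Number of PLS components to extract.
#' @param n_permutations,n_bootstraps Resampling depths.
#' @param alpha_perm Component-significance level for the permutation test.
#' @param alpha_assoc Family-wise level before Bonferroni division.
#' @param subset Feature subset for cross-cohort projection (block tag or
#'   feature names).
#' @param brackets,brackets_external Age-bracket breakpoints for the source
#'   and external cohorts.
#' @param seed Global integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            external = NULL,
                            k = 10,
                            n_permutations = 1000,
                            n_bootstraps = 1000,
                            alpha_perm = 0.001,
                            alpha_assoc = 0.05,
                            subset = "GMV",
                            brackets = age_brackets_ukb(),
                            brackets_external = age_brackets_abcd(),
                            seed = 1L) {
  stopifnot(k >= 1, n_permutations >= 1, n_bootstraps >= 2,
            alpha_perm > 0, alpha_perm < 1,
            alpha_assoc > 0, alpha_assoc < 1)
  if (is.character(cohort) && !dir.exists(cohort))
    stop("cohort directory does not exist: ", cohort, call. = FALSE)
  structure(list(cohort = cohort, external = external, k = as.integer(k),
                 n_permutations = as.integer(n_permutations),
                 n_bootstraps = as.integer(n_bootstraps),
                 alpha_perm = alpha_perm, alpha_assoc = alpha_assoc,
                 subset = subset, brackets = brackets,
                 brackets_external = brackets_external,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  stages <- c(simulate = 1L, fit = 2L, permute = 3L, bootstrap = 4L,
              phewas = 5L, project = 6L, stratify = 7L)
  (config$seed + 97L * stages[[stage]]) %% .Machine$integer.max
}

#' Run the chronotype subtyping pipeline end to end
#'
#' Executes, in order, any subset of the stages: `simulate` (draw the
#' synthetic cohort, or load it from disk), `fit` (preprocess and fit the
#' PLS model; writes `model.json` and `scores.tsv`), `permute`
#' (`perm_pvalues.tsv`), `bootstrap` (`boot_ci.tsv`), `phewas` (one
#' `assoc_<family>.tsv` per family plus `assoc_hits.tsv`), `project`
#' (simulate/load the external cohort, write `projection.json` and
#' `external_scores.tsv`) and `stratify` (`age_summary.tsv` for both
#' cohorts). Every artifact is written atomically, inputs are never
#' mutated, and `manifest.json` records the configuration, per-stage seeds,
#' row/column counts, wall time and output checksums — enough to re-run the
#' pipeline bit-identically with the same code version.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Stages to run (default: all, in canonical order).
#' @param quiet Suppress per-stage log lines.
#' @return The manifest (a list), invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "fit", "permute",
                                    "bootstrap", "phewas", "project",
                                    "stratify"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else
      list(package_version =
             as.character(utils::packageVersion("chronopls")),
           seed = config$seed, stages = list())
  say <- function(...) if (!quiet) message("[chronopls] ", ...)
  note <- function(stage, seed, counts, elapsed, files) {
    manifest$stages[[stage]] <<- list(
      seed = seed, counts = counts, wall_time_s = round(elapsed, 3),
      outputs = as.list(vapply(files, function(f)
        unname(tools::md5sum(file.path(out_dir, f))), "")))
  }

  load_cohort <- function() {
    cdir <- file.path(out_dir, "cohort")
    if (!dir.exists(cdir))
      stop("no cohort found under ", cdir,
           "; run the simulate stage first", call. = FALSE)
    read_cohort(cdir)
  }
  load_model <- function() {
    path <- file.path(out_dir, "model.json")
    if (!file.exists(path))
      stop("no fitted model at ", path, "; run the fit stage first",
           call. = FALSE)
    read_chronopls(path)
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    sseed <- stage_seed(config, stage)
    switch(stage,
      simulate = {
        if (is.character(config$cohort)) {
          sim <- read_cohort(config$cohort)
          write_cohort(sim$bundle, file.path(out_dir, "cohort"), sim$truth)
        } else {
          cfg <- config$cohort
          cfg$seed <- sseed
          sim <- generate_cohort(cfg)
          write_cohort(sim$bundle, file.path(out_dir, "cohort"), sim$truth)
        }
        say("simulate: ", nrow(sim$bundle$participants), " participants, ",
            ncol(sim$bundle$brain), " brain features")
        note(stage, sseed,
             list(n = nrow(sim$bundle$participants),
                  p = ncol(sim$bundle$brain)),
             proc.time()[["elapsed"]] - t0,
             file.path("cohort",
                       list.files(file.path(out_dir, "cohort"))))
      },
      fit = {
        sim <- load_cohort()
        prep <- preprocess_cohort(sim$bundle)
        fit <- chronopls(prep$x, prep$y, k = config$k)
        write_chronopls(fit, file.path(out_dir, "model.json"))
        write_tsv(data.frame(id = prep$ids, fit$T, check.names = FALSE),
                  file.path(out_dir, "scores.tsv"))
        say("fit: ", prep$report$n_analyzed, " participants analyzed, k = ",
            config$k, "; rho1 = ", format(fit$rho[1], digits = 3))
        note(stage, sseed,
             c(prep$report, list(k = config$k)),
             proc.time()[["elapsed"]] - t0,
             c("model.json", "scores.tsv"))
      },
      permute = {
        sim <- load_cohort()
        prep <- preprocess_cohort(sim$bundle)
        perm <- permutation_test(prep$x, prep$y, k = config$k,
                                 n_permutations = config$n_permutations,
                                 seed = sseed)
        write_tsv(data.frame(component = seq_len(config$k),
                             rho = perm$observed_rho,
                             p = perm$p_values,
                             significant = perm$p_values <
                               config$alpha_perm),
                  file.path(out_dir, "perm_pvalues.tsv"))
        say("permute: B = ", perm$B, "; p = ",
            paste(format(perm$p_values, digits = 3), collapse = ", "))
        note(stage, sseed, list(B = perm$B, k = config$k),
             proc.time()[["elapsed"]] - t0, "perm_pvalues.tsv")
      },
      bootstrap = {
        sim <- load_cohort()
        prep <- preprocess_cohort(sim$bundle)
        boot <- bootstrap_loadings(prep$x, prep$y, k = config$k,
                                   n_bootstraps = config$n_bootstraps,
                                   seed = sseed)
        blocks <- attr(prep$x, "blocks")
        long <- data.frame(
          feature = rep(rownames(boot$ci_low), config$k),
          block = rep(if (is.null(blocks)) NA_character_ else blocks,
                      config$k),
          component = rep(colnames(boot$ci_low),
                          each = nrow(boot$ci_low)),
          loading = as.vector(boot$reference$P),
          ci_low = as.vector(boot$ci_low),
          ci_high = as.vector(boot$ci_high),
          significant = as.vector(boot$significant))
        write_tsv(long, file.path(out_dir, "boot_ci.tsv"))
        say("bootstrap: B = ", boot$B, "; robust loadings per component: ",
            paste(colSums(boot$significant), collapse = ", "))
        note(stage, sseed, list(B = boot$B, redraws = boot$n_redraws),
             proc.time()[["elapsed"]] - t0, "boot_ci.tsv")
      },
      phewas = {
        sim <- load_cohort()
        prep <- preprocess_cohort(sim$bundle)
        fit <- load_model()
        all_hits <- NULL
        files <- character(0)
        for (f in names(prep$phenome)) {
          tab <- association_scan(fit$T, prep$phenome[[f]], family = f,
                                  alpha = config$alpha_assoc)
          fn <- paste0("assoc_", f, ".tsv")
          write_tsv(as.data.frame(tab), file.path(out_dir, fn))
          files <- c(files, fn)
          hits <- summarize_hits(tab)
          if (nrow(hits)) all_hits <- rbind(all_hits, hits)
          say("phewas[", f, "]: ", sum(tab$significant, na.rm = TRUE),
              " significant associations at p < ",
              format(tab$threshold[1], digits = 3))
        }
        if (is.null(all_hits))
          all_hits <- data.frame(component = character(0),
                                 family = character(0),
                                 phenotype = character(0))
        write_tsv(all_hits, file.path(out_dir, "assoc_hits.tsv"))
        note(stage, sseed,
             list(families = names(prep$phenome)),
             proc.time()[["elapsed"]] - t0, c(files, "assoc_hits.tsv"))
      },
      project = {
        fit <- load_model()
        sim <- load_cohort()
        edir <- file.path(out_dir, "external")
        if (!is.null(config$external)) {
          ecfg <- config$external
          ecfg$seed <- sseed
          ext <- generate_external_cohort(ecfg, sim$truth)
          write_cohort(ext$bundle, edir, ext$truth)
        } else if (dir.exists(edir)) {
          ext <- read_cohort(edir)
        } else {
          stop("project stage needs either config$external or existing ",
               edir, " tables", call. = FALSE)
        }
        proj <- build_projection(fit, config$subset)
        eprep <- preprocess_cohort(ext$bundle)
        exs <- project_cohort(proj, eprep$x[, proj$feature_subset,
                                            drop = FALSE])
        write_atomic(function(tmp)
          jsonlite::write_json(
            list(feature_subset = proj$feature_subset,
                 rotation = unname(proj$rotation),
                 condition_number = proj$condition_number, k = proj$k),
            tmp, digits = NA, auto_unbox = TRUE),
          file.path(out_dir, "projection.json"))
        write_tsv(data.frame(id = eprep$ids, exs, check.names = FALSE),
                  file.path(out_dir, "external_scores.tsv"))
        say("project: ", length(proj$feature_subset), " features, ",
            nrow(exs), " external participants")
        note(stage, sseed,
             list(n_external = nrow(exs),
                  p_subset = length(proj$feature_subset)),
             proc.time()[["elapsed"]] - t0,
             c("projection.json", "external_scores.tsv"))
      },
      stratify = {
        sim <- load_cohort()
        prep <- preprocess_cohort(sim$bundle)
        fit <- load_model()
        summ <- age_bracket_summary(fit$T, prep$participants$age,
                                    config$brackets)
        summ$cohort <- "source"
        espath <- file.path(out_dir, "external_scores.tsv")
        if (file.exists(espath) &&
            dir.exists(file.path(out_dir, "external"))) {
          exs <- utils::read.delim(espath, check.names = FALSE)
          ext <- read_cohort(file.path(out_dir, "external"))
          ages <- ext$bundle$participants$age[
            match(exs$id, ext$bundle$participants$id)]
          esumm <- age_bracket_summary(as.matrix(exs[, -1, drop = FALSE]),
                                       ages, config$brackets_external)
          esumm$cohort <- "external"
          summ <- rbind(summ, esumm)
        }
        write_tsv(summ, file.path(out_dir, "age_summary.tsv"))
        say("stratify: ", nrow(summ), " bracket x component rows")
        note(stage, sseed, list(rows = nrow(summ)),
             proc.time()[["elapsed"]] - t0, "age_summary.tsv")
      })
  }
  write_atomic(function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA),
    manifest_path)
  invisible(manifest)
}
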