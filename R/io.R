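# Tab-separated readers/writers for cohort tables and JSON serialization
# for models and ground truth. All writes are atomic (temp file + rename)
# so a failed stage never leaves a truncated artifact.

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write_atomic(function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE), path)
}

#' Write a cohort bundle as tab-separated tables
#'
#' Emits `participants.tsv`, `brain.tsv` (with a leading `#block`
#' annotation line tagging every feature column), one
#' `phenome_<family>.tsv` per family (with `#category` and `#type` header
#' lines), and — when ground truth is supplied — `ground_truth.json` and
#' `config.yaml`.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if absent).
#' @param truth Optional `cohort_truth` to serialize alongside.
#' @return `dir`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(bundle, dir, truth = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$participants, file.path(dir, "participants.tsv"))

  blocks <- attr(bundle$brain, "blocks")
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(paste(c("#block", blocks), collapse = "\t"), con)
    writeLines(paste(c("id", colnames(bundle$brain)), collapse = "\t"), con)
    utils::write.table(
      data.frame(id = rownames(bundle$brain),
                 as.data.frame(bundle$brain), check.names = FALSE),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }, file.path(dir, "brain.tsv"))

  for (f in names(bundle$phenome)) {
    m <- bundle$phenome[[f]]
    write_atomic(function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      writeLines(paste(c("#category", attr(m, "category")),
                       collapse = "\t"), con)
      writeLines(paste(c("#type", attr(m, "type")), collapse = "\t"), con)
      writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
      utils::write.table(
        data.frame(id = rownames(m), as.data.frame(m),
                   check.names = FALSE),
        con, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    }, file.path(dir, paste0("phenome_", f, ".tsv")))
  }

  if (!is.null(truth)) {
    write_ground_truth(truth, file.path(dir, "ground_truth.json"))
    write_atomic(function(tmp)
      yaml::write_yaml(unclass(truth$config), tmp),
      file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the tables.
#' @return A list with `bundle` (class `cohort_bundle`) and `truth` (the
#'   deserialized ground truth, or `NULL` if none was written).
#' @export
read_cohort <- function(dir) {
  pt <- utils::read.delim(file.path(dir, "participants.tsv"),
                          stringsAsFactors = FALSE)
  brain_path <- file.path(dir, "brain.tsv")
  hdr <- readLines(brain_path, n = 2)
  blocks <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-1]
  cols <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]]
  raw <- utils::read.delim(brain_path, skip = 2, header = FALSE,
                           col.names = cols, check.names = FALSE,
                           stringsAsFactors = FALSE)
  brain <- as.matrix(raw[, -1, drop = FALSE])
  rownames(brain) <- raw$id
  if (length(blocks) != ncol(brain))
    stop("brain.tsv block annotation does not match its feature columns",
         call. = FALSE)
  attr(brain, "blocks") <- blocks

  phe_files <- list.files(dir, pattern = "^phenome_.*\\.tsv$")
  phenome <- list()
  for (pf in phe_files) {
    fam <- sub("^phenome_(.*)\\.tsv$", "\\1", pf)
    path <- file.path(dir, pf)
    hdr <- readLines(path, n = 3)
    category <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-1]
    type <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-1]
    cols <- strsplit(hdr[3], "\t", fixed = TRUE)[[1]]
    raw <- utils::read.delim(path, skip = 3, header = FALSE,
                             col.names = cols, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- raw$id
    attr(m, "family") <- fam
    attr(m, "type") <- type
    attr(m, "category") <- category
    phenome[[fam]] <- m
  }
  bundle <- structure(list(participants = pt, brain = brain,
                           phenome = phenome), class = "cohort_bundle")
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) read_ground_truth(truth_path)
  list(bundle = bundle, truth = truth)
}

as_named_matrix <- function(x, rn = NULL, cn = NULL) {
  m <- as.matrix(x)
  if (!is.null(rn)) rownames(m) <- rn
  if (!is.null(cn)) colnames(m) <- cn
  m
}

#' Serialize / deserialize cohort ground truth as JSON
#'
#' @param truth A `cohort_truth`.
#' @param path File path.
#' @return `write_ground_truth()`: the path, invisibly;
#'   `read_ground_truth()`: a `cohort_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "cohort_truth"))
  payload <- list(
    ids = rownames(truth$latent_scores),
    modes = colnames(truth$latent_scores),
    features = rownames(truth$true_loadings),
    latent_scores = unname(truth$latent_scores),
    true_loadings = unname(truth$true_loadings),
    true_target_correlations = truth$true_target_correlations,
    target = unname(truth$target),
    phenotype_effect_map = truth$phenotype_effect_map,
    config = unclass(truth$config))
  write_atomic(function(tmp)
    jsonlite::write_json(payload, tmp, digits = I(17), auto_unbox = TRUE,
                         null = "null"), path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- j$config
  cfg$block_sizes <- as.list(cfg$block_sizes)
  cfg$covariate_spec <- as.list(cfg$covariate_spec)
  class(cfg) <- "cohort_config"
  structure(list(
    latent_scores = as_named_matrix(j$latent_scores, j$ids, j$modes),
    true_loadings = as_named_matrix(j$true_loadings, j$features, j$modes),
    true_target_correlations = j$true_target_correlations,
    phenotype_effect_map = j$phenotype_effect_map,
    target = stats::setNames(as.numeric(j$target), j$ids),
    config = cfg), class = "cohort_truth")
}

#' Serialize / deserialize a fitted model as JSON
#'
#' The round trip is lossless to full double precision (numbers are
#' written with 17 significant digits).
#'
#' @param model A `chronopls` fit.
#' @param path File path.
#' @return `write_chronopls()`: the path, invisibly; `read_chronopls()`:
#'   a `chronopls` object.
#' @export
write_chronopls <- function(model, path) {
  stopifnot(inherits(model, "chronopls"))
  payload <- list(
    class = "chronopls",
    package_version = as.character(utils::packageVersion("chronopls")),
    k = model$k, n = model$n,
    features = model$features, blocks = model$blocks,
    components = colnames(model$W),
    ids = rownames(model$T),
    W = unname(model$W), P = unname(model$P), T = unname(model$T),
    y_loadings = model$y_loadings,
    x_center = unname(model$x_center), x_scale = unname(model$x_scale),
    y_center = model$y_center, y_scale = model$y_scale,
    rho = model$rho, x_total_ss = model$x_total_ss, y = model$y)
  write_atomic(function(tmp)
    jsonlite::write_json(payload, tmp, digits = I(17), auto_unbox = TRUE,
                         null = "null"), path)
}

#' @rdname write_chronopls
#' @export
read_chronopls <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$class, "chronopls"))
    stop(path, " does not hold a serialized chronopls model", call. = FALSE)
  cn <- j$components
  structure(list(
    W = as_named_matrix(j$W, j$features, cn),
    P = as_named_matrix(j$P, j$features, cn),
    T = as_named_matrix(j$T, j$ids, cn),
    y_loadings = j$y_loadings,
    x_center = stats::setNames(j$x_center, j$features),
    x_scale = stats::setNames(j$x_scale, j$features),
    y_center = j$y_center, y_scale = j$y_scale,
    rho = j$rho, k = j$k, n = j$n, x_total_ss = j$x_total_ss,
    features = j$features, blocks = j$blocks,
    y = j$y, call = NULL), class = "chronopls")
}
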