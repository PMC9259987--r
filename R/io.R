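# File formats and model bundles. Matrices travel as tab-separated text
# (rows = samples, header of feature identifiers, first column = sample
# identifiers, "NA" for missing). Trained models are published as bundle
# directories: a JSON manifest (architecture, privacy record, seed, format
# version, weights checksum) plus a text weights file written at full
# double precision so reloaded models predict bit-identically. Bundles
# contain model parameters only — never any row of training data.

#' Read a sample-by-feature matrix from tab-separated text
#'
#' Expects a header row of feature identifiers and a first column of sample
#' identifiers; remaining cells must be numeric or `NA`. Ragged rows,
#' duplicated identifiers, and non-numeric cells are parse errors naming
#' the offending line or identifier.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with sample row names and feature column names;
#'   missing values are `NA`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(fields) < 2L)
    stop(sprintf("%s: need a header and at least one sample row", path),
         call. = FALSE)
  if (length(unique(fields)) != 1L) {
    bad <- which(fields != fields[1L])[1L]
    stop(sprintf("%s: ragged row at line %d", path, bad), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate sample id '%s'", path,
                 ids[duplicated(ids)][1L]), call. = FALSE)
  feats <- colnames(df)[-1L]
  if (length(feats) == 0L)
    stop(sprintf("%s: no feature columns", path), call. = FALSE)
  if (anyDuplicated(feats))
    stop(sprintf("%s: duplicate feature id '%s'", path,
                 feats[duplicated(feats)][1L]), call. = FALSE)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(num) & raw != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s: non-numeric cell '%s' at line %d, column '%s'",
                 path, raw[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L] + 1L,
                 feats[bad[1L, 2L]]), call. = FALSE)
  dimnames(num) <- list(ids, feats)
  num
}

#' Write a sample-by-feature matrix as tab-separated text
#'
#' The inverse of [read_matrix()]: header of feature identifiers, first
#' column of sample identifiers, `NA` for missing entries, values at full
#' double precision (so write-then-read round-trips exactly). Identifiers
#' are generated when absent. A matrix with no columns is refused.
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path) {
  x <- as_numeric_matrix(x)
  if (ncol(x) == 0L || nrow(x) == 0L)
    stop("refusing to write a degenerate (empty) matrix", call. = FALSE)
  ids <- rownames(x) %||% sprintf("s%04d", seq_len(nrow(x)))
  feats <- colnames(x) %||% sprintf("g%04d", seq_len(ncol(x)))
  cells <- matrix(sprintf("%.17g", x), nrow(x))
  cells[is.na(x)] <- "NA"
  lines <- c(paste(c("sample_id", feats), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(ids[i], cells[i, ]), collapse = "\t"), character(1)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to '%s'", path), call. = FALSE)
  invisible(path)
}

bundle_classes <- c("dp_autoencoder", "dp_classifier", "dp_regressor")

#' Publish a trained model as a bundle directory
#'
#' Writes the only artifact this framework ever publishes: the trained
#' model. The bundle holds a `manifest.json` (format version, model class,
#' architecture spec, the privacy record `{alpha, total/per-step/spent
#' epsilon, steps, sigma, clip_norm}`, training configuration, seed, and an
#' MD5 checksum of the weights file) and `weights.txt` (layer weights and
#' biases at full double precision). No training data, codes, or any other
#' intermediate representation is written.
#'
#' @param object A fitted [dp_autoencoder()], [dp_classifier()] or
#'   [dp_regressor()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_bundle <- function(object, dir) {
  cls <- class(object)[1L]
  if (!cls %in% bundle_classes)
    stop("cannot bundle objects of class '", cls, "'", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wpath <- file.path(dir, "weights.txt")
  lines <- unlist(lapply(seq_along(object$params), function(l) {
    W <- object$params[[l]]$W; b <- object$params[[l]]$b
    c(sprintf("layer %d W %d %d", l, nrow(W), ncol(W)),
      paste(sprintf("%.17g", as.numeric(W)), collapse = " "),
      sprintf("layer %d b %d", l, length(b)),
      paste(sprintf("%.17g", b), collapse = " "))
  }))
  writeLines(lines, wpath)
  manifest <- list(
    format_version = "1",
    class = cls,
    spec = object$spec,
    privacy = privacy_record(object$privacy),
    config = object$config,
    seed = object$seed,
    weights_md5 = unname(tools::md5sum(wpath)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Load a published model bundle
#'
#' Verifies the format version and the weights checksum, then rebuilds the
#' model object; a loaded bundle predicts bit-identically to the object
#' that was saved.
#'
#' @param dir A bundle directory written by [save_bundle()].
#' @return The model object (class recorded in the manifest).
#' @export
load_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  wpath <- file.path(dir, "weights.txt")
  if (!file.exists(mpath) || !file.exists(wpath))
    stop(sprintf("'%s' is not a model bundle (missing manifest or weights)",
                 dir), call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.character(manifest$format_version), "1"))
    stop(sprintf("unsupported bundle format version '%s'",
                 manifest$format_version), call. = FALSE)
  if (!identical(unname(tools::md5sum(wpath)), manifest$weights_md5))
    stop("weights checksum mismatch: bundle corrupted or tampered with",
         call. = FALSE)
  lines <- readLines(wpath)
  params <- list()
  i <- 1L
  while (i < length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    l <- as.integer(hdr[2L])
    vals <- scan(text = lines[i + 1L], quiet = TRUE)
    if (hdr[3L] == "W") {
      params[[l]] <- list(W = matrix(vals, as.integer(hdr[4L]),
                                     as.integer(hdr[5L])))
    } else {
      params[[l]]$b <- vals
    }
    i <- i + 2L
  }
  priv <- manifest$privacy
  accountant <- structure(
    list(alpha = priv$alpha, total_epsilon = null_inf(priv$total_epsilon),
         per_step_epsilon = null_inf(priv$per_step_epsilon),
         planned_steps = as.integer(priv$planned_steps),
         steps_taken = as.integer(priv$steps_taken),
         sigma = priv$sigma, clip_norm = null_inf(priv$clip_norm)),
    class = "rdp_accountant")
  spec <- manifest$spec
  if (!is.null(spec$widths)) spec$widths <- as.integer(spec$widths)
  if (!is.null(spec$hidden)) spec$hidden <- as.integer(spec$hidden)
  structure(list(params = params, spec = spec, privacy = accountant,
                 config = manifest$config, seed = manifest$seed),
            class = manifest$class)
}

# JSON has no Inf; it round-trips as the string "Inf" (or null). Map it
# back to a number for non-private bundles.
null_inf <- function(x) {
  if (is.null(x)) return(Inf)
  x <- suppressWarnings(as.numeric(x))
  if (is.na(x)) Inf else x
}
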