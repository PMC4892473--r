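#' Validated methylation matrix
#'
#' Wraps and validates a samples x CpGs beta-value matrix: no missing
#' entries, all values in \[0,1\], at least 4 samples. Zero-variance
#' columns are permitted but recorded in the `"constant_cpgs"` attribute so
#' downstream tests can flag or drop them.
#'
#' @param values Numeric matrix, samples in rows.
#' @param cpg_ids Column labels (defaults to existing colnames).
#' @param sample_ids Row labels (defaults to existing rownames).
#' @return The matrix with class `methylation_matrix` prepended.
#' @export
methylation_matrix <- function(values, cpg_ids = colnames(values),
                               sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %d; resolve missingness upstream",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (nrow(values) < 4) stop("need at least 4 samples", call. = FALSE)
  if (ncol(values) < 1) stop("need at least 1 CpG", call. = FALSE)
  if (any(values < 0) || any(values > 1)) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta-value %.4g at row %d, column %d is outside [0, 1]",
                 values[bad[1], bad[2]], bad[1], bad[2]), call. = FALSE)
  }
  if (is.null(cpg_ids)) cpg_ids <- sprintf("cpg%02d", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(nrow(values)))
  dimnames(values) <- list(sample_ids, cpg_ids)
  attr(values, "constant_cpgs") <- cpg_ids[matrixStats_colVars(values) <=
                                             .Machine$double.eps * 100]
  class(values) <- c("methylation_matrix", class(values))
  values
}

detect_delim <- function(line) {
  if (grepl("\t", line)) "\t" else ","
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a header of CpG IDs and sample IDs in the first column; the
#' delimiter (tab or comma) is auto-detected from the header unless given.
#' A dataset written by [write_dataset()] may carry a phenotype column `y`,
#' which is split off and returned alongside the matrix.
#'
#' @param path File path.
#' @param delim Optional explicit delimiter.
#' @return A `methylation_matrix`; if the file has a `y` column, the 0/1
#'   phenotype vector is attached as attribute `"phenotype"`.
#' @export
read_beta_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- detect_delim(header)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                      row.names = 1L, colClasses = "character"),
    error = function(e) stop(sprintf("malformed table in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  y <- NULL
  if ("y" %in% colnames(df)) {
    y <- as.integer(df[["y"]])
    df <- df[, setdiff(colnames(df), "y"), drop = FALSE]
  }
  values <- matrix(NA_real_, nrow(df), ncol(df),
                   dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at line %d, column '%s'",
                   df[bad[1], j], bad[1] + 1L, colnames(df)[j]), call. = FALSE)
    }
    values[, j] <- v
  }
  out <- methylation_matrix(values)
  if (!is.null(y)) attr(out, "phenotype") <- y
  out
}

#' Write a simulated dataset as TSV
#'
#' One row per sample: sample ID, phenotype column `y`, then one column per
#' CpG with full-precision beta-values. [read_beta_matrix()] reads the file
#' back bit-identically.
#'
#' @param G Methylation matrix (samples x CpGs).
#' @param y Binary phenotype vector.
#' @param path Output path.
#' @export
write_dataset <- function(G, y, path) {
  G <- as.matrix(G)
  stopifnot(length(y) == nrow(G))
  ids <- rownames(G)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(nrow(G)))
  Gchr <- matrix(sprintf("%.17g", G), nrow(G), ncol(G),
                 dimnames = dimnames(G))   # full double precision
  df <- data.frame(sample_id = ids, y = as.integer(y),
                   Gchr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CpG set definitions
#'
#' Two-column delimited text (set label, CpG ID), as used for gene-region
#' sets. Membership lists keep the file order, are de-duplicated, and may
#' overlap between sets. Empty sets are skipped with a warning; IDs absent
#' from a particular matrix are reported at test time, not here.
#'
#' @param path File path.
#' @param delim Optional delimiter (auto-detected otherwise).
#' @return Named list mapping set label to a character vector of CpG IDs.
#' @export
read_set_definitions <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- detect_delim(first)
  df <- utils::read.table(path, header = FALSE, sep = delim,
                          col.names = c("set", "cpg"),
                          colClasses = "character")
  sets <- split(df$cpg, factor(df$set, levels = unique(df$set)))
  sets <- lapply(sets, function(v) unique(v[nzchar(v)]))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("skipping empty set(s): %s",
                    paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  sets
}

#' Write test results or simulation summaries
#'
#' TSV output is the flat table; JSON output embeds run metadata (seed,
#' package version, configuration hash) alongside the records, and adds a
#' scientific-notation display column for p-values (e.g. `4.06E-05`).
#'
#' @param results Data frame from [run_set_tests()],
#'   [estimate_rejection_rate()], or a list of test objects.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param seed Seed recorded in the metadata.
#' @param config Optional list recorded (and hashed) in the metadata.
#' @export
write_results <- function(results, path, format = c("tsv", "json"),
                          seed = NA_integer_, config = list()) {
  format <- match.arg(format)
  if (!is.data.frame(results)) {
    if (inherits(results, "cpg_set_test")) results <- list(results)
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(method = r$method, statistic = r$statistic,
                 df = if (is.null(r$df) || is.na(r$df)) NA_real_ else r$df,
                 p.value = r$p.value)))
    if (is.null(results)) {
      results <- data.frame(method = character(), statistic = numeric(),
                            df = numeric(), p.value = numeric())
    }
  }
  if ("p.value" %in% names(results)) {
    results$p_display <- vapply(results$p.value, format_pvalue_scientific, "")
  }
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(
      metadata = list(
        package = "cpgset",
        version = as.character(utils::packageVersion("cpgset")),
        seed = seed,
        config = config,
        config_hash = config_hash(config),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      ),
      results = results
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  h <- 5381
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
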