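#' Read a numeric matrix from delimited text
#'
#' Reads CSV/TSV matrices with an optional header row of variable identifiers
#' and an optional first column of observation identifiers (detected when the
#' first column is non-numeric, or forced via `row_ids`).  Missing values,
#' non-numeric cells and ragged rows are errors, reported with the offending
#' line or column.
#'
#' @param path file path.
#' @param delimiter field separator; `"auto"` picks tab for `.tsv`/`.tab`
#'   files and comma otherwise.
#' @param header logical; does the first row hold variable identifiers?
#' @param row_ids `"auto"`, `TRUE` or `FALSE`: is the first column an
#'   identifier column?
#' @return list with `values` (numeric matrix), `row_ids` and `col_ids`
#'   (character or `NULL`).
#' @export
read_matrix <- function(path, delimiter = "auto", header = TRUE,
                        row_ids = "auto") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (identical(delimiter, "auto")) {
    if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  } else delimiter
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged input: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  ids <- NULL
  has_ids <- if (identical(row_ids, "auto")) {
    ncol(df) > 1L && !is.numeric(df[[1L]])
  } else isTRUE(row_ids)
  if (has_ids) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric value in column %d, data line %d", j,
                   if (is.na(bad_row)) 1L else bad_row))
    }
    if (anyNA(col)) {
      stop(sprintf("missing value in column %d, data line %d", j,
                   which(is.na(col))[1L]))
    }
  }
  values <- as.matrix(df)
  rownames(values) <- ids
  list(values = values, row_ids = ids, col_ids = if (header) colnames(values) else NULL)
}

#' Write a numeric matrix as delimited text
#'
#' Full-precision companion to [read_matrix()].
#'
#' @param values numeric matrix.
#' @param path output path.
#' @param delimiter field separator.
#' @param row_ids optional identifiers written as a first column.
#' @export
write_matrix <- function(values, path, delimiter = ",", row_ids = NULL) {
  df <- as.data.frame(values)
  # 17 significant digits: doubles survive the text round trip exactly
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  if (!is.null(row_ids)) df <- cbind(id = row_ids, df)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value config file
#'
#' One `key = value` assignment per line; `#` starts a comment.  Values are
#' parsed as logical (`true`/`false`), numeric where possible, and character
#' otherwise; comma-separated values become vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("config line without '=': %s", ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    parse1 <- function(v) {
      if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) return(num)
      v
    }
    parsed <- lapply(parts, parse1)
    out[[key]] <- if (length(parsed) == 1L) parsed[[1L]] else unlist(parsed)
  }
  out
}

#' Serialise a fitted model to a JSON + CSV bundle
#'
#' Writes the weights, loadings and scores as CSVs plus a JSON file holding
#' the settings and the convergence log.
#'
#' @param fit a `spcovr_fit`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_model_bundle <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    weights = file.path(dir, "weights.csv"),
    loadings_x = file.path(dir, "loadings_x.csv"),
    loadings_y = file.path(dir, "loadings_y.csv"),
    scores = file.path(dir, "scores.csv")
  )
  utils::write.csv(fit$weights, paths["weights"], row.names = FALSE)
  utils::write.csv(fit$loadings_x, paths["loadings_x"], row.names = FALSE)
  utils::write.csv(fit$loadings_y, paths["loadings_y"], row.names = FALSE)
  utils::write.csv(fit$scores, paths["scores"], row.names = FALSE)
  meta <- list(
    settings = unclass(fit$settings),
    summary = unclass(fit$summary),
    convergence = fit$convergence,
    best_start = fit$best_start,
    iterations = fit$iterations
  )
  json_path <- file.path(dir, "model.json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, model = json_path))
}
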