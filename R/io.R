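#' Write an experiment result to disk
#'
#' Serialises a result table (a criterion-proportion table, a
#' traditional-paradigm experiment, or any plain data.frame) to CSV or JSON.
#' Provenance metadata — master seed, replicate count, N — is carried in
#' `#`-prefixed comment lines for CSV and in a `meta` element for JSON, so a
#' written file can be read back with [read_results()] without loss.
#'
#' @param x Result object or data.frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  meta <- list()
  if (inherits(x, "slodr_table")) {
    meta <- list(kind = "contemporary", n_reps = x$n_reps, n = x$n,
                 seed = x$seed, n_nonconverged = x$n_nonconverged)
    df <- data.frame(criterion = rownames(x$proportions), x$proportions,
                     check.names = FALSE)
  } else if (inherits(x, "slodr_saturation")) {
    meta <- list(kind = "traditional", n_reps = x$n_reps, n = x$n, seed = x$seed)
    df <- x$subgroups
  } else if (is.data.frame(x)) {
    df <- x
  } else {
    stop("cannot serialise objects of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(meta))
      writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
    utils::write.csv(df, con, row.names = FALSE)
  } else {
    jsonlite::write_json(list(meta = meta, results = df), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a result file written by [write_results()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return List with `meta` (named list, possibly empty) and `results`
#'   (data.frame).
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    lines <- readLines(path)
    meta_lines <- grep("^# ", lines, value = TRUE)
    meta <- list()
    for (ml in meta_lines) {
      kv <- sub("^# ", "", ml)
      key <- sub(":.*$", "", kv)
      val <- sub("^[^:]*: *", "", kv)
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
    df <- utils::read.csv(text = paste(lines[!startsWith(lines, "# ")],
                                       collapse = "\n"), check.names = FALSE)
    list(meta = meta, results = df)
  } else {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    list(meta = as.list(out$meta), results = as.data.frame(out$results))
  }
}
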