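#' Write a spectrum to delimited text
#'
#' Two tab-separated columns (`frequency_hz`, `amplitude_m`) preceded by
#' `#`-prefixed metadata lines (bundle id, environment).
#'
#' @param spectrum A `spectrum` object.
#' @param path Output file path.
#' @param extra Optional named character vector of additional metadata.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, extra = NULL) {
  stopifnot(inherits(spectrum, "spectrum"))
  meta <- c(bundle_id = as.character(spectrum$bundle_id),
            environment = spectrum$environment, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  writeLines("frequency_hz\tamplitude_m", con)
  utils::write.table(
    data.frame(spectrum$frequency, signif(spectrum$amplitude, 8)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from delimited text
#'
#' Accepts tab- or comma-separated two-column files with `#` metadata
#' header as written by [write_spectrum()].
#'
#' @param path Input file path.
#' @return A `spectrum` object; metadata lines become attributes.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  sep <- if (grepl(",", body[length(body)])) "," else "\t"
  has_header <- grepl("[A-Za-z]", body[1])
  df <- utils::read.table(text = body, sep = sep, header = has_header)
  if (ncol(df) < 2) stop("spectrum file must have two columns: ", path)
  sp <- new_spectrum(df[[1]], df[[2]],
                     environment = meta$environment %||% "air",
                     bundle_id = meta$bundle_id %||% NA_character_)
  attr(sp, "metadata") <- meta
  sp
}

#' Write and read delimited tables
#'
#' Thin wrappers fixing the pipeline's table convention: tab-separated,
#' header row, no quoting or row names. The reader also accepts commas.
#'
#' @param table A data frame.
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns a data frame.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a machine-readable run report
#'
#' Serializes a list of results, parameters and seeds to JSON; the JSON
#' report is the source of truth from which human-readable tables derive.
#'
#' @param report A named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
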