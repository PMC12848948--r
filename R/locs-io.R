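# Localization table I/O.
#
# The mandatory schema is the common SMLM convention: frame, x, y, photons;
# sx, sy and precision_nm are carried when present, and any extra columns
# round-trip untouched. CSV is the primary on-disk format; Apache Parquet
# (via the arrow package) is available for large tables. An HDF5 dialect is
# not provided.

loc_mandatory <- c("frame", "x", "y", "photons")

check_loc_schema <- function(table, where = "localization table") {
  missing <- setdiff(loc_mandatory, names(table))
  if (length(missing)) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  where, paste(missing, collapse = ", ")))
  }
  invisible(table)
}

#' Read and write localization tables
#'
#' Lossless round trip for CSV (and Parquet when the arrow package is
#' available; select by file extension `.csv` / `.parquet`). Mandatory
#' columns follow the common single-molecule convention (`frame`, `x`, `y`,
#' `photons`); extra columns are preserved.
#'
#' @param table A localization tibble.
#' @param path File path ending in `.csv` or `.parquet`.
#' @return `write_locs()` returns `path` invisibly; `read_locs()` returns a
#'   tibble.
#' @export
write_locs <- function(table, path) {
  check_loc_schema(table)
  ext <- tolower(tools::file_ext(path))
  if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("parquet output needs the arrow package.")
    }
    arrow::write_parquet(table, path)
  } else if (ext == "csv") {
    readr::write_csv(table, path)
  } else {
    abort(sprintf("unsupported localization file type '.%s' (use .csv or .parquet).",
                  ext))
  }
  invisible(path)
}

#' @rdname write_locs
#' @export
read_locs <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("parquet input needs the arrow package.")
    }
    tibble::as_tibble(arrow::read_parquet(path))
  } else if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    abort(sprintf("unsupported localization file type '.%s' (use .csv or .parquet).",
                  ext))
  }
  check_loc_schema(tab, where = path)
  tab
}
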