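#' Write or read a run table with a metadata header
#'
#' Hits, singles and coincidence tables are plain columnar data.frames; this
#' pair of helpers stores them as CSV files prefixed with `#`-commented
#' metadata lines (run seed, geometry mode, event count, ...), one file per
#' run.
#'
#' @param x data.frame to store.
#' @param path output file path.
#' @param meta named list of scalar metadata values.
#' @return `write_run_table` returns `path` invisibly; `read_run_table`
#'   returns the data.frame with the metadata attached as attribute
#'   `"meta"`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_run_table(data.frame(a = 1:3), path, meta = list(seed = 7))
#' attr(read_run_table(path), "meta")$seed
#' @export
write_run_table <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, format(meta[[key]])), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_table
#' @export
read_run_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*: *", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), hdr)])
  attr(df, "meta") <- meta
  df
}
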