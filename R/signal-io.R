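#' Read and write sampled signals as CSV
#'
#' The on-disk dialect is a plain CSV with a header row of channel labels,
#' preceded by one metadata comment line of the form
#' `#rate_hz=<num>,t0_s=<num>`. Values are written with 15 significant
#' digits, so a write/read round trip is lossless to better than 1e-12
#' relative tolerance.
#'
#' @param signal A [sampled_signal()].
#' @param path File path.
#' @return `write_signal_csv()` returns `path` invisibly; `read_signal_csv()`
#'   returns a [sampled_signal()].
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#rate_hz=%.15g,t0_s=%.15g", signal$rate_hz, signal$t0_s), con)
  writeLines(paste(signal$labels, collapse = ","), con)
  body <- apply(signal$values, 1L, function(r) {
    paste(sprintf("%.15g", r), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  meta <- readLines(path, n = 1L)
  if (!grepl("^#rate_hz=", meta)) {
    stop("not a signal CSV: missing '#rate_hz=' metadata line in ", path,
         call. = FALSE)
  }
  fields <- strsplit(sub("^#", "", meta), ",")[[1]]
  kv <- vapply(strsplit(fields, "="), function(p) as.numeric(p[2]), numeric(1))
  names(kv) <- vapply(strsplit(fields, "="), `[`, character(1), 1L)
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  sampled_signal(as.matrix(df), colnames(df), kv[["rate_hz"]], kv[["t0_s"]])
}
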