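#' Read a hypnogram from a TSV file
#'
#' Expected dialect: two tab-separated columns with header
#' `epoch_index<TAB>state`; epoch indices are 0-based and must be contiguous
#' from 0; states are `WAKE`, `NREM` or `REM`. Epoch length and start
#' zeitgeber time may be declared in `#epoch_length=`/`#start_zt=` comment
#' lines (defaults 4 s and ZT0).
#'
#' @param path TSV file path.
#' @return A [hypnogram].
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list(epoch_length = 4, start_zt = 0)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
  }
  tab <- utils::read.delim(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                           colClasses = c("integer", "character"))
  idx <- tab[[1]]
  expected <- seq(0L, length(idx) - 1L)
  if (!identical(idx, expected)) {
    gap <- expected[which(idx != expected)[1]]
    stop(sprintf("non-contiguous epoch indices: gap at %d", gap))
  }
  hypnogram(tab[[2]], epoch_length = kv$epoch_length,
            start_zeitgeber_time = kv$start_zt)
}

#' Write a hypnogram to a TSV file
#'
#' Inverse of [read_hypnogram()]; round-trips exactly.
#'
#' @param hyp A [hypnogram].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#epoch_length=%g", hyp$epoch_length), con)
  writeLines(sprintf("#start_zt=%g", hyp$start_zeitgeber_time), con)
  writeLines("epoch_index\tstate", con)
  writeLines(sprintf("%d\t%s", seq_along(hyp$labels) - 1L, hyp$labels), con)
  invisible(path)
}
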