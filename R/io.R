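#' Read a multichannel signal or phase file
#'
#' Reads delimited text (comma or tab separated, header row of channel
#' labels, one row per sample). A `time` (or `time_s`) column is used when
#' present; otherwise `fs` must be given and a time axis is synthesised.
#'
#' @param path file path.
#' @param fs sampling rate (Hz), required when the file has no time column.
#' @return A signal tibble (see [signal-tibbles]).
#' @export
read_signals <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- as_tibble(utils::read.table(path, header = TRUE, sep = sep))
  if ("time_s" %in% names(df)) names(df)[names(df) == "time_s"] <- "time"
  if (!"time" %in% names(df)) {
    if (is.null(fs)) abort("File has no time column; supply `fs`.")
    df <- dplyr::mutate(df, time = (dplyr::row_number() - 1L) / fs,
                        .before = 1L)
  }
  df
}

#' Write phases (or any channel tibble) as CSV
#'
#' Writes `time_s` followed by one `<label>_rad` column per phase channel.
#'
#' @param phases phase tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phases <- function(phases, path) {
  out <- phases
  names(out)[names(out) == "time"] <- "time_s"
  chans <- setdiff(names(out), c("time_s", "trial"))
  names(out)[match(chans, names(out))] <- paste0(chans, "_rad")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
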