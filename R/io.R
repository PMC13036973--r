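#' Write / read an IMU session as CSV plus JSON sidecar
#'
#' The CSV holds `time_s` and one column per channel; the sidecar
#' (`<path>.json`) holds sample rate, scenario segments, injury events,
#' dropout intervals and subject id. Values round-trip to the declared
#' precision (12 significant digits).
#'
#' @param stream An `imu_stream`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  df <- as.data.frame(stream$data)
  df[] <- lapply(df, function(x) format(x, digits = 12, trim = TRUE,
                                        scientific = FALSE))
  df[is.na(stream$data)] <- NA
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  meta <- list(sample_rate = stream$sample_rate,
               channels = stream$channels,
               segments = stream$segments,
               events = stream$events,
               dropout = stream$dropout,
               subject = stream$subject)
  jsonlite::write_json(meta, paste0(path, ".json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^time_s", header)) {
    abort("malformed IMU CSV: missing `time_s` header")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  t <- df$time_s
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    abort(sprintf("non-monotone timestamps at line %d", bad[1L] + 2L))
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else NULL
  as_tib <- function(x, template) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x)) template
    else tibble::as_tibble(x)
  }
  new_imu_stream(
    tibble::as_tibble(df),
    sample_rate = meta$sample_rate %||% round(1 / median(diff(t))),
    segments = as_tib(meta$segments, tibble::tibble(
      scenario = character(), start_s = double(), end_s = double())),
    events = as_tib(meta$events, empty_events()),
    dropout = as_tib(meta$dropout, empty_dropout()),
    subject = meta$subject %||% NA_character_
  )
}
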