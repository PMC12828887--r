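#' Write / read a session recording as plain CSV files
#'
#' The on-disk layout of a session is a directory of three CSV files:
#' `trials.csv` (the trial table), `units.csv` (per-unit parameters), and
#' `counts_long.csv` (`unit`, `trial`, `bin`, `count`; zero counts are
#' omitted), plus `meta.json` with the session id, region and time grid.
#'
#' @param session A `session_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_csv <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$units, file.path(dir, "units.csv"),
                   row.names = FALSE)
  nz <- which(session$counts != 0, arr.ind = TRUE)
  long <- data.frame(unit = nz[, 1], trial = nz[, 2], bin = nz[, 3],
                     count = session$counts[nz])
  long <- long[order(long$unit, long$trial, long$bin), ]
  utils::write.csv(long, file.path(dir, "counts_long.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(session_id = session$session_id, region = session$region,
         time_bins_ms = session$time_bins_ms,
         dims = dim(session$counts)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  units <- utils::read.csv(file.path(dir, "units.csv"),
                           stringsAsFactors = FALSE)
  long <- utils::read.csv(file.path(dir, "counts_long.csv"))
  counts <- array(0L, dim = meta$dims)
  counts[cbind(long$unit, long$trial, long$bin)] <- as.integer(long$count)
  structure(list(
    session_id = meta$session_id, region = meta$region,
    trials = trials, counts = counts,
    time_bins_ms = as.numeric(meta$time_bins_ms), units = units
  ), class = "session_recording")
}
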