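# On-disk formats: flat binary int16 + JSON sidecar for continuous signals
# (the layout of open-source acquisition systems), CSV for event tables, JSON
# for ground truth.

#' Write a recording as flat binary int16 + JSON sidecar
#'
#' Signals are interleaved sample-major (all channels of sample 1, then
#' sample 2, ...) as little-endian int16 scaled by `scale_uv_per_bit`. The
#' sidecar records the sampling rate, channel names, regions and scale; the
#' accelerometer (if any) goes to `<prefix>_accel.bin`, events to
#' `<prefix>_events.csv`.
#'
#' @param rec a `recording`.
#' @param prefix file path prefix (no extension).
#' @param scale_uv_per_bit microvolts per integer step (default 0.195, a
#'   common amplifier scale).
#' @return invisibly, the sidecar path.
#' @export
write_recording <- function(rec, prefix, scale_uv_per_bit = 0.195) {
  dat <- as.integer(round(rec$signals / scale_uv_per_bit))
  dat <- pmax(pmin(dat, 32767L), -32768L)
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.integer(dat[seq_along(dat)]), con, size = 2L,
           endian = "little")
  close(con)
  side <- list(fs = rec$fs, n_channels = nrow(rec$signals),
               n_samples = ncol(rec$signals),
               channels = rownames(rec$signals), regions = rec$regions,
               scale_uv_per_bit = scale_uv_per_bit,
               seed = rec$meta$seed)
  if (!is.null(rec$accel)) {
    cona <- file(paste0(prefix, "_accel.bin"), "wb")
    writeBin(as.numeric(rec$accel), cona, size = 8L, endian = "little")
    close(cona)
    side$accel_file <- basename(paste0(prefix, "_accel.bin"))
  }
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(rec$events)) {
    utils::write.csv(rec$events, paste0(prefix, "_events.csv"),
                     row.names = FALSE)
  }
  invisible(paste0(prefix, ".json"))
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix file path prefix used at write time.
#' @return a `recording` (values quantized to the int16 scale).
#' @export
read_recording <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  raw <- readBin(con, integer(), n = side$n_channels * side$n_samples,
                 size = 2L, signed = TRUE, endian = "little")
  close(con)
  sig <- matrix(raw * side$scale_uv_per_bit, nrow = side$n_channels)
  rownames(sig) <- side$channels
  accel <- NULL
  if (!is.null(side$accel_file)) {
    cona <- file(file.path(dirname(paste0(prefix, ".json")),
                           side$accel_file), "rb")
    accel <- matrix(readBin(cona, numeric(), n = 3L * side$n_samples,
                            size = 8L, endian = "little"), nrow = 3L)
    close(cona)
  }
  ev_path <- paste0(prefix, "_events.csv")
  events <- if (file.exists(ev_path)) {
    utils::read.csv(ev_path, stringsAsFactors = FALSE)
  } else NULL
  recording(sig, side$fs, side$regions, accel = accel, events = events,
            meta = list(seed = side$seed))
}

#' Write ground truth as JSON
#' @param gt a `ground_truth`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
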