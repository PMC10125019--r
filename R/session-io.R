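#' Write a session to a flat on-disk layout
#'
#' Persists an LFP recording, sorted units and a speed trace as a directory of
#' Parquet / CSV / JSON files:
#' \describe{
#'   \item{lfp.parquet}{`timestamp_s`, `artifact`, then one column per channel
#'     (named by channel id).}
#'   \item{channels.csv}{channel metadata, see [as_channel_info()].}
#'   \item{units.parquet}{unit metadata with a `spike_times` list column.}
#'   \item{speed.csv}{behavioural speed trace.}
#'   \item{session.json}{sampling rate, start time, voltage unit.}
#' }
#'
#' @param session A list with elements `lfp` ([lfp_recording()]), `units`
#'   (tibble with a `spike_times` list column), `speed` (tibble from
#'   [speed_trace()]).
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rec <- session$lfp
  lfp_df <- as_tibble(as.data.frame(t(rec$samples)))
  names(lfp_df) <- rec$channel_info$channel_id
  lfp_df <- bind_cols(tibble(timestamp_s = lfp_times(rec),
                             artifact = rec$artifact_mask), lfp_df)
  arrow::write_parquet(lfp_df, file.path(path, "lfp.parquet"))
  readr::write_csv(rec$channel_info, file.path(path, "channels.csv"))
  if (!is.null(session$units)) {
    arrow::write_parquet(session$units, file.path(path, "units.parquet"))
  }
  if (!is.null(session$speed)) {
    readr::write_csv(session$speed, file.path(path, "speed.csv"))
  }
  meta <- list(sampling_rate = rec$sampling_rate,
               start_time = rec$start_time, unit = rec$unit)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from the flat on-disk layout
#'
#' Inverse of [write_session()], with the integrity checks applied to the raw
#' dataset in the source study: a non-monotonic LFP time axis is a
#' data-integrity error, and byte-identical LFP traces on distinct probes
#' raise a duplicate-trace warning.
#'
#' @param path Session directory.
#' @return List with `lfp`, `units` (or `NULL`), `speed` (or `NULL`).
#' @export
read_session <- function(path) {
  required <- c("lfp.parquet", "channels.csv", "session.json")
  missing <- required[!file.exists(file.path(path, required))]
  if (length(missing) > 0) {
    abort(paste0("session at ", path, " is missing: ",
                 paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  lfp_df <- arrow::read_parquet(file.path(path, "lfp.parquet"))
  ts <- lfp_df$timestamp_s
  if (length(ts) > 1 && any(diff(ts) <= 0)) {
    abort("LFP timestamps are not monotonically increasing",
          class = "ripplemapr_data_integrity")
  }
  channels <- as_channel_info(
    readr::read_csv(file.path(path, "channels.csv"), show_col_types = FALSE))
  chan_cols <- as.matrix(lfp_df[, channels$channel_id, drop = FALSE])
  # duplicate traces across distinct probes
  if (nrow(channels) > 1) {
    key <- apply(chan_cols, 2, function(v) rlang::hash(v))
    for (k in unique(key[duplicated(key)])) {
      probes <- unique(channels$probe_id[key == k])
      if (length(probes) > 1) {
        warn(paste0("byte-identical LFP traces on distinct probes: ",
                    paste(probes, collapse = ", ")))
      }
    }
  }
  samples <- t(chan_cols)
  dimnames(samples) <- NULL
  rec <- lfp_recording(samples, meta$sampling_rate, channels,
                       start_time = meta$start_time,
                       artifact_mask = lfp_df$artifact, unit = meta$unit)
  units <- NULL
  if (file.exists(file.path(path, "units.parquet"))) {
    units <- arrow::read_parquet(file.path(path, "units.parquet"))
    if ("spike_times" %in% names(units)) {
      units$spike_times <- lapply(units$spike_times, as.numeric)
    }
  }
  speed <- NULL
  if (file.exists(file.path(path, "speed.csv"))) {
    speed <- readr::read_csv(file.path(path, "speed.csv"),
                             show_col_types = FALSE)
  }
  list(lfp = rec, units = units, speed = speed)
}
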