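#' Validate and normalise channel metadata
#'
#' Checks a table of channel metadata (one row per recording channel) against
#' the area vocabulary used throughout the package and flags channels whose
#' anatomical annotation is ambiguous (e.g. a compound label such as "HPF"
#' instead of a specific subfield). Flagged channels are kept in the table but
#' marked `excluded = TRUE`, so downstream selections can drop them without
#' losing track of the original probe geometry.
#'
#' @param channels A data frame with columns `channel_id`, `probe_id`, `area`,
#'   and CCF coordinates `ap`, `dv`, `ml` (micrometres, anterior-posterior,
#'   dorso-ventral, medio-lateral).
#' @return A tibble with the same rows plus a logical `excluded` column.
#' @export
as_channel_info <- function(channels) {
  channels <- as_tibble(channels)
  required <- c("channel_id", "probe_id", "area", "ap", "dv", "ml")
  missing <- setdiff(required, names(channels))
  if (length(missing) > 0) {
    abort(paste0("channel table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  coords <- as.matrix(channels[, c("ap", "dv", "ml")])
  if (!all(is.finite(coords)) || any(coords < 0)) {
    bad <- channels$channel_id[!apply(is.finite(coords) & coords >= 0, 1, all)]
    abort(paste0("non-finite or negative CCF coordinates for channel(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  channels$excluded <- !(channels$area %in% AREA_VOCABULARY)
  channels
}

#' Construct a multi-channel LFP recording
#'
#' Bundles an LFP sample matrix with its sampling rate, channel metadata and a
#' per-sample artifact mask. Samples are stored channels x time; the time axis
#' is the implied uniform grid `start_time + (0:(n-1)) / sampling_rate`.
#'
#' @param samples Numeric matrix, channels x time.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_info Channel metadata, see [as_channel_info()]; one row per
#'   row of `samples`, in order.
#' @param start_time Time of the first sample, seconds.
#' @param artifact_mask Logical vector, one per time sample; `TRUE` marks
#'   samples excluded from analysis. Defaults to all `FALSE`.
#' @param unit Unit label for the stored voltages (default `"uV"`).
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, sampling_rate, channel_info,
                          start_time = 0, artifact_mask = NULL, unit = "uV") {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (sampling_rate <= 0) abort("sampling_rate must be > 0")
  channel_info <- as_channel_info(channel_info)
  if (nrow(channel_info) != nrow(samples)) {
    abort("channel_info must have one row per channel (row of `samples`)")
  }
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, ncol(samples))
  if (length(artifact_mask) != ncol(samples)) {
    abort("artifact_mask length must equal the number of time samples")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         start_time = start_time, channel_info = channel_info,
         artifact_mask = as.logical(artifact_mask), unit = unit),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s, %s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate, x$unit))
  cat("  areas:", paste(unique(x$channel_info$area), collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of an LFP recording
#' @param rec An [lfp_recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
lfp_times <- function(rec) {
  rec$start_time + (seq_len(ncol(rec$samples)) - 1) / rec$sampling_rate
}

#' Construct a running-speed trace
#'
#' Stores a behavioural speed trace together with its z-scored version, which
#' is what the running-exclusion rule operates on. Missing samples (`NA`) are
#' preserved and treated as "no behavioural data available".
#'
#' @param times Sample times, seconds.
#' @param speed Speed in arbitrary units (same length as `times`).
#' @return A tibble with columns `time_s`, `speed`, `standardized_speed`.
#' @export
speed_trace <- function(times, speed) {
  if (length(times) != length(speed)) abort("times and speed must match")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("speed trace times must be strictly increasing")
  }
  mu <- mean(speed, na.rm = TRUE)
  s <- sd(speed, na.rm = TRUE)
  z <- if (isTRUE(s > 0)) (speed - mu) / s else speed * 0
  tibble(time_s = times, speed = speed, standardized_speed = z)
}

#' Per-probe positions from channel metadata
#'
#' Probe position is taken at the probe's (selected) CA1 channel, the same
#' convention used for ripple detection; if a probe has several CA1 channels
#' and no explicit selection is given, their mean position is used.
#'
#' @param channels Channel metadata (see [as_channel_info()]).
#' @param selected_channels Optional character vector of channel ids (one per
#'   probe) naming the channel whose position represents the probe.
#' @param area Area whose channels define the probe position.
#' @return Tibble with columns `probe_id`, `ap`, `dv`, `ml`.
#' @export
probe_positions <- function(channels, selected_channels = NULL, area = "CA1") {
  channels <- as_channel_info(channels)
  keep <- !channels$excluded & channels$area == area
  if (!is.null(selected_channels)) {
    keep <- keep & channels$channel_id %in% selected_channels
  }
  if (!any(keep)) abort(paste0("no usable ", area, " channels"))
  channels[keep, ] |>
    group_by(.data$probe_id) |>
    summarise(ap = mean(.data$ap), dv = mean(.data$dv), ml = mean(.data$ml),
              .groups = "drop")
}

#' Divide probes into medial / central / lateral sections
#'
#' Probes are ordered along the medio-lateral (M-L) axis and split into three
#' contiguous groups with counts as equal as possible; when the count is not
#' divisible by three the extra probes go to the more medial group(s). Ties in
#' M-L position are broken by probe id so the assignment does not depend on
#' input order.
#'
#' @param probes A data frame with columns `probe_id` and `ml` (CCF
#'   medio-lateral coordinate, micrometres), e.g. from [probe_positions()].
#' @return A tibble `probe_id`, `ml`, `section` (factor medial/central/lateral)
#'   with the two section boundaries (µm, midpoints between adjacent groups)
#'   stored in `attr(, "boundaries")`.
#' @export
assign_sections <- function(probes) {
  probes <- as_tibble(probes)
  if (!all(c("probe_id", "ml") %in% names(probes))) {
    abort("`probes` needs columns probe_id and ml")
  }
  probes <- distinct(probes, .data$probe_id, .keep_all = TRUE)
  n <- nrow(probes)
  if (n < 3) abort("need at least 3 probes to assign sections")
  ord <- order(probes$ml, probes$probe_id)
  probes <- probes[ord, ]
  base <- n %/% 3
  extra <- n %% 3
  sizes <- base + c(extra >= 1, extra >= 2, 0)  # remainder allotted medial-first
  section <- rep(c("medial", "central", "lateral"), times = sizes)
  out <- mutate(probes,
                section = factor(section,
                                 levels = c("medial", "central", "lateral")))
  cuts <- cumsum(sizes)[1:2]
  boundaries <- (out$ml[cuts] + out$ml[pmin(cuts + 1, n)]) / 2
  attr(out, "boundaries") <- boundaries
  out
}

#' Pairwise 3D distances between channels or probes
#'
#' Euclidean distance in CCF space (micrometres). Works on any table with an
#' id column and `ap`, `dv`, `ml` coordinates.
#'
#' @param positions Data frame with an id column (first of `channel_id` /
#'   `probe_id` found) and coordinates `ap`, `dv`, `ml`.
#' @return Symmetric distance matrix (µm) with ids as dimnames.
#' @export
pairwise_distances <- function(positions) {
  positions <- as_tibble(positions)
  id_col <- intersect(c("channel_id", "probe_id"), names(positions))[1]
  if (is.na(id_col)) abort("`positions` needs a channel_id or probe_id column")
  coords <- as.matrix(positions[, c("ap", "dv", "ml")])
  bad <- !apply(is.finite(coords), 1, all)
  if (any(bad)) {
    abort(paste0("missing coordinates for: ",
                 paste(positions[[id_col]][bad], collapse = ", ")))
  }
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(positions[[id_col]], positions[[id_col]])
  d
}
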