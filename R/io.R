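#' Write and read trajectory tables
#'
#' Trajectories travel between pipeline stages as plain CSV with one row per
#' well x frame: `well_id, frame, t_s, zt_h, x_mm, y_mm, found, moving`.
#' Missing positions (`found == FALSE`) have empty `x_mm`/`y_mm`; `moving`
#' is the generator's ground-truth flag and is empty for tracked data.
#'
#' @param trajectories A `plate_trajectories` list (or named list of
#'   `trajectory` data frames).
#' @param path CSV path.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a `plate_trajectories` list.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(names(trajectories), function(id) {
    tr <- trajectories[[id]]
    data.frame(well_id = id,
               frame = tr$frame, t_s = tr$t_s,
               zt_h = if ("zt_h" %in% names(tr)) tr$zt_h else NA_real_,
               x_mm = ifelse(tr$found, tr$x_mm, NA_real_),
               y_mm = ifelse(tr$found, tr$y_mm, NA_real_),
               found = tr$found,
               moving = if ("moving" %in% names(tr)) tr$moving else NA,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param frame_rate_hz Acquisition rate to attach; inferred from `t_s`
#'   spacing when `NULL`.
#' @export
read_trajectories <- function(path, frame_rate_hz = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "frame", "t_s", "x_mm", "y_mm", "found")
  if (!all(need %in% names(df)))
    stop("trajectory CSV lacks required columns", call. = FALSE)
  out <- lapply(split(df, df$well_id), function(d) {
    d <- d[order(d$frame), ]
    fr <- frame_rate_hz
    if (is.null(fr)) {
      dt <- diff(d$t_s)
      fr <- if (length(dt)) 1 / stats::median(dt) else 1
    }
    structure(data.frame(frame = d$frame, t_s = d$t_s, zt_h = d$zt_h,
                         x_mm = d$x_mm, y_mm = d$y_mm,
                         found = as.logical(d$found),
                         moving = if ("moving" %in% names(d))
                           as.logical(d$moving) else NA),
              well_id = d$well_id[1], frame_rate_hz = fr,
              t0_zt_h = d$zt_h[1],
              class = c("trajectory", "data.frame"))
  })
  # preserve plate order rather than alphabetical split order
  out <- out[unique(df$well_id)]
  structure(out, class = c("plate_trajectories", "list"))
}

#' Write / read a stimulus event log
#'
#' CSV with columns `trial, block, trial_in_block, t_s`.
#'
#' @param events Data frame as returned by [stim_events()].
#' @param path CSV path.
#' @export
write_stim_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stim_events
#' @export
read_stim_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("trial", "block", "t_s") %in% names(df)))
    stop("stimulus CSV lacks required columns", call. = FALSE)
  df
}
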