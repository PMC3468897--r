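#' Construct a frame stack
#'
#' Bundles an ordered list of grayscale frames (numeric matrices, 8-bit
#' values 0-255) with acquisition metadata.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param frame_rate_hz Acquisition rate (Hz).
#' @param t0_zt_h Zeitgeber time (h) of the first frame.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz, t0_zt_h = 0) {
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0", call. = FALSE)
  if (length(frames) == 0) stop("no frames", call. = FALSE)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must share dimensions", call. = FALSE)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 t0_zt_h = t0_zt_h, bit_depth = 8L),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames, %d x %d px, %.2f Hz, ZT0 = %g h\n",
              length(x$frames), d[2], d[1], x$frame_rate_hz, x$t0_zt_h))
  invisible(x)
}

# Dark-larva blob depth profile: flat core (the body) with a Gaussian skirt,
# ~1 mm overall diameter at the default calibration.
.blob_depth <- function(r_px, px_per_mm) {
  r_core <- 0.35 * px_per_mm
  sigma <- 0.10 * px_per_mm
  ifelse(r_px <= r_core, 1, exp(-(r_px - r_core)^2 / (2 * sigma^2)))
}

#' Render a plate video from trajectories
#'
#' Produces the synthetic counterpart of the recording setup: a light,
#' larva-free reference frame and a stack of frames with one dark blob per
#' occupied well at the trajectory position. The blob has a flat-intensity
#' body core with a Gaussian edge (overall diameter about 1 mm at the
#' configured calibration); each larva's body intensity is drawn once from
#' its group's pigmentation distribution, and i.i.d. Gaussian pixel noise is
#' added to every frame (and to the reference). Frames are 8-bit: values are
#' rounded and clamped to 0-255.
#'
#' @param trajectories A `plate_trajectories` list (or a named list of
#'   `trajectory` objects whose names are well ids of `layout`).
#' @param layout A [plate_layout()].
#' @param pigment_gray_mean,pigment_gray_sd Body intensity distribution;
#'   when `NULL`, taken per larva from the group parameters attached to the
#'   trajectories' assignment.
#' @param background Background gray level of the diffusive light panel.
#' @param noise_sd Standard deviation of additive pixel noise (gray levels).
#' @param frames Which frame indices (1-based into the trajectories) to
#'   render; defaults to all.
#' @param seed Optional integer seed.
#' @return A list with `stack` (a [frame_stack()]) and `reference` (matrix).
#' @examples
#' lay <- plate_layout(n_rows = 1, n_cols = 1)
#' ga <- group_assignment(lay, list(wt = preset_params("wildtype")))
#' pt <- simulate_plate(ga, duration_s = 10, seed = 1)
#' rf <- render_frames(pt, lay, noise_sd = 0, seed = 1)
#' dim(rf$reference)
#' @export
render_frames <- function(trajectories, layout, pigment_gray_mean = NULL,
                          pigment_gray_sd = NULL, background = 200,
                          noise_sd = 2, frames = NULL, seed = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  if (!is.null(seed)) set.seed(seed)
  ids <- names(trajectories)
  if (is.null(ids) || !all(ids %in% layout$well_id))
    stop("trajectory names must be well ids of the layout", call. = FALSE)
  r_mm <- well_radius_mm(layout)
  for (id in ids) {
    tr <- trajectories[[id]]
    ok <- !tr$found | (tr$x_mm^2 + tr$y_mm^2 <= (r_mm + 1e-9)^2)
    if (!all(ok))
      stop(sprintf("trajectory for well %s leaves its well", id),
           call. = FALSE)
  }
  n_avail <- nrow(trajectories[[1]])
  if (is.null(frames)) frames <- seq_len(n_avail)
  if (any(frames < 1 | frames > n_avail))
    stop("frame index out of range", call. = FALSE)

  assignment <- attr(trajectories, "assignment")
  params <- if (!is.null(assignment)) attr(assignment, "params") else NULL
  body <- numeric(length(ids)); names(body) <- ids
  for (id in ids) {
    if (!is.null(pigment_gray_mean)) {
      m <- pigment_gray_mean
      s <- if (is.null(pigment_gray_sd)) 0 else pigment_gray_sd
    } else if (!is.null(params)) {
      g <- assignment$group_label[match(id, assignment$well_id)]
      m <- params[[g]]$pigment_gray_mean
      s <- params[[g]]$pigment_gray_sd
    } else {
      m <- 80; s <- 0
    }
    body[id] <- min(max(rnorm(1, m, s), 0), 255)
  }

  h <- layout$image_h; w <- layout$image_w
  ppm <- layout$px_per_mm
  base <- matrix(background, nrow = h, ncol = w)
  pad <- ceiling(0.8 * ppm)   # blob support half-width in px
  quantize <- function(img) {
    if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
    matrix(pmin(pmax(round(img), 0), 255), h, w)
  }
  reference <- quantize(base)
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    img <- base
    for (id in ids) {
      tr <- trajectories[[id]]
      row <- frames[fi]
      if (!tr$found[row]) next
      cx <- layout$well_centers_px[id, "x"] + tr$x_mm[row] * ppm
      cy <- layout$well_centers_px[id, "y"] + tr$y_mm[row] * ppm
      jr <- max(1, floor(cx - pad)):min(w, ceiling(cx + pad))
      ir <- max(1, floor(cy - pad)):min(h, ceiling(cy + pad))
      px <- outer(rep(1, length(ir)), jr - 0.5)
      py <- outer(ir - 0.5, rep(1, length(jr)))
      depth <- .blob_depth(sqrt((px - cx)^2 + (py - cy)^2), ppm)
      img[ir, jr] <- img[ir, jr] - (background - body[id]) * depth
    }
    out[[fi]] <- quantize(img)
  }
  fr <- attr(trajectories[[1]], "frame_rate_hz")
  zt0 <- attr(trajectories[[1]], "t0_zt_h")
  list(stack = frame_stack(out, frame_rate_hz = if (is.null(fr)) 1 else fr,
                           t0_zt_h = if (is.null(zt0)) 0 else zt0),
       reference = reference)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' 8-bit grayscale, one page per frame. Metadata (frame rate, ZT origin) is
#' not stored in the TIFF; supply it again when reading.
#'
#' @param stack A [frame_stack()] (or a single matrix for `write_reference`).
#' @param path Output .tif path.
#' @return `write_*` return `path` invisibly; `read_frame_stack` returns a
#'   [frame_stack()]; `read_reference` a matrix.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_frame_stack
#' @param frame_rate_hz,t0_zt_h Metadata to attach on read.
#' @export
read_frame_stack <- function(path, frame_rate_hz, t0_zt_h = 0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frame_stack(lapply(pages, function(p) round(p * 255)),
              frame_rate_hz = frame_rate_hz, t0_zt_h = t0_zt_h)
}

#' @rdname write_frame_stack
#' @param reference A reference image matrix (0-255).
#' @export
write_reference <- function(reference, path) {
  tiff::writeTIFF(reference / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_reference <- function(path) {
  round(tiff::readTIFF(path) * 255)
}
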