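#' Reference subtraction
#'
#' Subtracts a video frame from a larva-free reference image of the same
#' scene, clamping at zero, so dark larvae on the light background become
#' bright signal on a dark field.
#'
#' @param frame,reference Numeric matrices of identical dimension (8-bit
#'   gray values).
#' @return Difference image `pmax(reference - frame, 0)`.
#' @examples
#' subtract_reference(matrix(80, 2, 2), matrix(200, 2, 2))
#' @export
subtract_reference <- function(frame, reference) {
  if (!identical(dim(frame), dim(reference)))
    stop("frame and reference dimensions differ", call. = FALSE)
  pmax(reference - frame, 0)
}

# Otsu-style 1-D threshold: the cut (midpoint between adjacent order
# statistics) minimizing total within-class variance. NA when degenerate.
split_two_means <- function(values) {
  v <- sort(unique(values))
  if (length(v) < 2) return(NA_real_)
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x); css <- cumsum(x^2)
  i <- seq_len(n - 1)          # split after the i-th order statistic
  ss1 <- css[i] - cs[i]^2 / i
  ss2 <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  keep <- x[i] < x[i + 1]      # only cuts between distinct values
  i <- i[keep]
  best <- i[which.min((ss1 + ss2)[keep])]
  (x[best] + x[best + 1]) / 2
}

#' Locate a larva centroid in one well
#'
#' Finds the intensity-weighted center of mass of the larva signal inside a
#' well ROI of a difference image: pixels above the detection threshold are
#' labeled into connected components (8-connectivity), the largest component
#' by pixel count is kept (rejecting reflections and debris), and its
#' difference-intensity-weighted centroid is returned in pixel coordinates
#' (pixel `[i, j]` center at `(j - 0.5, i - 0.5)`).
#'
#' @param diff_img Difference image (matrix, from [subtract_reference()]).
#' @param roi Logical matrix of the same dimension marking the well ROI.
#' @param intensity_threshold Detection threshold in gray levels; `NULL`
#'   (default) uses an Otsu-style two-means split of the ROI intensities
#'   with a floor of 10 gray levels.
#' @return Named numeric `c(x, y)` in pixels, or `c(NA, NA)` when no pixel
#'   exceeds the threshold.
#' @export
locate_centroid <- function(diff_img, roi, intensity_threshold = NULL) {
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  vals <- diff_img[roi]
  thr <- intensity_threshold
  if (is.null(thr)) {
    thr <- split_two_means(vals)
    thr <- if (is.na(thr)) 10 else max(thr, 10)
  }
  hit <- roi & diff_img > thr
  if (!any(hit)) return(c(x = NA_real_, y = NA_real_))
  lab <- EBImage::bwlabel(hit)
  counts <- tabulate(lab[lab > 0])
  comp <- which.max(counts)
  sel <- which(lab == comp, arr.ind = TRUE)
  w <- diff_img[sel]
  c(x = sum(w * (sel[, 2] - 0.5)) / sum(w),
    y = sum(w * (sel[, 1] - 0.5)) / sum(w))
}

#' Track all wells of a frame stack
#'
#' Composes [subtract_reference()], the well ROI map from [assign_wells()]
#' and [locate_centroid()] over every frame, returning one trajectory per
#' well in well-centered millimeter coordinates. Frames where no larva is
#' detected are flagged `found = FALSE` and left missing, not interpolated.
#'
#' @param stack A [frame_stack()].
#' @param reference Larva-free reference image (matrix).
#' @param layout A [plate_layout()] whose image size matches the frames.
#' @param intensity_threshold Passed to [locate_centroid()].
#' @param search_margin_mm Dilation of each well's search disc beyond its
#'   nominal radius, so the image of a larva sitting against the wall is
#'   not truncated by the ROI edge; capped automatically to keep search
#'   discs disjoint.
#' @return A `plate_trajectories` list (one `trajectory` per well).
#' @examples
#' lay <- plate_layout(n_rows = 1, n_cols = 1)
#' ga <- group_assignment(lay, list(wt = preset_params("wildtype")))
#' pt <- simulate_plate(ga, duration_s = 10, seed = 1)
#' rf <- render_frames(pt, lay, noise_sd = 0, seed = 1)
#' tk <- track(rf$stack, rf$reference, lay)
#' head(tk[["A1"]])
#' @export
track <- function(stack, reference, layout, intensity_threshold = NULL,
                  search_margin_mm = 0.6) {
  stopifnot(inherits(stack, "frame_stack"), inherits(layout, "plate_layout"))
  d <- dim(stack$frames[[1]])
  if (d[1] != layout$image_h || d[2] != layout$image_w)
    stop("layout image size does not match frames", call. = FALSE)
  margin <- max(0, min(search_margin_mm,
                       (layout$well_pitch_mm - layout$well_diameter_mm) / 2 -
                         0.05))
  search_layout <- layout
  search_layout$well_diameter_mm <- layout$well_diameter_mm + 2 * margin
  roi_map <- assign_wells(search_layout)
  n_wells <- length(layout$well_id)
  # bounding boxes so per-well work stays local
  boxes <- lapply(seq_len(n_wells), function(k) {
    idx <- which(roi_map == k, arr.ind = TRUE)
    list(ir = min(idx[, 1]):max(idx[, 1]),
         jr = min(idx[, 2]):max(idx[, 2]))
  })
  masks <- lapply(seq_len(n_wells), function(k) {
    b <- boxes[[k]]
    m <- roi_map[b$ir, b$jr]
    !is.na(m) & m == k
  })
  n_frames <- length(stack$frames)
  xs <- matrix(NA_real_, n_frames, n_wells)
  ys <- matrix(NA_real_, n_frames, n_wells)
  for (f in seq_len(n_frames)) {
    diff_img <- subtract_reference(stack$frames[[f]], reference)
    for (k in seq_len(n_wells)) {
      b <- boxes[[k]]
      ctr <- locate_centroid(diff_img[b$ir, b$jr], masks[[k]],
                             intensity_threshold)
      if (!is.na(ctr[1])) {
        xs[f, k] <- ctr[1] + (b$jr[1] - 1)
        ys[f, k] <- ctr[2] + (b$ir[1] - 1)
      }
    }
  }
  t_s <- (seq_len(n_frames) - 1) / stack$frame_rate_hz
  zt <- (stack$t0_zt_h + t_s / 3600) %% 24
  out <- vector("list", n_wells)
  names(out) <- layout$well_id
  for (k in seq_len(n_wells)) {
    found <- !is.na(xs[, k])
    out[[k]] <- structure(
      data.frame(frame = seq_len(n_frames) - 1L, t_s = t_s, zt_h = zt,
                 x_mm = (xs[, k] - layout$well_centers_px$x[k]) /
                   layout$px_per_mm,
                 y_mm = (ys[, k] - layout$well_centers_px$y[k]) /
                   layout$px_per_mm,
                 found = found),
      well_id = layout$well_id[k], frame_rate_hz = stack$frame_rate_hz,
      t0_zt_h = stack$t0_zt_h, well_radius_mm = well_radius_mm(layout),
      class = c("trajectory", "data.frame"))
  }
  structure(out, class = c("plate_trajectories", "list"))
}
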