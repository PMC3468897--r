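#' Plate layout and pixel calibration
#'
#' Describes the geometry of a multiwell recording plate as seen by the
#' camera: grid size, well diameter, pixel calibration and the pixel
#' coordinates of each well center. The default is a 24-well plate
#' (4 rows x 6 columns) with 7 mm wells imaged at 10 px/mm.
#'
#' Pixel coordinates use the image convention: origin at the top-left
#' corner, x increasing rightwards (columns), y downwards (rows), with the
#' center of pixel `[i, j]` at `(j - 0.5, i - 0.5)`. Millimeter coordinates
#' of tracked positions are relative to each well's center.
#'
#' @param n_rows,n_cols Well grid dimensions.
#' @param well_diameter_mm Well diameter (mm).
#' @param px_per_mm Pixel calibration (pixels per mm), > 0.
#' @param well_pitch_mm Center-to-center well spacing (mm); must exceed the
#'   well diameter so well discs do not overlap.
#' @param margin_mm Margin between the plate edge wells and the image border.
#'
#' @return An object of class `plate_layout`: a list with `n_rows`,
#'   `n_cols`, `well_diameter_mm`, `px_per_mm`, `image_w`, `image_h`,
#'   `well_id` (e.g. "A1".."D6", row-major) and `well_centers_px`
#'   (data frame `x`, `y`).
#' @examples
#' lay <- plate_layout()
#' head(lay$well_centers_px)
#' @export
plate_layout <- function(n_rows = 4, n_cols = 6, well_diameter_mm = 7,
                         px_per_mm = 10, well_pitch_mm = 9, margin_mm = 1) {
  if (px_per_mm <= 0) stop("px_per_mm must be > 0", call. = FALSE)
  if (well_pitch_mm <= well_diameter_mm)
    stop("wells overlap: well_pitch_mm must exceed well_diameter_mm",
         call. = FALSE)
  if (n_rows < 1 || n_cols < 1) stop("need at least one well", call. = FALSE)
  half <- well_pitch_mm / 2
  cx_mm <- margin_mm + half + (seq_len(n_cols) - 1) * well_pitch_mm
  cy_mm <- margin_mm + half + (seq_len(n_rows) - 1) * well_pitch_mm
  centers <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  centers <- centers[order(centers$row, centers$col), ]
  well_id <- paste0(LETTERS[centers$row], centers$col)
  out <- list(
    n_rows = n_rows, n_cols = n_cols,
    well_diameter_mm = well_diameter_mm,
    px_per_mm = px_per_mm,
    well_pitch_mm = well_pitch_mm,
    image_w = ceiling((2 * margin_mm + n_cols * well_pitch_mm) * px_per_mm),
    image_h = ceiling((2 * margin_mm + n_rows * well_pitch_mm) * px_per_mm),
    well_id = well_id,
    well_centers_px = data.frame(
      x = cx_mm[centers$col] * px_per_mm,
      y = cy_mm[centers$row] * px_per_mm,
      row.names = well_id)
  )
  structure(out, class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("Plate layout: %d x %d wells, %.1f mm diameter, %.1f px/mm, image %d x %d px\n",
              x$n_rows, x$n_cols, x$well_diameter_mm, x$px_per_mm,
              x$image_w, x$image_h))
  invisible(x)
}

#' Well radius in mm
#' @param layout A [plate_layout()].
#' @return Well radius (mm).
#' @export
well_radius_mm <- function(layout) layout$well_diameter_mm / 2

#' Map image pixels to wells
#'
#' Builds the region-of-interest map used to sort tracked coordinates by
#' well: each pixel whose center falls inside the disc of one well (radius =
#' well diameter / 2 around the well center) is assigned to that well;
#' pixels outside every disc are unassigned.
#'
#' @param layout A [plate_layout()].
#' @return An integer matrix of dimension `image_h` x `image_w`; entry
#'   `[i, j]` is the well index (into `layout$well_id`) owning pixel
#'   `(i, j)`, or `NA` for unassigned pixels.
#' @examples
#' lay <- plate_layout(n_rows = 1, n_cols = 2)
#' m <- assign_wells(lay)
#' table(m, useNA = "ifany")
#' @export
assign_wells <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  if (layout$well_pitch_mm <= layout$well_diameter_mm)
    stop("wells overlap", call. = FALSE)
  h <- layout$image_h; w <- layout$image_w
  r_px <- well_radius_mm(layout) * layout$px_per_mm
  px <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)   # pixel-center x
  py <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)  # pixel-center y
  roi <- matrix(NA_integer_, nrow = h, ncol = w)
  for (k in seq_along(layout$well_id)) {
    cx <- layout$well_centers_px$x[k]
    cy <- layout$well_centers_px$y[k]
    inside <- (px - cx)^2 + (py - cy)^2 <= r_px^2
    roi[inside] <- k
  }
  roi
}
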