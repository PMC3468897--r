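# Shared fixtures: everything is generated in code at test time.

one_well_layout <- function() plate_layout(n_rows = 1, n_cols = 1)

two_group_assignment <- function(layout = plate_layout(),
                                 p1 = preset_params("gr_mutant"),
                                 p2 = preset_params("wildtype")) {
  group_assignment(layout, list(gr_mutant = p1, wildtype = p2))
}

# brute-force intensity-weighted centroid over ALL above-threshold ROI
# pixels (no component labeling): the oracle for locate_centroid on
# single-blob images
brute_centroid <- function(diff_img, roi, thr) {
  sel <- which(roi & diff_img > thr, arr.ind = TRUE)
  if (nrow(sel) == 0) return(c(x = NA_real_, y = NA_real_))
  w <- diff_img[sel]
  c(x = sum(w * (sel[, 2] - 0.5)) / sum(w),
    y = sum(w * (sel[, 1] - 0.5)) / sum(w))
}

# a stationary trajectory at a fixed offset from the well center
still_trajectory <- function(n = 10, x = 0.5, y = -0.25,
                             frame_rate_hz = 0.5) {
  structure(
    data.frame(frame = seq_len(n) - 1L,
               t_s = (seq_len(n) - 1) / frame_rate_hz,
               zt_h = 0, x_mm = x, y_mm = y, found = TRUE),
    well_id = "A1", frame_rate_hz = frame_rate_hz, t0_zt_h = 0,
    well_radius_mm = 3.5, class = c("trajectory", "data.frame"))
}

# 100 Hz post-stimulus segment from per-frame step lengths along +x
segment_from_steps <- function(steps, stim_t = 0, frame_rate_hz = 100) {
  x <- c(0, cumsum(steps))
  data.frame(t_s = stim_t + (seq_along(x) - 1) / frame_rate_hz,
             x_mm = x, y_mm = 0)
}

# RMS tracking error (px) of a tracked plate against simulated ground truth
tracking_rms_px <- function(truth, tracked, px_per_mm) {
  err <- unlist(lapply(names(tracked), function(id) {
    a <- truth[[id]]; b <- tracked[[id]]
    sqrt((a$x_mm - b$x_mm)^2 + (a$y_mm - b$y_mm)^2) * px_per_mm
  }))
  sqrt(mean(err^2, na.rm = TRUE))
}
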