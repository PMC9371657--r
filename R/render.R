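#' Render a synthetic cohort as a 16-bit image stack
#'
#' Draws each cell as a uniform disk whose per-frame intensity equals its
#' trace value, on a zero background, and writes a multi-page 16-bit
#' grayscale TIFF (one page per frame) plus an ROI table. Intended as an
#' image-mode fixture for testing ROI extraction: per-frame pixel means
#' inside each ROI reproduce the trace intensities up to 16-bit
#' quantisation.
#'
#' @param dataset A `hicr_cohort` from [simulate_cohort()] (or any list with
#'   `traces` and `roi`).
#' @param tiff_path Output TIFF path.
#' @param roi_path Output ROI CSV path (cell_id, x_px, y_px, radius_px,
#'   distance_um).
#' @param geometry List: `width`, `height` (pixels), `px_per_um` (pixel pitch),
#'   `radius_px` (disk radius), `max_intensity` (a.u. mapped to the 16-bit
#'   full scale; default slightly above the observed maximum).
#' @return Invisibly, a list with `tiff_path`, `roi_path`, `source_px`
#'   (heat-source pixel, 0-based), `scale` (a.u. per full scale) and the ROI
#'   table used.
#' @export
render_image_stack <- function(dataset, tiff_path, roi_path,
                               geometry = list()) {
  traces <- dataset$traces
  roi <- dataset$roi
  keep <- !is.na(roi$x_px)
  roi <- roi[keep, , drop = FALSE]
  traces <- traces[roi$cell_id]
  if (length(traces) == 0L) stop("no placeable ROIs in dataset")
  n_frames <- length(traces[[1]]$time_s)
  if (n_frames == 0L) stop("traces have 0 frames")
  g <- utils::modifyList(list(width = 96, height = 96, px_per_um = 1,
                              radius_px = 4, max_intensity = NULL), geometry)
  cx <- g$width / 2
  cy <- g$height / 2
  x <- cx + roi$x_px * g$px_per_um
  y <- cy + roi$y_px * g$px_per_um
  rad <- rep_len(if (is.null(roi$radius_px)) g$radius_px else roi$radius_px,
                 nrow(roi))
  if (any(x - rad < 0 | x + rad > g$width - 1 |
          y - rad < 0 | y + rad > g$height - 1)) {
    stop("ROI outside image bounds; shrink distances or enlarge the frame")
  }
  # pairwise overlap check
  if (nrow(roi) > 1L) {
    dd <- as.matrix(stats::dist(cbind(x, y)))
    rs <- outer(rad, rad, "+")
    diag(dd) <- Inf
    if (any(dd < rs)) warning("overlapping ROIs in rendered stack")
  }
  imax <- g$max_intensity
  if (is.null(imax)) {
    imax <- 1.05 * max(vapply(traces, function(tr) max(tr$intensity_au),
                              numeric(1)))
  }
  masks <- lapply(seq_len(nrow(roi)), function(i) {
    xs <- pmax(0, floor(x[i] - rad[i])):pmin(g$width - 1, ceiling(x[i] + rad[i]))
    ys <- pmax(0, floor(y[i] - rad[i])):pmin(g$height - 1, ceiling(y[i] + rad[i]))
    grid <- expand.grid(px = xs, py = ys)
    grid <- grid[(grid$px - x[i])^2 + (grid$py - y[i])^2 <= rad[i]^2, ]
    grid
  })
  pages <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- matrix(0, nrow = g$height, ncol = g$width)
    for (i in seq_along(masks)) {
      v <- traces[[i]]$intensity_au[f] / imax
      img[cbind(masks[[i]]$py + 1L, masks[[i]]$px + 1L)] <- max(0, min(1, v))
    }
    # quantise to the 16-bit grid explicitly
    pages[[f]] <- round(img * 65535) / 65535
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16)
  out_roi <- data.frame(cell_id = roi$cell_id, x_px = x, y_px = y,
                        radius_px = rad, distance_um = roi$distance_um)
  utils::write.csv(out_roi, roi_path, row.names = FALSE)
  invisible(list(tiff_path = tiff_path, roi_path = roi_path,
                 source_px = c(x = cx, y = cy), scale = imax,
                 px_per_um = g$px_per_um, roi = out_roi))
}

#' Extract ROI-mean traces from an image stack
#'
#' Reads a multi-page grayscale TIFF and an ROI table (disk ROIs in 0-based
#' pixel coordinates) and returns, for each ROI, the per-frame mean pixel
#' intensity inside the disk as a [fluor_trace()]. The distance of each ROI
#' to the declared heat-source pixel is computed from the ROI centre.
#'
#' @param tiff_path Path to the TIFF stack (>= 2 pages).
#' @param roi ROI table (data frame with cell_id, x_px, y_px, radius_px) or
#'   path to such a CSV.
#' @param frame_interval_s Frame interval, s.
#' @param source_px Heat-source pixel, c(x, y), 0-based.
#' @param scale Intensity corresponding to the image full scale (a.u.);
#'   returned traces are in these units.
#' @param px_per_um Pixel pitch used to convert pixel distances to um.
#' @param protocol Optional [heat_protocol()] used to set laser-on flags.
#' @param channel Channel label for the returned traces.
#' @return Named list of [fluor_trace()].
#' @export
extract_rois <- function(tiff_path, roi, frame_interval_s = 0.2,
                         source_px = NULL, scale = 1, px_per_um = 1,
                         protocol = NULL, channel = "fluo4") {
  if (is.character(roi)) roi <- utils::read.csv(roi)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("image stack must have at least 2 pages")
  h <- nrow(pages[[1]])
  w <- ncol(pages[[1]])
  times <- (seq_along(pages) - 1L) * frame_interval_s
  on <- if (is.null(protocol)) rep(FALSE, length(times)) else {
    times > protocol$t_start + 1e-9 &
      times <= protocol$t_start + protocol$duration + 1e-9
  }
  out <- list()
  for (i in seq_len(nrow(roi))) {
    x <- roi$x_px[i]; y <- roi$y_px[i]; rad <- roi$radius_px[i]
    if (x - rad < 0 || x + rad > w - 1 || y - rad < 0 || y + rad > h - 1) {
      stop(sprintf("ROI '%s' outside image bounds", roi$cell_id[i]))
    }
    xs <- floor(x - rad):ceiling(x + rad)
    ys <- floor(y - rad):ceiling(y + rad)
    grid <- expand.grid(px = xs, py = ys)
    grid <- grid[(grid$px - x)^2 + (grid$py - y)^2 <= rad^2, ]
    idx <- cbind(grid$py + 1L, grid$px + 1L)
    vals <- vapply(pages, function(pg) mean(pg[idx]), numeric(1)) * scale
    dist_um <- if (is.null(source_px)) NA_real_ else {
      sqrt((x - source_px[1])^2 + (y - source_px[2])^2) / px_per_um
    }
    id <- as.character(roi$cell_id[i])
    out[[id]] <- fluor_trace(times, vals, laser_on = on, cell_id = id,
                             channel = channel, distance_um = dist_um)
  }
  out
}
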