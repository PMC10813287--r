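# Specimen width tracking from grayscale video frames: binarize, extract
# the silhouette boundary, split it into the four specimen edges, and
# report per-frame minimum width and extension.

#' Construct a frame object
#'
#' @param pixels Numeric matrix of grayscale intensities in `[0, 1]`; rows
#'   run along the loading (vertical) axis.
#' @param scale_mm_px Physical size of one pixel, mm.
#' @param t_s Frame timestamp, s.
#' @return An object of class `tissue_frame`.
#' @export
tissue_frame <- function(pixels, scale_mm_px, t_s = 0) {
  if (!is.matrix(pixels) || length(pixels) == 0) {
    abort("`pixels` must be a non-empty numeric matrix")
  }
  if (scale_mm_px <= 0) abort("`scale_mm_px` must be positive")
  structure(
    list(pixels = pixels, scale_mm_px = scale_mm_px, t_s = t_s),
    class = "tissue_frame"
  )
}

#' Render a synthetic specimen frame
#'
#' Draws the silhouette of a uniaxially stretched specimen (bright rectangle
#' on a dark background) for testing the tracking pipeline against known
#' ground truth. Incompressible uniaxial kinematics scale the specimen
#' length by `stretch` and the width by `stretch^(-1/2)`. Gaussian pixel
#' noise is added and intensities clipped to `[0, 1]`; the true rendered
#' width in pixels and mm is stored in the `truth` attribute.
#'
#' @param geometry A one-row geometry tibble ([specimen_geometry()]); the
#'   gauge length and (pre-conditioning) width set the reference silhouette.
#' @param stretch Axial stretch.
#' @param scale_mm_px Pixel size, mm.
#' @param noise_sd Standard deviation of the Gaussian pixel noise
#'   (intensity units).
#' @param seed Integer seed for the noise.
#' @param t_s Timestamp, s.
#' @return A `tissue_frame` with attribute `truth` (list with `width_px`,
#'   `width_mm`, `length_px`).
#' @examples
#' fr <- render_frame(specimen_geometry("circ"), stretch = 1.2)
#' attr(fr, "truth")$width_mm
#' @export
render_frame <- function(geometry, stretch = 1, scale_mm_px = 0.1,
                         noise_sd = 0.02, seed = 1, t_s = 0) {
  g <- as.list(geometry)
  if (stretch <= 0) abort("`stretch` must be positive")
  len_px <- round(g$gauge_length_mm * stretch / scale_mm_px)
  wid_px <- round(g$width_mm / sqrt(stretch) / scale_mm_px)
  if (len_px < 2 || wid_px < 2) abort("specimen smaller than 2 px; reduce scale")
  n_row <- round(g$gauge_length_mm * 1.6 / scale_mm_px)
  n_col <- round(g$width_mm * 2.5 / scale_mm_px)
  n_row <- max(n_row, len_px + 10)
  n_col <- max(n_col, wid_px + 10)
  px <- matrix(0.15, n_row, n_col)
  r0 <- floor((n_row - len_px) / 2) + 1
  c0 <- floor((n_col - wid_px) / 2) + 1
  px[r0:(r0 + len_px - 1), c0:(c0 + wid_px - 1)] <- 0.85
  if (noise_sd > 0) {
    px <- withr::with_seed(
      as.integer(seed),
      px + matrix(stats::rnorm(length(px), 0, noise_sd), n_row, n_col)
    )
  }
  px <- pmin(pmax(px, 0), 1)
  fr <- tissue_frame(px, scale_mm_px, t_s)
  attr(fr, "truth") <- list(
    width_px = wid_px, width_mm = wid_px * scale_mm_px, length_px = len_px
  )
  fr
}

#' Binarize a specimen frame
#'
#' Thresholds a grayscale frame with Otsu's bimodal-histogram method and
#' removes background specks below a minimum area (connected-component
#' filtering).
#'
#' @param frame A `tissue_frame`.
#' @param polarity `"bright"` if the specimen is brighter than the
#'   background (the default; a backlit dark specimen should use
#'   `"dark"`, which inverts the frame first).
#' @param min_area Minimum connected-component area in pixels; smaller
#'   foreground specks are dropped.
#' @return A logical matrix, `TRUE` on the specimen.
#' @export
binarize <- function(frame, polarity = c("bright", "dark"), min_area = 20) {
  stopifnot(inherits(frame, "tissue_frame"))
  polarity <- match.arg(polarity)
  px <- frame$pixels
  if (polarity == "dark") px <- 1 - px
  if (stats::sd(px) < 1e-8) {
    abort("segmentation failed: frame has no contrast")
  }
  thr <- EBImage::otsu(EBImage::Image(px), range = c(0, 1))
  mask <- px > thr
  if (!any(mask) || all(mask)) {
    abort("segmentation failed: threshold separated nothing")
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) {
    abort("segmentation failed: no component above the minimum area")
  }
  matrix(lab %in% keep, nrow(px), ncol(px))
}

#' Split a silhouette boundary into the four specimen edges
#'
#' Takes the largest foreground component, finds its boundary pixels (those
#' with a 4-neighbour outside the component or on the image border), and
#' classifies each into left, right, top or bottom by the dominant
#' direction of its offset from the component centroid, normalised by the
#' component half-extents so elongated specimens classify correctly. The
#' four groups partition the boundary exactly.
#'
#' @param mask Logical matrix from [binarize()].
#' @return An object of class `edge_groups`: a list of tibbles `left`,
#'   `right`, `top`, `bottom`, each with pixel coordinates `row`, `col`.
#' @export
extract_edges <- function(mask) {
  if (!is.matrix(mask) || !any(mask)) {
    abort("`mask` has no foreground")
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  if (sum(comp) < 4) abort("foreground component is degenerate (< 4 px)")
  nr <- nrow(comp)
  nc <- ncol(comp)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- comp
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  boundary <- comp & !interior
  idx <- which(boundary, arr.ind = TRUE)
  cx <- mean(range(idx[, "col"]))
  cy <- mean(range(idx[, "row"]))
  hx <- max(diff(range(idx[, "col"])) / 2, 0.5)
  hy <- max(diff(range(idx[, "row"])) / 2, 0.5)
  nx <- (idx[, "col"] - cx) / hx
  ny <- (idx[, "row"] - cy) / hy
  side <- ifelse(
    abs(nx) >= abs(ny),
    ifelse(nx < 0, "left", "right"),
    ifelse(ny < 0, "top", "bottom")
  )
  groups <- lapply(c("left", "right", "top", "bottom"), function(s) {
    sel <- side == s
    tibble(row = unname(idx[sel, "row"]), col = unname(idx[sel, "col"]))
  })
  names(groups) <- c("left", "right", "top", "bottom")
  structure(groups, class = "edge_groups")
}

#' Track minimum specimen width and extension across frames
#'
#' For each frame: binarize, extract the four edges, measure the horizontal
#' span between the left and right edges on every row covered by both, and
#' report the minimum width (in mm). Extension is the change in the
#' top-to-bottom edge distance relative to the first frame. The minimum
#' width at the onset of the post-conditioning pull is the reference width
#' for stress normalisation.
#'
#' @param frames A list of `tissue_frame` objects.
#' @param polarity,min_area Passed to [binarize()].
#' @return A tibble with columns `t_s`, `min_width_mm`, `extension_mm`.
#' @examples
#' frames <- lapply(c(1, 1.1), function(s) {
#'   render_frame(specimen_geometry("circ"), stretch = s, t_s = s)
#' })
#' track_width(frames)
#' @export
track_width <- function(frames, polarity = "bright", min_area = 20) {
  if (inherits(frames, "tissue_frame")) frames <- list(frames)
  if (length(frames) == 0) abort("no frames supplied")
  rows <- purrr::imap(frames, function(fr, i) {
    res <- tryCatch(
      {
        mask <- binarize(fr, polarity = polarity, min_area = min_area)
        edges <- extract_edges(mask)
        frame_measurements(edges, fr$scale_mm_px)
      },
      error = function(e) {
        abort(paste0("frame ", i, ": ", conditionMessage(e)))
      }
    )
    tibble(
      t_s = fr$t_s, min_width_mm = res$min_width_mm, length_mm = res$length_mm
    )
  })
  out <- dplyr::bind_rows(rows)
  out$extension_mm <- out$length_mm - out$length_mm[1]
  out[c("t_s", "min_width_mm", "extension_mm")]
}

frame_measurements <- function(edges, scale) {
  lr <- dplyr::inner_join(
    dplyr::summarise(dplyr::group_by(edges$left, .data$row),
      lc = min(.data$col), .groups = "drop"
    ),
    dplyr::summarise(dplyr::group_by(edges$right, .data$row),
      rc = max(.data$col), .groups = "drop"
    ),
    by = "row"
  )
  if (nrow(lr) == 0) abort("left and right edges share no rows")
  widths <- lr$rc - lr$lc + 1
  len_px <- max(edges$bottom$row) - min(edges$top$row) + 1
  list(min_width_mm = min(widths) * scale, length_mm = len_px * scale)
}
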