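# Hairy-root GFP intensity measurement. Order of operations follows the
# assay protocol: extract the green channel, subtract the mean gray of a
# background box placed in the medium adjacent to the root (reflection halo
# and autofluorescence), threshold-segment the expressing pixels, take the
# masked mean, then subtract the negative-control baseline. Subtractions
# clamp at zero (8-bit grayscale arithmetic).

as_box <- function(box) {
  if (is.numeric(box) && length(box) == 4)
    box <- list(row = box[1], col = box[2], height = box[3], width = box[4])
  stopifnot(is.list(box),
            all(c("row", "col", "height", "width") %in% names(box)))
  lapply(box, as.integer)
}

box_cells <- function(box, nr, nc) {
  box <- as_box(box)
  if (box$row < 1 || box$col < 1 || box$height < 1 || box$width < 1 ||
      box$row + box$height - 1 > nr || box$col + box$width - 1 > nc)
    stop("background box lies outside the frame", call. = FALSE)
  list(rows = box$row:(box$row + box$height - 1),
       cols = box$col:(box$col + box$width - 1))
}

#' Extract the green channel of a root image
#'
#' @param img a `root_image` or an RGB array (h x w x 3).
#' @return the green plane as a matrix, dimensions preserved.
#' @export
extract_green <- function(img) {
  px <- if (inherits(img, "root_image")) img$pixels else img
  if (is.matrix(px)) return(px)
  if (length(dim(px)) != 3) stop("expected an RGB raster", call. = FALSE)
  px[, , 2]
}

#' Subtract the mean gray of a background box from every pixel
#'
#' The mean grayscale value of the box is subtracted from the whole channel
#' and negative results are clamped to zero. The realized background value
#' is stored in attribute `"background_value"`.
#'
#' @param channel green-channel matrix.
#' @param box box as `list(row, col, height, width)` or a length-4 numeric.
#' @param root_region optional logical mask; an error is raised if the box
#'   intersects it.
#' @return the background-subtracted channel.
#' @export
subtract_background_box <- function(channel, box, root_region = NULL) {
  bc <- box_cells(box, nrow(channel), ncol(channel))
  if (!is.null(root_region) && any(root_region[bc$rows, bc$cols]))
    stop("background box overlaps the declared root region", call. = FALSE)
  bg <- mean(channel[bc$rows, bc$cols])
  out <- pmax(channel - bg, 0)
  attr(out, "background_value") <- bg
  out
}

otsu_threshold <- function(channel) {
  EBImage::otsu(channel, range = c(0, 255), levels = 256L)
}

#' Segment expressing pixels of a background-subtracted channel
#'
#' @param channel background-subtracted green channel.
#' @param method `"otsu"` (parameter-free, default) or `"fixed"`.
#' @param threshold grayscale level for `method = "fixed"`; pixels strictly
#'   above it are kept.
#' @return logical mask; the realized threshold is stored in attribute
#'   `"threshold"`.
#' @export
segment_expressing <- function(channel, method = c("otsu", "fixed"),
                               threshold = NULL) {
  method <- match.arg(method)
  thr <- if (method == "otsu") {
    if (all(channel == channel[1])) channel[1]  # flat channel: empty mask
    else otsu_threshold(channel)
  } else {
    if (is.null(threshold)) stop("fixed method needs a threshold",
                                 call. = FALSE)
    as.numeric(threshold)
  }
  mask <- channel > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Mean of a channel over a mask
#'
#' @param channel numeric matrix.
#' @param mask logical mask; an empty mask returns 0 with attribute
#'   `"empty_mask" = TRUE` (and a warning unless `warn = FALSE`).
#' @param warn warn on empty masks.
#' @return grayscale mean in a.u.
#' @export
masked_mean <- function(channel, mask, warn = TRUE) {
  if (!any(mask)) {
    if (warn) warning("empty mask; returning 0")
    return(structure(0, empty_mask = TRUE))
  }
  mean(channel[mask])
}

root_gray_mean <- function(img, method = "otsu", threshold = NULL) {
  ch <- extract_green(img)
  sub <- subtract_background_box(ch, img$background_box,
                                 root_region = img$root_region)
  mask <- segment_expressing(sub, method = method, threshold = threshold)
  m <- masked_mean(sub, mask, warn = FALSE)
  list(mean = as.numeric(m), n_px = sum(mask),
       threshold = attr(mask, "threshold"),
       background = attr(sub, "background_value"),
       empty = isTRUE(attr(m, "empty_mask")))
}

#' Negative-control autofluorescence baseline
#'
#' Control roots (induced without the reporter construct) are processed with
#' the same box-subtraction and segmentation pipeline; the baseline is the
#' mean of their per-root grayscale means.
#'
#' @param control_imgs list of `root_image` objects (>= 1).
#' @param method,threshold passed to [segment_expressing()].
#' @return object of class `control_baseline`: `mean_gray`,
#'   `n_control_roots`, `per_root`.
#' @export
control_baseline <- function(control_imgs, method = "otsu",
                             threshold = NULL) {
  if (length(control_imgs) < 1)
    stop("need at least one control image", call. = FALSE)
  per <- vapply(control_imgs, function(img)
    root_gray_mean(img, method, threshold)$mean, numeric(1))
  structure(list(mean_gray = mean(per),
                 n_control_roots = length(control_imgs), per_root = per),
            class = "control_baseline")
}

#' Quantify one hairy-root event
#'
#' `corrected_mean = max(0, masked_mean(box-subtracted channel) -
#' baseline$mean_gray)`.
#'
#' @param img a `root_image` carrying its `background_box`.
#' @param baseline a [control_baseline()] (or a number).
#' @param method,threshold passed to [segment_expressing()].
#' @return a one-row data.frame (class `root_intensity_record`):
#'   `event_id, promoter_id, corrected_mean, n_segmented_px, threshold`.
#' @export
quantify_root <- function(img, baseline, method = "otsu", threshold = NULL) {
  base <- if (inherits(baseline, "control_baseline")) baseline$mean_gray
          else as.numeric(baseline)
  r <- root_gray_mean(img, method, threshold)
  out <- data.frame(event_id = img$event_id, promoter_id = img$promoter_id,
                    corrected_mean = max(0, r$mean - base),
                    n_segmented_px = r$n_px, threshold = r$threshold)
  class(out) <- c("root_intensity_record", class(out))
  out
}

#' Quantify a cohort of root images
#'
#' @param images list of `root_image` objects.
#' @inheritParams quantify_root
#' @return data.frame with one [quantify_root()] record per image.
#' @export
quantify_cohort <- function(images, baseline, method = "otsu",
                            threshold = NULL) {
  recs <- lapply(images, quantify_root, baseline = baseline,
                 method = method, threshold = threshold)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Pick a background box of minimal variance outside the root
#'
#' Slides a `size x size` window over the image (half-window stride),
#' discards windows touching the coarse Otsu segmentation of the raw green
#' channel (dilated by the window size), and returns the window of minimal
#' variance — a flat patch of medium adjacent to the root.
#'
#' @param img a `root_image` or RGB array.
#' @param size box side in pixels (the assay's convention is 100).
#' @return `list(row, col, height, width)`.
#' @export
auto_box <- function(img, size = 100) {
  ch <- extract_green(img)
  nr <- nrow(ch); nc <- ncol(ch)
  if (size > min(nr, nc) - 2)
    stop("box size exceeds the frame", call. = FALSE)
  rough <- ch > otsu_threshold(ch)
  occupied <- EBImage::dilate(rough * 1,
                              EBImage::makeBrush(2 * (size %/% 2) + 1,
                                                 "box")) > 0
  stride <- max(1, size %/% 2)
  best <- NULL; best_var <- Inf
  for (r0 in unique(c(seq(1, nr - size + 1, by = stride), nr - size + 1))) {
    for (c0 in unique(c(seq(1, nc - size + 1, by = stride), nc - size + 1))) {
      rows <- r0:(r0 + size - 1); cols <- c0:(c0 + size - 1)
      if (occupied[r0 + size %/% 2, c0 + size %/% 2]) next
      v <- stats::var(as.numeric(ch[rows, cols]))
      if (v < best_var) {
        best_var <- v
        best <- list(row = r0, col = c0, height = size, width = size)
      }
    }
  }
  if (is.null(best))
    stop("no window clear of the segmented region", call. = FALSE)
  best
}
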