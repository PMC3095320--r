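# Disk formats: zero-padded PNG frame series for time-lapse stacks, PNG for
# root images, JSON sidecars for ground truth, CSV tables with header rows.

array_to_png <- function(frame, path) {
  png::writePNG(frame / 255, target = path)
}

png_to_array <- function(path) {
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3]
  a * 255
}

#' Write a time-lapse stack as a numbered PNG frame series
#'
#' Frames land as `frame_0000.png`, `frame_0001.png`, ... plus a
#' `times_h.csv` table; an optional ground truth is stored as a JSON
#' sidecar.
#'
#' @param stack a `timelapse_stack`.
#' @param dir output directory (created if needed).
#' @param truth optional `ground_truth` to store alongside.
#' @export
write_timelapse <- function(stack, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$frames))
    array_to_png(stack$frames[[i]],
                 file.path(dir, sprintf("frame_%04d.png", i - 1)))
  utils::write.csv(data.frame(frame = seq_along(stack$frames) - 1,
                              time_h = stack$times_h),
                   file.path(dir, "times_h.csv"), row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a time-lapse stack from a PNG frame series
#'
#' @param dir directory written by [write_timelapse()] (or any directory of
#'   frames matching `pattern` in capture order).
#' @param pattern filename glob for frames.
#' @param subject_id label for the stack.
#' @return a `timelapse_stack`.
#' @export
read_timelapse <- function(dir, pattern = "frame_*.png",
                           subject_id = basename(dir)) {
  files <- sort(Sys.glob(file.path(dir, pattern)))
  if (length(files) < 2) stop("need at least two frames", call. = FALSE)
  frames <- lapply(files, png_to_array)
  tfile <- file.path(dir, "times_h.csv")
  times <- if (file.exists(tfile)) utils::read.csv(tfile)$time_h
           else seq_along(files) - 1
  structure(list(frames = frames, times_h = times, subject_id = subject_id),
            class = "timelapse_stack")
}

#' Write a root image (PNG) with its mask, box and ground truth sidecars
#' @param img a `root_image`.
#' @param path output PNG path; sidecars take derived names.
#' @param truth optional `ground_truth`.
#' @export
write_root_image <- function(img, path, truth = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  array_to_png(img$pixels, path)
  meta <- list(event_id = img$event_id, promoter_id = img$promoter_id,
               background_box = img$background_box)
  if (!is.null(truth)) meta$truth <- unclass(truth)
  jsonlite::write_json(meta, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
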