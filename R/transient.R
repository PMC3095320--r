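# Transient-expression quantification: hourly time-lapse frames are reduced
# to a scalar fluorescence value (thresholded green-channel sum), assembled
# into an expression profile, smoothed, and expressed as percent of the peak
# of the CaMV35S reference profile.

#' Construct an expression profile
#'
#' @param times_h strictly increasing capture times in hours.
#' @param values non-negative fluorescence values (raw a.u., or percent of
#'   the reference peak when `normalized`).
#' @param normalized logical flag.
#' @param reference_id label of the reference promoter when normalized.
#' @param subject_id label of the profiled subject.
#' @param n_replicates number of replicates averaged into this profile.
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(times_h, values, normalized = FALSE,
                               reference_id = NA_character_,
                               subject_id = NA_character_,
                               n_replicates = 1L) {
  if (length(times_h) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times_h) && any(diff(times_h) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("profile values must be >= 0", call. = FALSE)
  if (normalized && (is.na(reference_id) || !nzchar(reference_id)))
    stop("a normalized profile must record its reference", call. = FALSE)
  structure(list(times_h = as.numeric(times_h), values = as.numeric(values),
                 normalized = isTRUE(normalized), reference_id = reference_id,
                 subject_id = subject_id,
                 n_replicates = as.integer(n_replicates)),
            class = "expression_profile")
}

frame_green <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3) return(frame[, , 2])
  stop("frame must be an RGB array or a green-channel matrix", call. = FALSE)
}

#' Quantify one frame by thresholded green-channel sum
#'
#' Returns the sum of green-channel values over pixels strictly above the
#' threshold (0 if none qualify). The sum responds to both the number and
#' the brightness of expressing cells, matching whole-image monitoring of a
#' bombarded explant.
#'
#' @param frame RGB array (h x w x 3) or green-channel matrix, values on
#'   `[0, 255]`.
#' @param threshold grayscale level in `[0, 255]`.
#' @return fluorescence in a.u.
#' @export
quantify_frame <- function(frame, threshold) {
  g <- frame_green(frame)
  if (length(g) == 0) stop("empty frame", call. = FALSE)
  if (threshold < 0 || threshold > 255)
    stop("threshold outside the valid pixel range", call. = FALSE)
  sum(g[g > threshold])
}

#' Default detection threshold from the pre-expression frame
#'
#' Mean + 3 SD of the first frame's green channel, i.e. the upper envelope
#' of the background before expression is detectable.
#'
#' @param stack a `timelapse_stack`.
#' @return a grayscale threshold.
#' @export
auto_threshold <- function(stack) {
  g <- frame_green(stack$frames[[1]])
  min(255, mean(g) + 3 * stats::sd(as.numeric(g)))
}

#' Build a raw expression profile from a time-lapse stack
#'
#' @param stack a `timelapse_stack`.
#' @param threshold `"auto"` (mean + 3 SD of the first frame) or a numeric
#'   grayscale level.
#' @return a raw `expression_profile`; the realized threshold is stored in
#'   attribute `"threshold"`.
#' @export
build_profile <- function(stack, threshold = "auto") {
  stopifnot(inherits(stack, "timelapse_stack"))
  thr <- if (identical(threshold, "auto")) auto_threshold(stack)
         else as.numeric(threshold)
  vals <- vapply(stack$frames, quantify_frame, numeric(1), threshold = thr)
  p <- expression_profile(stack$times_h, vals, normalized = FALSE,
                          subject_id = stack$subject_id)
  attr(p, "threshold") <- thr
  p
}

#' Centred moving-average smoothing with edge truncation
#'
#' @param p an `expression_profile`.
#' @param window odd window length; `window = 1` returns the input.
#' @return a smoothed `expression_profile`.
#' @export
smooth_profile <- function(p, window = 5) {
  stopifnot(inherits(p, "expression_profile"))
  if (window < 1 || window %% 2 == 0)
    stop("window must be a positive odd integer", call. = FALSE)
  if (window == 1) return(p)
  half <- (window - 1) / 2
  n <- length(p$values)
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(p$values[lo:hi])
  }, numeric(1))
  out <- p
  out$values <- sm
  out
}

#' Peak of an expression profile
#'
#' Ties are broken toward the earliest time attaining the maximum.
#'
#' @param p an `expression_profile`.
#' @return a `profile_summary` list: `peak_value`, `peak_time_h`,
#'   `n_replicates`.
#' @export
peak_of <- function(p) {
  stopifnot(inherits(p, "expression_profile"))
  if (length(p$values) == 0) stop("empty profile", call. = FALSE)
  i <- which.max(p$values)
  structure(list(peak_value = p$values[i], peak_time_h = p$times_h[i],
                 n_replicates = p$n_replicates),
            class = "profile_summary")
}

#' Express a profile as percent of the reference promoter's peak
#'
#' Every value becomes `100 * value / peak(ref)`. The reference profile must
#' be raw (un-normalized); pass the smoothed mean reference profile (see
#' [reference_profile()]) so reference noise is not inflated into every
#' normalized value.
#'
#' @param p a raw `expression_profile`.
#' @param ref the raw reference `expression_profile`.
#' @return a normalized `expression_profile` recording `ref`'s subject as
#'   its reference.
#' @export
normalize_percent_of_reference <- function(p, ref) {
  stopifnot(inherits(p, "expression_profile"),
            inherits(ref, "expression_profile"))
  if (ref$normalized)
    stop("reference profile must be raw", call. = FALSE)
  if (p$normalized)
    stop("profile is already normalized", call. = FALSE)
  rp <- peak_of(ref)$peak_value
  if (rp <= 0)
    stop("reference peak is zero (failed reference bombardment)",
         call. = FALSE)
  refid <- if (is.na(ref$subject_id)) "reference" else ref$subject_id
  expression_profile(p$times_h, 100 * p$values / rp, normalized = TRUE,
                     reference_id = refid, subject_id = p$subject_id,
                     n_replicates = p$n_replicates)
}

#' Pointwise mean of replicate profiles
#'
#' All replicates must share the same time grid and normalization state.
#'
#' @param replicates list of `expression_profile` objects (>= 1).
#' @param subject_id label for the mean profile.
#' @return list with `profile` (the mean `expression_profile`) and
#'   `summary` (its [peak_of()] with `n_replicates` recorded).
#' @export
mean_profile <- function(replicates, subject_id = NULL) {
  if (length(replicates) < 1) stop("need at least one profile", call. = FALSE)
  stopifnot(all(vapply(replicates, inherits, TRUE, "expression_profile")))
  t0 <- replicates[[1]]$times_h
  for (p in replicates) {
    if (length(p$times_h) != length(t0) || any(p$times_h != t0))
      stop("replicate profiles are on mismatched time grids", call. = FALSE)
    if (p$normalized != replicates[[1]]$normalized)
      stop("replicates mix raw and normalized profiles", call. = FALSE)
  }
  vals <- rowMeans(vapply(replicates, `[[`, numeric(length(t0)), "values"))
  sid <- if (is.null(subject_id)) replicates[[1]]$subject_id else subject_id
  mp <- expression_profile(t0, vals,
                           normalized = replicates[[1]]$normalized,
                           reference_id = replicates[[1]]$reference_id,
                           subject_id = sid,
                           n_replicates = length(replicates))
  list(profile = mp, summary = peak_of(mp))
}

#' Smoothed mean reference profile for normalization
#'
#' @param replicates list of raw reference profiles on one grid.
#' @param window smoothing window (odd).
#' @param subject_id label, default `"CaMV35S"`.
#' @return the smoothed mean raw `expression_profile`.
#' @export
reference_profile <- function(replicates, window = 5,
                              subject_id = "CaMV35S") {
  smooth_profile(mean_profile(replicates, subject_id = subject_id)$profile,
                 window = window)
}

#' Write an expression profile to CSV
#'
#' Columns: `time_h, value, normalized, reference_id`.
#' @param p an `expression_profile`.
#' @param path output CSV path.
#' @export
write_profile <- function(p, path) {
  df <- data.frame(time_h = p$times_h, value = p$values,
                   normalized = p$normalized,
                   reference_id = ifelse(is.na(p$reference_id), "",
                                         p$reference_id))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an expression profile from CSV
#' @param path CSV written by [write_profile()].
#' @param subject_id optional label.
#' @return an `expression_profile`.
#' @export
read_profile <- function(path, subject_id = NA_character_) {
  df <- utils::read.csv(path)
  refid <- if (any(nzchar(df$reference_id))) df$reference_id[1] else NA_character_
  expression_profile(df$time_h, df$value, normalized = df$normalized[1],
                     reference_id = refid, subject_id = subject_id)
}
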