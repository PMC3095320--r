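# Synthetic fluorescence scenes: transient-expression time-lapse stacks and
# hairy-root still images, both with known ground truth. Pixel model is 8-bit
# per channel: values live on [0, 255] and additive noise is clipped to that
# range. Scene geometry (focus layout, root mask) is a deterministic function
# of the configuration; `seed` drives only the noise fields, so two configs
# that differ only in seed share identical noise-free components.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Transient-expression scene configuration
#'
#' Describes a bombarded cotyledon monitored by hourly fluorescence imaging.
#' Each transformed cell ("focus") follows the kinetic law
#' \deqn{I(t) = A (1 - e^{-t/\tau_r}) e^{-t/\tau_d}}
#' a saturating rise times an exponential decay, whose peak time has the
#' closed form \eqn{t^* = \tau_r \log(1 + \tau_d/\tau_r)}. In `retained`
#' mode (lima-bean-like) each focus is a uniformly bright disk of fixed
#' radius; in `diffusing` mode (soybean-like) each focus is a normalized
#' Gaussian plume whose width grows linearly at `spread_rate` while its
#' frame-integrated signal still follows \eqn{I(t)}.
#'
#' @param width_px,height_px frame dimensions in pixels.
#' @param n_foci number of transformed cells.
#' @param amplitude kinetic amplitude per focus, in summed fluorescence a.u.
#' @param rise_hours,decay_hours kinetic time constants in hours; the
#'   defaults place the reference peak near 21 h with ~20% of peak signal
#'   left at 100 h.
#' @param diffusion_mode `"retained"` or `"diffusing"`.
#' @param spread_rate Gaussian width growth in px/h (diffusing mode only).
#' @param noise_sd per-pixel Gaussian read-noise SD in a.u.
#' @param baseline constant background level in a.u.
#' @param seed integer seed for the noise field.
#' @param focus_radius_px disk radius of a retained focus.
#' @param sigma0_px initial Gaussian width of a diffusing focus.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(width_px = 96, height_px = 96, n_foci = 15,
                         amplitude = 2000, rise_hours = 18, decay_hours = 40,
                         diffusion_mode = c("retained", "diffusing"),
                         spread_rate = 0.5, noise_sd = 1, baseline = 0,
                         seed = 1, focus_radius_px = 4, sigma0_px = 2) {
  diffusion_mode <- match.arg(diffusion_mode)
  if (width_px < 1 || height_px < 1)
    stop("scene dimensions must be positive", call. = FALSE)
  if (n_foci < 0) stop("n_foci must be non-negative", call. = FALSE)
  if (rise_hours <= 0 || decay_hours <= 0)
    stop("kinetic time constants must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spread_rate < 0) stop("spread_rate must be >= 0", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_foci = as.integer(n_foci), amplitude = amplitude,
                 rise_hours = rise_hours, decay_hours = decay_hours,
                 diffusion_mode = diffusion_mode, spread_rate = spread_rate,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed),
                 focus_radius_px = focus_radius_px, sigma0_px = sigma0_px),
            class = "scene_config")
}

# Deterministic golden-angle layout: foci never depend on the seed.
focus_centers <- function(width, height, n, margin) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  rmax <- max(1, min(width, height) / 2 - margin)
  i <- seq_len(n)
  r <- rmax * sqrt((i - 1) / n)
  th <- i * 2.399963229728653
  cbind(x = width / 2 + r * cos(th), y = height / 2 + r * sin(th))
}

#' Kinetic intensity law of a transient-expression focus
#'
#' @param t time in hours (vectorized).
#' @param amplitude,rise_hours,decay_hours kinetic parameters.
#' @return total focal fluorescence at `t`, in a.u.
#' @export
kinetic_intensity <- function(t, amplitude, rise_hours, decay_hours) {
  amplitude * (1 - exp(-t / rise_hours)) * exp(-t / decay_hours)
}

#' Closed-form peak time of the focus kinetics
#' @inheritParams kinetic_intensity
#' @return the argmax of [kinetic_intensity()], in hours.
#' @export
kinetic_peak_hour <- function(rise_hours, decay_hours) {
  rise_hours * log(1 + decay_hours / rise_hours)
}

disk_indices <- function(cx, cy, radius, width, height) {
  x0 <- max(1L, floor(cx - radius)); x1 <- min(width, ceiling(cx + radius))
  y0 <- max(1L, floor(cy - radius)); y1 <- min(height, ceiling(cy + radius))
  xs <- x0:x1; ys <- y0:y1
  grid <- expand.grid(y = ys, x = xs)
  keep <- (grid$x - cx)^2 + (grid$y - cy)^2 <= radius^2
  (grid$x[keep] - 1L) * height + grid$y[keep]
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Generate a synthetic transient-expression time-lapse stack
#'
#' One RGB frame per hour. The green channel carries the baseline plus the
#' focal kinetics; red and blue carry baseline plus noise only. In diffusing
#' mode the Gaussian footprint is analytically normalized so the
#' frame-integrated focal signal tracks \eqn{I(t)} (photon conservation up
#' to border/discretization loss).
#'
#' @param config a [scene_config()].
#' @param duration_h number of hourly frames (capture times `0:(duration_h-1)`).
#' @param subject_id label stored on the stack.
#' @return a list with elements `stack` (class `timelapse_stack`: `frames`,
#'   `times_h`, `subject_id`) and `truth` (class `ground_truth`, carrying the
#'   kinetic parameters, the closed-form peak hour and the focus centers).
#' @export
make_timelapse <- function(config, duration_h = 100, subject_id = "scene") {
  stopifnot(inherits(config, "scene_config"))
  if (duration_h < 2) stop("duration_h must be >= 2", call. = FALSE)
  w <- config$width_px; h <- config$height_px
  times <- seq_len(duration_h) - 1L
  margin <- if (config$diffusion_mode == "retained")
    config$focus_radius_px + 2 else config$sigma0_px + 2
  centers <- focus_centers(w, h, config$n_foci, margin)
  disks <- NULL
  if (config$diffusion_mode == "retained" && config$n_foci > 0)
    disks <- lapply(seq_len(nrow(centers)), function(i)
      disk_indices(centers[i, 1], centers[i, 2], config$focus_radius_px, w, h))
  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), times = w), h, w)

  set.seed(config$seed)
  frames <- vector("list", duration_h)
  for (fi in seq_along(times)) {
    t <- times[fi]
    it <- kinetic_intensity(t, config$amplitude, config$rise_hours,
                            config$decay_hours)
    g <- matrix(config$baseline, h, w)
    if (config$n_foci > 0 && it > 0) {
      if (config$diffusion_mode == "retained") {
        for (d in disks) g[d] <- g[d] + it / length(d)
      } else {
        sg <- config$sigma0_px + config$spread_rate * t
        norm <- it / (2 * pi * sg^2)
        for (i in seq_len(nrow(centers))) {
          g <- g + norm * exp(-((xg - centers[i, 1])^2 +
                                (yg - centers[i, 2])^2) / (2 * sg^2))
        }
      }
    }
    frame <- array(0, dim = c(h, w, 3))
    if (config$noise_sd > 0) {
      frame[, , 2] <- clip255(g + rnorm(h * w, 0, config$noise_sd))
      frame[, , 1] <- clip255(config$baseline + rnorm(h * w, 0, config$noise_sd))
      frame[, , 3] <- clip255(config$baseline + rnorm(h * w, 0, config$noise_sd))
    } else {
      frame[, , 2] <- clip255(g)
      frame[, , 1] <- clip255(matrix(config$baseline, h, w))
      frame[, , 3] <- clip255(matrix(config$baseline, h, w))
    }
    frames[[fi]] <- frame
  }
  stack <- structure(list(frames = frames, times_h = times,
                          subject_id = subject_id),
                     class = "timelapse_stack")
  truth <- structure(list(
    amplitude = config$amplitude, n_foci = config$n_foci,
    rise_hours = config$rise_hours, decay_hours = config$decay_hours,
    true_peak_hour = kinetic_peak_hour(config$rise_hours, config$decay_hours),
    diffusion_mode = config$diffusion_mode, centers = centers,
    baseline = config$baseline), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Hairy-root scene configuration
#'
#' A single RGB image of a fluorescing root tip on culture medium. The green
#' channel carries an autofluorescence baseline everywhere, `true_signal`
#' inside the root mask, and a reflection halo (`halo_gain * true_signal`)
#' in a ring of medium adjacent to the root; red and blue carry baseline and
#' noise only. The default mask is a vertical capsule (ellipse) emulating a
#' ~5 mm root tip centred in the frame.
#'
#' @param width_px,height_px image dimensions (the study's nominal capture
#'   size is 1600 x 1200).
#' @param true_signal root fluorescence above baseline, grayscale a.u.
#' @param halo_gain fraction of `true_signal` bled into the adjacent medium;
#'   must satisfy `0 <= halo_gain < 1`.
#' @param halo_width_px width of the halo ring in pixels.
#' @param autofluor_baseline medium/root autofluorescence level, a.u.
#' @param noise_sd per-pixel Gaussian noise SD, a.u.
#' @param box_px side of the square background box the analysis will use.
#' @param root_mask `NULL` for the default capsule, a list
#'   `(cx, cy, rx, ry)` describing an ellipse, or a logical matrix.
#' @param seed integer noise seed.
#' @return an object of class `root_scene_config`.
#' @export
root_scene_config <- function(width_px = 1600, height_px = 1200,
                              true_signal = 80, halo_gain = 0.2,
                              halo_width_px = max(4, round(width_px / 40)),
                              autofluor_baseline = 15, noise_sd = 5,
                              box_px = 100, root_mask = NULL, seed = 1) {
  if (width_px < 8 || height_px < 8)
    stop("scene dimensions too small", call. = FALSE)
  if (halo_gain < 0 || halo_gain >= 1)
    stop("halo_gain must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 true_signal = true_signal, halo_gain = halo_gain,
                 halo_width_px = halo_width_px,
                 autofluor_baseline = autofluor_baseline,
                 noise_sd = noise_sd, box_px = as.integer(box_px),
                 root_mask = root_mask, seed = as.integer(seed)),
            class = "root_scene_config")
}

ellipse_mask <- function(width, height, cx, cy, rx, ry) {
  xg <- matrix(rep(seq_len(width), each = height), height, width)
  yg <- matrix(rep(seq_len(height), times = width), height, width)
  ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
}

root_mask_matrices <- function(config) {
  w <- config$width_px; h <- config$height_px
  hw <- config$halo_width_px
  rm <- config$root_mask
  if (is.null(rm))
    rm <- list(cx = w * 0.62, cy = h * 0.5, rx = w * 0.06, ry = h * 0.3)
  if (is.matrix(rm)) {
    mask <- rm
    if (!all(dim(mask) == c(h, w)))
      stop("root_mask matrix dimensions do not match the frame", call. = FALSE)
    if (any(mask[1, ]) || any(mask[h, ]) || any(mask[, 1]) || any(mask[, w]))
      stop("root_mask touches the frame border", call. = FALSE)
    ring <- EBImage::dilate(mask * 1, EBImage::makeBrush(2 * hw + 1, "disc")) > 0
    ring <- ring & !mask
  } else {
    if (rm$cx - rm$rx <= 1 || rm$cx + rm$rx >= w ||
        rm$cy - rm$ry <= 1 || rm$cy + rm$ry >= h)
      stop("root_mask touches the frame border", call. = FALSE)
    mask <- ellipse_mask(w, h, rm$cx, rm$cy, rm$rx, rm$ry)
    ring <- ellipse_mask(w, h, rm$cx, rm$cy, rm$rx + hw, rm$ry + hw) & !mask
  }
  if (!any(mask)) stop("root_mask is empty", call. = FALSE)
  list(mask = mask, ring = ring)
}

place_background_box <- function(mask, ring, box) {
  h <- nrow(mask); w <- ncol(mask)
  if (box > min(w, h) - 4)
    stop("background box does not fit in the frame", call. = FALSE)
  occupied <- mask | ring
  corners <- list(c(3L, 3L), c(3L, w - box - 2L),
                  c(h - box - 2L, 3L), c(h - box - 2L, w - box - 2L))
  for (cc in corners) {
    rows <- cc[1]:(cc[1] + box - 1); cols <- cc[2]:(cc[2] + box - 1)
    if (!any(occupied[rows, cols]))
      return(list(row = cc[1], col = cc[2], height = box, width = box))
  }
  stop("no room for a background box adjacent to the root", call. = FALSE)
}

#' Generate a synthetic hairy-root image
#'
#' @param config a [root_scene_config()].
#' @param event_id,promoter_id labels stored on the image.
#' @return a list with elements `image` (class `root_image`: `pixels`
#'   (h x w x 3 array), `root_region` logical mask, `background_box`,
#'   labels) and `truth` (class `ground_truth` with `true_root_signal`).
#' @export
make_root_scene <- function(config, event_id = "event1",
                            promoter_id = "promoter") {
  stopifnot(inherits(config, "root_scene_config"))
  geo <- root_mask_matrices(config)
  w <- config$width_px; h <- config$height_px
  box <- place_background_box(geo$mask, geo$ring, config$box_px)
  g <- matrix(config$autofluor_baseline, h, w)
  g[geo$mask] <- g[geo$mask] + config$true_signal
  g[geo$ring] <- g[geo$ring] + config$halo_gain * config$true_signal
  set.seed(config$seed)
  px <- array(0, dim = c(h, w, 3))
  if (config$noise_sd > 0) {
    px[, , 2] <- clip255(g + rnorm(h * w, 0, config$noise_sd))
    px[, , 1] <- clip255(config$autofluor_baseline +
                         rnorm(h * w, 0, config$noise_sd))
    px[, , 3] <- clip255(config$autofluor_baseline +
                         rnorm(h * w, 0, config$noise_sd))
  } else {
    px[, , 2] <- clip255(g)
    px[, , 1] <- clip255(matrix(config$autofluor_baseline, h, w))
    px[, , 3] <- clip255(matrix(config$autofluor_baseline, h, w))
  }
  image <- structure(list(pixels = px, root_region = geo$mask,
                          background_box = box, event_id = event_id,
                          promoter_id = promoter_id),
                     class = "root_image")
  truth <- structure(list(true_root_signal = config$true_signal,
                          autofluor_baseline = config$autofluor_baseline,
                          halo_gain = config$halo_gain),
                     class = "ground_truth")
  list(image = image, truth = truth)
}

#' Generate a cohort of synthetic hairy-root images with known fold-changes
#'
#' Emulates a hairy-root screening experiment: for each promoter, `n_events`
#' independent transformation events whose true signal is
#' `fold * ref_signal` jittered by a lognormal event effect (events vary much
#' more than clonal secondary roots do), plus negative-control roots with no
#' transgene signal.
#'
#' @param folds named numeric vector of true fold-changes versus the
#'   reference (the reference itself, fold 1, is added under
#'   `reference_label` if absent).
#' @param n_events independent transformation events per promoter.
#' @param ref_signal reference-promoter true signal in a.u.
#' @param event_cv lognormal SD (log scale) of the event effect.
#' @param n_controls number of negative-control roots.
#' @param reference_label label of the reference promoter.
#' @param width_px,height_px,box_px,noise_sd,autofluor_baseline,halo_gain
#'   passed to [root_scene_config()].
#' @param seed integer seed (drives event effects and per-image noise).
#' @return list with `images` (list of `root_image`), `controls`
#'   (list of control `root_image`) and `truth` (named true signals per event).
#' @export
make_root_cohort <- function(folds, n_events = 20, ref_signal = 60,
                             event_cv = 0.25, n_controls = 6,
                             reference_label = "CaMV35S",
                             width_px = 128, height_px = 96, box_px = 20,
                             noise_sd = 4, autofluor_baseline = 20,
                             halo_gain = 0.15, seed = 1) {
  if (is.null(names(folds)) || any(!nzchar(names(folds))))
    stop("folds must be a named vector", call. = FALSE)
  if (!reference_label %in% names(folds))
    folds <- c(stats::setNames(1, reference_label), folds)
  set.seed(seed)
  images <- list(); truth <- list()
  for (prom in names(folds)) {
    eff <- exp(rnorm(n_events, 0, event_cv))
    sig <- folds[[prom]] * ref_signal * eff
    for (ev in seq_len(n_events)) {
      sc <- root_scene_config(width_px = width_px, height_px = height_px,
                              true_signal = sig[ev], halo_gain = halo_gain,
                              autofluor_baseline = autofluor_baseline,
                              noise_sd = noise_sd, box_px = box_px,
                              seed = sample.int(2^30, 1))
      id <- sprintf("%s_ev%02d", prom, ev)
      images[[id]] <- make_root_scene(sc, event_id = id,
                                      promoter_id = prom)$image
      truth[[id]] <- sig[ev]
    }
  }
  controls <- lapply(seq_len(n_controls), function(i) {
    sc <- root_scene_config(width_px = width_px, height_px = height_px,
                            true_signal = 0, halo_gain = 0,
                            autofluor_baseline = autofluor_baseline,
                            noise_sd = noise_sd, box_px = box_px,
                            seed = sample.int(2^30, 1))
    make_root_scene(sc, event_id = sprintf("control%02d", i),
                    promoter_id = "control")$image
  })
  list(images = images, controls = controls,
       truth = unlist(truth), folds = folds, ref_signal = ref_signal)
}

#' Simulate intensity versus transgene copy number
#'
#' Copy numbers must lie in 1..7, the range supported by single-cutter
#' Southern blot band counts in hairy-root events.
#'
#' @param true_slope expression gain per extra copy, a.u.
#' @param intercept intensity at zero copies, a.u.
#' @param noise_sd Gaussian noise SD on intensity.
#' @param copies integer vector of copy counts (one per event).
#' @param seed integer seed.
#' @return data.frame with columns `copy_count` and `intensity`.
#' @export
make_copy_number_data <- function(true_slope, intercept, noise_sd, copies,
                                  seed = 1) {
  copies <- as.integer(copies)
  if (any(copies < 1L | copies > 7L))
    stop("copy counts must lie in 1..7", call. = FALSE)
  set.seed(seed)
  intensity <- intercept + true_slope * copies +
    if (noise_sd > 0) rnorm(length(copies), 0, noise_sd) else 0
  data.frame(copy_count = copies, intensity = intensity)
}
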