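# Shared fixtures: everything is generated in code at test time.

small_scene <- function(...) {
  args <- utils::modifyList(
    list(width_px = 64, height_px = 64, n_foci = 6, amplitude = 1500,
         rise_hours = 10, decay_hours = 30, noise_sd = 1, baseline = 0,
         seed = 1),
    list(...))
  do.call(scene_config, args)
}

small_root_scene <- function(...) {
  args <- utils::modifyList(
    list(width_px = 128, height_px = 96, box_px = 20, true_signal = 80,
         halo_gain = 0.2, autofluor_baseline = 15, noise_sd = 5, seed = 1),
    list(...))
  do.call(root_scene_config, args)
}

# Direct Tukey-Kramer pairwise decision matrix: the independent oracle the
# compact letter display is decoded against.
tukey_kramer_decisions <- function(tbl, alpha = 0.05) {
  tbl <- as_intensity_table(tbl)
  k <- length(tbl)
  ns <- lengths(tbl)
  means <- vapply(tbl, mean, numeric(1))
  N <- sum(ns)
  mse <- sum(vapply(tbl, function(v) sum((v - mean(v))^2), numeric(1))) /
    (N - k)
  sig <- matrix(FALSE, k, k, dimnames = list(names(tbl), names(tbl)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      q <- abs(means[i] - means[j]) /
        sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      p <- stats::ptukey(q, k, N - k, lower.tail = FALSE)
      sig[i, j] <- sig[j, i] <- p < alpha
    }
  }
  sig
}

random_unrooted_tree <- function(n, blmin = 0.05, blmax = 0.3) {
  ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, blmin, blmax)))
}
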