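# Generators: determinism, kinetic law, photon conservation, sequence
# evolution and copy-number fixtures.

test_that("sourceless noise-free scenes are all-zero and configs validate", {
  cfg <- small_scene(n_foci = 0, noise_sd = 0, baseline = 0)
  st <- make_timelapse(cfg, 5)$stack
  expect_true(all(vapply(st$frames, function(f) all(f == 0), TRUE)))
  expect_length(st$frames, 5)
  expect_identical(st$times_h, 0:4)

  expect_error(scene_config(width_px = 0), "positive")
  expect_error(scene_config(rise_hours = 0), "time constants")
  expect_error(scene_config(noise_sd = -1), "noise_sd")
  expect_error(make_timelapse(small_scene(), 1), "duration")
})

test_that("noise-free frame-summed signal peaks at the analytic argmax", {
  cfg <- small_scene(noise_sd = 0)
  res <- make_timelapse(cfg, 80)
  sums <- vapply(res$stack$frames, function(f) sum(f[, , 2]), numeric(1))
  # oracle: dense numeric maximization of I(t) on a 0.01 h grid
  tg <- seq(0, 80, by = 0.01)
  it <- kinetic_intensity(tg, cfg$amplitude, cfg$rise_hours, cfg$decay_hours)
  t_star_grid <- tg[which.max(it)]
  expect_equal(t_star_grid, res$truth$true_peak_hour, tolerance = 1e-3)
  expect_equal(res$stack$times_h[which.max(sums)], round(t_star_grid),
               tolerance = 1)
})

test_that("seed drives only the noise field", {
  a <- make_timelapse(small_scene(seed = 1), 4)$stack
  b <- make_timelapse(small_scene(seed = 2), 4)$stack
  a0 <- make_timelapse(small_scene(seed = 1, noise_sd = 0), 4)$stack
  b0 <- make_timelapse(small_scene(seed = 2, noise_sd = 0), 4)$stack
  expect_identical(a0$frames, b0$frames)        # identical noise-free part
  expect_false(identical(a$frames, b$frames))   # different noise fields
  # same config + seed is bit-identical
  expect_identical(a$frames, make_timelapse(small_scene(seed = 1), 4)$stack$frames)
})

test_that("diffusing mode conserves frame-integrated focal signal", {
  cfg <- scene_config(width_px = 160, height_px = 160, n_foci = 1,
                      amplitude = 3000, rise_hours = 5, decay_hours = 1e9,
                      diffusion_mode = "diffusing", spread_rate = 0.5,
                      noise_sd = 0, baseline = 0, seed = 1)
  res <- make_timelapse(cfg, 20)
  sums <- vapply(res$stack$frames, function(f) sum(f[, , 2]), numeric(1))
  expect_it <- kinetic_intensity(res$stack$times_h, cfg$amplitude,
                                 cfg$rise_hours, cfg$decay_hours)
  rel <- abs(sums[-1] - expect_it[-1]) / expect_it[-1]
  expect_lt(max(rel), 0.005)
})

test_that("root scenes are constructed exactly and validate geometry", {
  cfg <- small_root_scene(true_signal = 0, halo_gain = 0, noise_sd = 0)
  img <- make_root_scene(cfg)$image
  expect_true(all(img$pixels == cfg$autofluor_baseline))

  cfg2 <- small_root_scene(noise_sd = 0)
  res2 <- make_root_scene(cfg2)
  g <- extract_green(res2$image)
  expect_equal(mean(g[res2$image$root_region]),
               cfg2$autofluor_baseline + cfg2$true_signal)

  expect_error(root_scene_config(halo_gain = 1), "halo_gain")
  expect_error(
    make_root_scene(small_root_scene(
      root_mask = list(cx = 10, cy = 48, rx = 12, ry = 20))),
    "border")
})

test_that("noisy root scenes recover the true signal over replicates", {
  truth <- 70; base <- 15
  rec <- vapply(1:50, function(i) {
    img <- make_root_scene(small_root_scene(true_signal = truth,
                                            noise_sd = 6,
                                            seed = 100 + i))$image
    mean(extract_green(img)[img$root_region]) - base
  }, numeric(1))
  se <- sd(rec) / sqrt(length(rec))
  expect_lt(abs(mean(rec) - truth), 3 * se + 1e-9)
})

test_that("alignment evolution honours the tree and the equal-rates model", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  msa <- evolve_alignment(tr, 50, seed = 1)
  expect_true(all(unclass(msa) == unclass(msa)[1]))  # zero branches: identical

  # empirical oracle for expected p at distance 0.5: direct simulation of
  # the per-site jump chain, independent of evolve_alignment
  set.seed(99)
  n_or <- 60000
  k <- rpois(n_or, 0.5)
  same <- vapply(k, function(kk) {
    s <- 1L
    for (i in seq_len(kk)) s <- sample((1:20)[-s], 1L)
    s == 1L
  }, TRUE)
  p_oracle <- mean(!same)
  two <- ape::read.tree(text = "(A:0.25,B:0.25);")
  n_sim <- 20000
  msa2 <- evolve_alignment(two, n_sim, seed = 7)
  p_sim <- p_distance(unclass(msa2)[["A"]], unclass(msa2)[["B"]])
  se <- sqrt(p_oracle * (1 - p_oracle) * (1 / n_or + 1 / n_sim))
  expect_lt(abs(p_sim - p_oracle), 3 * se)

  # star symmetry: equal branches give equal pairwise p within sampling error
  star <- ape::read.tree(text = "(A:0.15,B:0.15,C:0.15,D:0.15);")
  msas <- evolve_alignment(star, 4000, seed = 11)
  D <- poisson_dist_matrix(msas)
  off <- D[upper.tri(D)]
  expect_lt(max(off) - min(off), 0.06)

  expect_error(evolve_alignment(two, 0), "n_sites")
})

test_that("site independence: concatenated runs match a doubled run", {
  two <- ape::read.tree(text = "(A:0.3,B:0.3);")
  n <- 4000
  m1 <- evolve_alignment(two, n, seed = 21)
  m2 <- evolve_alignment(two, n, seed = 22)
  m12 <- evolve_alignment(two, 2 * n, seed = 23)
  p_cat <- mean(c(p_distance(unclass(m1)[["A"]], unclass(m1)[["B"]]),
                  p_distance(unclass(m2)[["A"]], unclass(m2)[["B"]])))
  p_dbl <- p_distance(unclass(m12)[["A"]], unclass(m12)[["B"]])
  se <- sqrt(2 * p_dbl * (1 - p_dbl) / (2 * n))
  expect_lt(abs(p_cat - p_dbl), 4 * se)
})

test_that("copy-number fixture is collinear without noise and validated", {
  d <- make_copy_number_data(30, 10, 0, copies = c(1:7, 1:7, 1:4), seed = 1)
  expect_equal(d$intensity, 10 + 30 * d$copy_count)
  fit <- fit_regression(d)
  expect_equal(fit$slope, 30)
  expect_equal(fit$r_squared, 1)
  expect_error(make_copy_number_data(30, 10, 0, copies = c(0, 3)), "1..7")
  expect_error(make_copy_number_data(30, 10, 0, copies = c(3, 8)), "1..7")
})
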