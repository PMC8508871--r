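# brute-force winding tracker: net passes = how many times the unwrapped
# displacement advances through the whole slab, tracked frame by frame
brute_net <- function(z, lo, hi) {
  state <- 0L  # -1 below, +1 above, 0 unknown
  net <- 0L
  for (x in z) {
    if (x < lo) {
      if (state == 1L) net <- net - 1L
      state <- -1L
    } else if (x > hi) {
      if (state == -1L) net <- net + 1L
      state <- 1L
    }
  }
  net
}

test_that("hysteresis counting registers full passages only", {
  slab <- slab_spec(-5, 5)
  up <- count_crossings(c(-8, -2, 3, 8), slab)
  expect_equal(nrow(up), 1L)
  expect_equal(up$direction_z, "up")
  expect_equal(up$direction, "cytosol_to_lumen")
  expect_equal(up$frame, 4L)

  # rattling between the planes: no events
  osc <- c(-8, -4, 4, -4, 4, -4, -8)
  expect_equal(nrow(count_crossings(osc, slab)), 0L)

  # up, retreat inside, and out again on the far side: still one event
  expect_equal(nrow(count_crossings(c(-8, 0, 8, 0, 8), slab)), 1L)

  # return passage counts in the opposite direction
  ev <- count_crossings(c(-8, 8, -8), slab)
  expect_equal(ev$direction_z, c("up", "down"))
  expect_equal(ev$direction, c("cytosol_to_lumen", "lumen_to_cytosol"))

  lum_low <- slab_spec(-5, 5, cytosol = "upper")
  expect_equal(count_crossings(c(-8, 8), lum_low)$direction, "lumen_to_cytosol")
})

test_that("counts are invariant to z translation and match time reversal", {
  sc <- crossing_script(data.frame(ion = c(1, 1, 2),
                                   direction = c("up", "down", "down"),
                                   t_start = c(50, 300, 100),
                                   t_end = c(120, 380, 200)),
                        n_ions = 2, n_frames = 500, seed = 10)
  trj <- make_crossing_trajectories(sc)
  slab <- slab_spec(-5, 5)
  ev <- count_crossings(trj, slab)
  expect_equal(sum(ev$direction_z == "up"), 1L)
  expect_equal(sum(ev$direction_z == "down"), 2L)

  shifted <- lapply(trj, `+`, 123.4)
  ev2 <- count_crossings(shifted, slab_spec(-5 + 123.4, 5 + 123.4))
  expect_equal(ev2$direction_z, ev$direction_z)

  rev_ev <- count_crossings(lapply(trj, rev), slab)
  expect_equal(sum(rev_ev$direction_z == "down"),
               sum(ev$direction_z == "up"))
  expect_equal(sum(rev_ev$direction_z == "up"),
               sum(ev$direction_z == "down"))
})

test_that("unwrapping reconstructs crossings of wrapped trajectories", {
  sc <- crossing_script(data.frame(ion = 1, direction = "up",
                                   t_start = 100, t_end = 300),
                        n_frames = 500, box_length_z = 60, wrap = TRUE,
                        seed = 4)
  z <- make_crossing_trajectories(sc)[[1]]
  expect_true(all(z >= 0 & z < 60))
  ev <- count_crossings(z, slab_spec(-5, 5, box_length_z = 60))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction_z, "up")

  # unwrap of a wrapped ramp recovers the ramp up to the periodic offset
  ramp <- seq(-40, 40, by = 0.5)
  wrapped <- ramp %% 60
  un <- unwrap_z(wrapped, 60)
  expect_equal(diff(un), diff(ramp))
})

test_that("time-reversal and winding identities hold on random fixtures", {
  set.seed(99)
  slab <- slab_spec(-5, 5)
  for (rep in seq_len(100)) {
    n_cross <- sample(0:4, 1)
    if (n_cross > 0) {
      first <- sample(c("up", "down"), 1)
      dirs <- rep(c(first, setdiff(c("up", "down"), first)),
                  length.out = n_cross)
      starts <- sort(sample(seq(10, 900, by = 10), n_cross)) +
        seq(0, by = 45, length.out = n_cross)
      cross <- data.frame(ion = 1, direction = dirs, t_start = starts,
                          t_end = starts + 40)
      sc <- crossing_script(cross, n_frames = max(starts) + 60,
                            noise_sd = 0.4, seed = rep)
    } else {
      sc <- crossing_script(n_frames = 200, noise_sd = 0.4, seed = rep)
    }
    z <- make_crossing_trajectories(sc)[[1]]
    ev <- count_crossings(z, slab)
    expect_equal(nrow(ev), n_cross)
    rev_ev <- count_crossings(rev(z), slab)
    expect_equal(sum(rev_ev$direction_z == "down"),
                 sum(ev$direction_z == "up"))
    net <- sum(ev$direction_z == "up") - sum(ev$direction_z == "down")
    expect_equal(net, brute_net(z, -5, 5))
  }
})

test_that("flux summaries report mean, SD, range and median per direction", {
  s <- summarize_flux(c(0, 4, 30, 31, 100))
  expect_equal(s$mean, 33)
  expect_equal(s$median, 30)
  expect_equal(s$min, 0)
  expect_equal(s$max, 100)
  expect_equal(s$sd, sd(c(0, 4, 30, 31, 100)))

  z <- summarize_flux(c(0, 0, 0))
  expect_equal(unlist(z[c("mean", "sd", "min", "max", "median")]),
               c(mean = 0, sd = 0, min = 0, max = 0, median = 0))

  one <- summarize_flux(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))

  per_dir <- summarize_flux(data.frame(up = c(4, 30, 100),
                                       down = c(0, 20, 40)))
  expect_equal(per_dir$mean[per_dir$condition == "total"], 194 / 3)
  expect_equal(per_dir$median[per_dir$condition == "up"], 30)
})

test_that("field/voltage/conductance conversions reproduce the worked numbers", {
  expect_equal(field_to_voltage(0, 100), 0)
  expect_equal(field_to_voltage(0.180, 128.1), 1.000, tolerance = 1e-3)
  expect_equal(field_to_voltage(-0.180, 128.1), -field_to_voltage(0.180, 128.1))
  expect_equal(field_to_voltage(0.360, 128.1), 2 * field_to_voltage(0.180, 128.1))

  ex <- expected_crossings(80, 1, 500, 1)
  expect_equal(ex$expected, 249.66, tolerance = 1e-4)
  expect_equal(ex$nearest, 250L)
  expect_equal(expected_crossings(80, 1, 500, 2)$expected, ex$expected / 2)
  # linear in each of conductance, voltage and time
  expect_equal(expected_crossings(160, 1, 500, 1)$expected, 2 * ex$expected)
  expect_equal(expected_crossings(80, 2, 500, 1)$expected, 2 * ex$expected)
  expect_equal(expected_crossings(80, 1, 1000, 1)$expected, 2 * ex$expected)
  expect_error(expected_crossings(80, 1, 500, 0), "valence")
  expect_error(expected_crossings(0, 1, 500, 1))
})
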