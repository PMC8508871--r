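# helper: wrap a bare free-energy curve as a profile object
fake_profile <- function(xi, G, shifted = FALSE) {
  structure(list(xi = xi, G = G, n_samples = rep(1L, length(xi)),
                 f = 0, iterations = 0L, residual = 0,
                 kT = thermal_energy(300), breaks = NULL,
                 shift_applied = 0, shifted = shifted, error = NULL),
            class = "pmf_profile")
}

# independent WHAM oracle: plain loops, brute-force alternation
naive_wham <- function(centers, ks, samples, breaks, kT,
                       tol = 1e-10, maxit = 2e5) {
  J <- length(centers)
  nb <- length(breaks) - 1L
  mids <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  counts <- matrix(0, nb, J)
  for (j in seq_len(J))
    for (x in samples[[j]]) {
      b <- findInterval(x, breaks, rightmost.closed = TRUE)
      if (b >= 1 && b <= nb) counts[b, j] <- counts[b, j] + 1
    }
  N <- colSums(counts)
  f <- rep(0, J)
  for (it in seq_len(maxit)) {
    P <- rep(0, nb)
    for (b in seq_len(nb)) {
      den <- 0
      for (j in seq_len(J))
        den <- den + N[j] * exp((f[j] - 0.5 * ks[j] * (mids[b] - centers[j])^2) / kT)
      if (den > 0) P[b] <- sum(counts[b, ]) / den
    }
    P <- P / sum(P)
    fn <- numeric(J)
    for (j in seq_len(J)) {
      z <- 0
      for (b in seq_len(nb))
        z <- z + P[b] * exp(-0.5 * ks[j] * (mids[b] - centers[j])^2 / kT)
      fn[j] <- -kT * log(z)
    }
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  G <- ifelse(P > 0, -kT * log(P), Inf)
  list(f = f, G = G - min(G[is.finite(G)]), mids = mids)
}

test_that("window planning reproduces the pull-protocol arithmetic", {
  p <- plan_windows(50, 0.5)
  expect_equal(p$n_total, 100)
  expect_equal(p$centers[1], 0.5)
  expect_equal(p$centers[100], 50)

  p2 <- plan_windows(50, 0.5, drop_terminal = 15)
  expect_equal(p2$n_dropped_terminal, 30)
  expect_equal(p2$n_retained, 70)
  expect_equal(sum(p2$retained), 70)
  expect_false(any(p2$retained[71:100]))

  expect_equal(plan_windows(1, 1)$n_total, 1)
  expect_error(plan_windows(1, 2), "exceeds")
})

test_that("window binning honours the equilibration discard", {
  w <- umbrella_window(0, 10, rep(0.5, 10))
  breaks <- seq(0, 3, by = 1)
  counts <- bin_window(w, breaks)
  expect_equal(as.numeric(counts), c(10, 0, 0))

  # "10 ns at 1000 frames/ns, first 3 ns discarded" -> 7000 frames binned
  w2 <- umbrella_window(5, 10, rnorm(10000, 5, 0.3), n_discard = 3000)
  c2 <- bin_window(w2, seq(0, 10, length.out = 301))
  expect_equal(sum(c2), 7000)

  expect_error(umbrella_window(0, 10, rnorm(100), n_discard = 100), "empty")
  expect_error(bin_window(w, c(10, 11, 12)), "outside")
})

test_that("an unbiased single window degenerates to Boltzmann inversion", {
  set.seed(4)
  s <- rnorm(5000, 5, 1)
  w <- umbrella_window(5, 0, s)
  cfg <- wham_config(n_bins = 50, range = c(1, 9), bulk_points = 2)
  prof <- wham_solve(w, cfg)
  counts <- bin_window(w, prof$breaks)
  direct <- -cfg$kT * log(as.numeric(counts))
  direct <- direct - min(direct[is.finite(direct)])
  fin <- is.finite(prof$G)
  expect_lt(max(abs(prof$G[fin] - direct[fin])), 1e-10)
})

test_that("duplicated windows and window order do not change the solution", {
  wins <- us_windows()[seq(5, 15)]
  cfg <- wham_config(n_bins = 120, range = c(2, 8.2))
  base <- wham_solve(wins, cfg)
  expect_equal(base$f[1], 0)  # gauge

  # duplication invariance is exact only when each window's histogram
  # matches its reweighted reconstruction; with finite sampling the
  # duplicate re-weights the likelihood slightly
  dup <- wham_solve(c(wins[1], wins), cfg)
  fin <- is.finite(base$G) & is.finite(dup$G)
  expect_lt(max(abs(base$G[fin] - dup$G[fin])), 0.05)

  set.seed(1)
  perm <- wham_solve(sample(wins), cfg)
  fin2 <- is.finite(base$G) & is.finite(perm$G)
  expect_lt(max(abs(base$G[fin2] - perm$G[fin2])), 1e-6)
})

test_that("iterative WHAM matches a brute-force alternation oracle", {
  truth <- double_gaussian()
  centers <- c(4, 5, 6)
  samples <- lapply(seq_along(centers), function(j) {
    cfg <- langevin_config(4000, seed = 50 + j, initial_position = centers[j])
    as.numeric(simulate_overdamped(truth, harmonic_bias(centers[j], 10), cfg))
  })
  wins <- lapply(seq_along(centers), function(j)
    umbrella_window(centers[j], 10, samples[[j]]))
  cfg <- wham_config(n_bins = 40, range = c(3, 7), tolerance = 1e-10,
                     max_iterations = 2e5)
  prof <- wham_solve(wins, cfg)
  oracle <- naive_wham(centers, rep(10, 3), samples, prof$breaks, cfg$kT)
  fin <- is.finite(prof$G) & is.finite(oracle$G)
  expect_lt(max(abs(prof$G[fin] - oracle$G[fin])), 1e-8)
  expect_lt(max(abs(prof$f - oracle$f)), 1e-8)
})

test_that("disconnected window coverage is reported as such", {
  w1 <- umbrella_window(0, 10, rnorm(500, 0, 0.2))
  w2 <- umbrella_window(8, 10, rnorm(500, 8, 0.2))
  expect_error(wham_solve(list(w1, w2), wham_config(n_bins = 100)),
               "disconnected")
})

test_that("WHAM recovers a known double-Gaussian landscape to < 0.3 kcal/mol", {
  prof <- shift_profile(wham_solve(us_windows(), us_config()), 10)
  expect_lt(recovery_rmse(prof, double_gaussian()), 0.3)
  expect_equal(prof$residual < 1e-7, TRUE)
})

test_that("doubling the samples per window reduces recovery error", {
  truth <- double_gaussian()
  centers <- seq(0.5, 10, by = 0.5)
  # frames saved every 10 steps, as trajectories are in practice, so the
  # retained samples are close to independent
  sample_win <- function(j, n_frames, seed) {
    cfg <- langevin_config(n_frames * 10 + 5000, seed = seed,
                           initial_position = centers[j])
    xi <- simulate_overdamped(truth, harmonic_bias(centers[j], 10), cfg)
    as.numeric(xi[-seq_len(5000)][seq(10, n_frames * 10, by = 10)])
  }
  solve_p <- function(win_samples) {
    wins <- lapply(seq_along(centers), function(j)
      umbrella_window(centers[j], 10, win_samples[[j]]))
    shift_profile(wham_solve(wins, wham_config(n_bins = 100,
                                               range = c(0.3, 10.2))), 10)
  }
  wins_better <- vapply(1:10, function(r) {
    base <- lapply(seq_along(centers), function(j)
      sample_win(j, 1500, 10000 * r + j))
    extra <- lapply(seq_along(centers), function(j)      # new-seed replica
      sample_win(j, 1500, 10000 * r + 5000 + j))
    recovery_rmse(solve_p(Map(c, base, extra)), truth) <
      recovery_rmse(solve_p(base), truth)
  }, logical(1))
  expect_gte(sum(wins_better), 8)
})

test_that("bulk shifting zeroes the reference and is idempotent", {
  flat <- fake_profile(1:40, rep(7.3, 40))
  s1 <- shift_profile(flat, 10)
  expect_equal(s1$G, rep(0, 40))
  expect_equal(s1$shift_applied, 7.3)

  set.seed(2)
  g <- rnorm(60)
  p <- fake_profile(1:60, g)
  s <- shift_profile(p, 10)
  bulk <- c(1:10, 51:60)
  expect_equal(mean(s$G[bulk]), 0)
  expect_lt(abs(mean(shift_profile(s, 10)$G[bulk])), 1e-12)     # idempotent
  expect_equal(diff(s$G), diff(g))                              # shape kept

  known <- fake_profile(1:20, c(rep(2.5, 5), 4, 5, rep(2.5, 13)))
  expect_equal(shift_profile(known, 5)$G, known$G - 2.5)

  expect_error(shift_profile(fake_profile(1:10, rnorm(10)), 10), "fewer")
})

test_that("identical blocks give zero block SEM", {
  block <- rnorm(300, 5, 0.3)
  wins <- lapply(c(4.8, 5.2), function(cc)
    umbrella_window(cc, 10, rep(block + (cc - 5), 7), block_length = 300))
  be <- block_error(wins, wham_config(n_bins = 40, range = c(4, 6),
                                      bulk_points = 3))
  expect_equal(be$n_blocks, 7)
  expect_equal(max(be$sem, na.rm = TRUE), 0)
})

test_that("block SEM covers the true recovery error", {
  wins <- us_windows()
  be <- block_error(wins, us_config())
  expect_equal(be$n_blocks, 5)
  prof <- shift_profile(wham_solve(wins, us_config()), 10)
  fin <- is.finite(prof$G) & !is.na(be$sem)
  d <- prof$G[fin] - eval_potential(double_gaussian(), prof$xi[fin])$energy
  d <- d - mean(d)
  expect_gte(mean(abs(d) < 3 * be$sem[fin]), 0.95)
  expect_error(block_error(list(umbrella_window(5, 10, rnorm(300),
                                                block_length = 200))),
               "2 complete blocks")
})

test_that("feature extraction reads barrier and minimum off the profile", {
  # the printed-extrema pattern: bulk 0, minimum -4.1, barrier 2.8, bulk 0
  xi <- seq(0, 30, by = 0.1)
  G <- -4.1 * exp(-(xi - 12)^2 / 2) + 2.8 * exp(-(xi - 18)^2 / 2)
  f <- extract_features(fake_profile(xi, G, shifted = TRUE),
                        sf_region = c(15, 21))
  expect_equal(f$sf_barrier, 2.8, tolerance = 1e-3)
  expect_equal(f$global_minimum, -4.1, tolerance = 1e-3)
  expect_equal(f$luminal_to_cytosolic_barrier, 6.9, tolerance = 1e-2)

  mono <- extract_features(fake_profile(1:50, seq(0, 5, length.out = 50),
                                        shifted = TRUE), sf_region = c(40, 50))
  expect_equal(mono$luminal_to_cytosolic_barrier, 5)   # total rise
  expect_equal(mono$minimum_xi, 1)                     # minimum at the start

  flat <- extract_features(fake_profile(1:50, rep(0, 50), shifted = TRUE),
                           sf_region = c(1, 10))
  expect_equal(flat$sf_barrier, 0)
  expect_equal(flat$luminal_to_cytosolic_barrier, 0)

  expect_error(extract_features(fake_profile(1:50, rep(0, 50), shifted = TRUE),
                                sf_region = c(60, 70)), "no covered bins")
})

test_that("removing the luminal well collapses the barrier contrast", {
  sf <- c(6, 8)
  wt <- shift_profile(wham_solve(us_windows(), us_config()), 10)
  fw <- extract_features(wt, sf)
  # well present: the lumen-to-cytosol climb exceeds the SF barrier alone
  expect_gt(fw$luminal_to_cytosolic_barrier, fw$sf_barrier + 1)

  mut <- shift_profile(wham_solve(
    us_windows(double_gaussian_mutant(), seed_base = 3000, key = "mut"),
    us_config()), 10)
  fm <- extract_features(mut, sf)
  # well absent: the climb is just the SF barrier
  expect_lt(abs(fm$luminal_to_cytosolic_barrier - fm$sf_barrier), 0.3)
  expect_gt(fm$sf_barrier, fw$sf_barrier + 1)
})
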