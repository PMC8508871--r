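#' Plan umbrella windows along a pulled coordinate
#'
#' Window centers are placed at `start + i * spacing`, i = 1..n, with
#' `n = round(pull_span / spacing)` (the starting frame itself is not a
#' window).  A terminal stretch of the coordinate — e.g. a gate region
#' that is not part of the permeation analysis — can be dropped after
#' planning.
#'
#' @param pull_span total pulled distance (angstrom).
#' @param spacing window spacing (angstrom, > 0, <= `pull_span`).
#' @param drop_terminal length of the terminal stretch to drop
#'   (angstrom, <= `pull_span`).
#' @param start coordinate of the pull start (angstrom).
#' @return object of class `window_plan` with `centers`, `retained`
#'   (logical per window), `n_total`, `n_dropped_terminal`, `n_retained`.
#' @examples
#' plan_windows(50, 0.5)              # 100 windows
#' plan_windows(50, 0.5, drop_terminal = 15)$n_retained  # 70
#' @export
plan_windows <- function(pull_span, spacing, drop_terminal = 0, start = 0) {
  stopifnot(pull_span > 0, spacing > 0, drop_terminal >= 0,
            drop_terminal <= pull_span)
  if (spacing > pull_span)
    stop("window spacing exceeds the pulled span")
  n_total <- round(pull_span / spacing)
  n_drop <- round(drop_terminal / spacing)
  centers <- start + seq_len(n_total) * spacing
  retained <- rep(TRUE, n_total)
  if (n_drop > 0) retained[seq(n_total - n_drop + 1L, n_total)] <- FALSE
  structure(list(centers = centers, spacing = spacing, retained = retained,
                 n_total = n_total, n_dropped_terminal = n_drop,
                 n_retained = n_total - n_drop),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat("window plan:", x$n_total, "windows at", x$spacing, "A spacing;",
      x$n_dropped_terminal, "terminal window(s) dropped,", x$n_retained,
      "retained\n")
  invisible(x)
}

#' One umbrella window
#'
#' @param center restraint center (angstrom).
#' @param force_constant harmonic force constant (kcal mol^-1 A^-2;
#'   zero means an unbiased window).
#' @param samples reaction-coordinate series (angstrom).
#' @param n_discard leading frames discarded as equilibration.
#' @param block_length frames per error-analysis block (the "1 ns" unit
#'   used by [block_error()]).
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, samples, n_discard = 0L,
                            block_length = NULL) {
  stopifnot(is.finite(center), force_constant >= 0, is.numeric(samples))
  if (length(samples) <= n_discard)
    stop("window at ", center, " A is empty after the equilibration discard")
  structure(list(center = center, force_constant = force_constant,
                 samples = as.numeric(samples),
                 n_discard = as.integer(n_discard),
                 block_length = block_length),
            class = "umbrella_window")
}

retained_samples <- function(w) {
  if (w$n_discard > 0L) w$samples[-seq_len(w$n_discard)] else w$samples
}

#' Histogram a window onto the WHAM grid
#'
#' Discards the equilibration frames, then counts samples per bin.
#' Out-of-grid samples are dropped and recorded in the
#' `n_out_of_range` attribute.
#'
#' @param window an [umbrella_window()].
#' @param breaks bin boundaries (length `n_bins + 1`, increasing).
#' @return integer vector of per-bin counts.
#' @export
bin_window <- function(window, breaks) {
  stopifnot(inherits(window, "umbrella_window"), length(breaks) >= 3L)
  s <- retained_samples(window)
  nb <- length(breaks) - 1L
  idx <- findInterval(s, breaks, rightmost.closed = TRUE)
  ok <- idx >= 1L & idx <= nb & s >= breaks[1]
  if (!any(ok))
    stop("all samples of the window at ", window$center,
         " A fall outside the histogram grid [", breaks[1], ", ",
         breaks[length(breaks)], "]")
  counts <- tabulate(idx[ok], nbins = nb)
  attr(counts, "n_out_of_range") <- sum(!ok)
  counts
}

#' WHAM configuration
#'
#' @param n_bins histogram bins (default 300).
#' @param tolerance convergence threshold on max |change in window free
#'   energy f_j| between iterations, kcal/mol (default 1e-7).
#' @param max_iterations iteration cap.
#' @param kT thermal energy (kcal/mol).
#' @param bulk_points bins at each profile end treated as bulk solution
#'   for [shift_profile()] (default 10).
#' @param range optional fixed grid range `c(lo, hi)`; default spans the
#'   pooled samples.
#' @return object of class `wham_config`.
#' @export
wham_config <- function(n_bins = 300L, tolerance = 1e-7,
                        max_iterations = 100000L, kT = thermal_energy(300),
                        bulk_points = 10L, range = NULL) {
  stopifnot(n_bins >= 2L, tolerance > 0, max_iterations >= 1L, kT > 0,
            bulk_points >= 1L)
  if (!is.null(range)) stopifnot(length(range) == 2L, range[1] < range[2])
  structure(list(n_bins = as.integer(n_bins), tolerance = tolerance,
                 max_iterations = as.integer(max_iterations), kT = kT,
                 bulk_points = as.integer(bulk_points), range = range),
            class = "wham_config")
}

## connectivity of window coverage: windows form one component if linked
## through shared histogram bins; otherwise relative free energies are
## undetermined across the gap.
check_coverage <- function(counts, centers_xi) {
  J <- ncol(counts)
  if (J == 1L) return(invisible(TRUE))
  cov <- counts > 0
  comp <- integer(J)
  comp[1] <- 1L
  repeat {
    grew <- FALSE
    for (j in which(comp == 0L)) {
      linked <- vapply(which(comp > 0L), function(k)
        any(cov[, j] & cov[, k]), logical(1))
      if (any(linked)) {
        comp[j] <- 1L
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  if (any(comp == 0L)) {
    inside <- range(centers_xi[rowSums(cov[, comp > 0L, drop = FALSE]) > 0])
    stop("disconnected sampling coverage: windows near xi = ",
         signif(min(centers_xi[rowSums(cov[, comp == 0L, drop = FALSE]) > 0]), 4),
         " A share no histogram bins with the component covering [",
         signif(inside[1], 4), ", ", signif(inside[2], 4), "] A")
  }
  invisible(TRUE)
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Self-consistent iteration of
#' \deqn{P(\xi_b) = \frac{\sum_j n_j(\xi_b)}
#'       {\sum_j N_j \exp[(f_j - w_j(\xi_b))/k_B T]},\qquad
#'       f_j = -k_B T \ln \sum_b P(\xi_b) e^{-w_j(\xi_b)/k_B T},}
#' with the harmonic window restraint \eqn{w_j(\xi) = k_j (\xi -
#' \xi_j)^2/2}, gauge fixed by \eqn{f_1 = 0}, iterated until
#' \eqn{\max_j |\Delta f_j|} falls below the tolerance.  The profile is
#' \eqn{G(\xi) = -k_B T \ln P(\xi)} up to a constant; bins with no
#' samples carry a `+Inf` sentinel and are excluded from shifting and
#' feature extraction.
#'
#' @param windows list of [umbrella_window()] objects (>= 1).
#' @param cfg a [wham_config()].
#' @return object of class `pmf_profile`: `xi` (bin centers), `G`
#'   (kcal/mol, unshifted), `n_samples` per bin, `f` (window free
#'   energies), `iterations`, `residual`, `kT`, `breaks`,
#'   `shift_applied` (0 until [shift_profile()]), `error` (NULL until
#'   [block_error()]).
#' @export
wham_solve <- function(windows, cfg = wham_config()) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, inherits, logical(1), "umbrella_window")),
            inherits(cfg, "wham_config"))
  rng <- cfg$range
  if (is.null(rng)) {
    rng <- range(unlist(lapply(windows, retained_samples)))
    if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  }
  breaks <- seq(rng[1], rng[2], length.out = cfg$n_bins + 1L)
  xi <- (breaks[-1] + breaks[-length(breaks)]) / 2

  counts <- vapply(windows, bin_window, numeric(cfg$n_bins), breaks = breaks)
  counts <- matrix(counts, nrow = cfg$n_bins)
  check_coverage(counts, xi)
  N <- colSums(counts)
  n_b <- rowSums(counts)

  ## A[b, j] = exp(-w_j(xi_b)/kT); far-off bins underflow harmlessly to 0
  cen <- vapply(windows, `[[`, numeric(1), "center")
  kk <- vapply(windows, `[[`, numeric(1), "force_constant")
  W <- 0.5 * outer(xi, cen, `-`)^2 %*% diag(kk, length(kk))
  A <- exp(-W / cfg$kT)

  f <- numeric(length(windows))
  it <- 0L
  residual <- Inf
  covered <- n_b > 0
  repeat {
    it <- it + 1L
    denom <- as.numeric(A %*% (N * exp(f / cfg$kT)))
    P <- ifelse(covered & denom > 0, n_b / denom, 0)
    P <- P / sum(P)
    Z <- as.numeric(crossprod(A, P))
    f_new <- -cfg$kT * log(Z)
    f_new <- f_new - f_new[1]
    residual <- max(abs(f_new - f))
    f <- f_new
    if (residual < cfg$tolerance) break
    if (it >= cfg$max_iterations)
      stop("WHAM did not converge in ", cfg$max_iterations,
           " iterations (residual ", signif(residual, 3), " kcal/mol)")
  }

  G <- rep(Inf, cfg$n_bins)
  G[covered] <- -cfg$kT * log(P[covered])
  G[covered] <- G[covered] - min(G[covered])
  structure(list(xi = xi, G = G, n_samples = n_b, f = f, iterations = it,
                 residual = residual, kT = cfg$kT, breaks = breaks,
                 shift_applied = 0, shifted = FALSE, error = NULL),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  fin <- is.finite(x$G)
  cat("PMF profile:", length(x$xi), "bins over [",
      signif(min(x$xi), 4), ",", signif(max(x$xi), 4), "] A;",
      sum(fin), "covered\n")
  cat(sprintf("converged in %d iterations (residual %.2e kcal/mol); %s\n",
              x$iterations, x$residual,
              if (x$shifted) sprintf("bulk-shifted by %.4g kcal/mol",
                                     x$shift_applied) else "unshifted"))
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(xi = x$xi, G = x$G,
             sem = if (is.null(x$error)) NA_real_ else x$error,
             n_samples = x$n_samples)
}

#' Shift a PMF so that the bulk reference is zero
#'
#' Subtracts the mean free energy over the first and last `bulk_points`
#' bins (the bulk-solution ends of the coordinate), leaving the shape
#' unchanged.  Idempotent.
#'
#' @param profile a `pmf_profile`.
#' @param bulk_points bins at each end treated as bulk (default 10).
#' @return the shifted `pmf_profile`.
#' @export
shift_profile <- function(profile, bulk_points = 10L) {
  stopifnot(inherits(profile, "pmf_profile"), bulk_points >= 1L)
  nb <- length(profile$G)
  if (nb < 2L * bulk_points)
    stop("profile has fewer than 2 * bulk_points bins")
  idx <- c(seq_len(bulk_points), seq(nb - bulk_points + 1L, nb))
  g <- profile$G[idx]
  if (!any(is.finite(g)))
    stop("bulk bins are empty (no samples); cannot anchor the profile")
  sh <- mean(g[is.finite(g)])
  profile$G <- profile$G - sh
  profile$shift_applied <- profile$shift_applied + sh
  profile$shifted <- TRUE
  profile$bulk_points <- as.integer(bulk_points)
  profile
}

#' Block-wise error estimation for a WHAM profile
#'
#' Splits each window's retained series into contiguous blocks of
#' `block_length` frames (the per-window "1 ns" unit; a trailing
#' remainder is dropped and recorded), solves WHAM + bulk shift per
#' block, and returns the per-bin standard error of the mean across
#' block profiles (n - 1 denominator).
#'
#' @param windows list of [umbrella_window()] objects with
#'   `block_length` set.
#' @param cfg a [wham_config()]; the grid is fixed to the full-data grid
#'   so block profiles are bin-aligned.
#' @return list with `sem` (per-bin SEM; NA where any block lacks
#'   coverage), `block_G` (bins x blocks matrix of shifted profiles),
#'   `n_blocks`, `dropped_frames`.
#' @export
block_error <- function(windows, cfg = wham_config()) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  bl <- vapply(windows, function(w) {
    if (is.null(w$block_length)) stop("every window needs a block_length")
    as.integer(w$block_length)
  }, integer(1))
  nret <- vapply(windows, function(w) length(retained_samples(w)), integer(1))
  n_blocks <- min(nret %/% bl)
  if (n_blocks < 2L)
    stop("block error needs at least 2 complete blocks per window (got ",
         n_blocks, ")")
  dropped <- sum(nret - n_blocks * bl)

  full <- wham_solve(windows, cfg)
  cfg_fixed <- cfg
  cfg_fixed$range <- range(full$breaks)

  block_G <- matrix(NA_real_, length(full$xi), n_blocks)
  for (b in seq_len(n_blocks)) {
    sub <- lapply(seq_along(windows), function(j) {
      s <- retained_samples(windows[[j]])
      seg <- s[seq.int((b - 1L) * bl[j] + 1L, b * bl[j])]
      umbrella_window(windows[[j]]$center, windows[[j]]$force_constant,
                      seg, n_discard = 0L)
    })
    p <- shift_profile(wham_solve(sub, cfg_fixed), cfg$bulk_points)
    block_G[, b] <- ifelse(is.finite(p$G), p$G, NA_real_)
  }
  ok <- rowSums(is.na(block_G)) == 0L
  sem <- rep(NA_real_, nrow(block_G))
  sem[ok] <- apply(block_G[ok, , drop = FALSE], 1, sd) / sqrt(n_blocks)
  list(sem = sem, block_G = block_G, n_blocks = n_blocks,
       dropped_frames = dropped)
}

#' Extract barrier and minimum features from a shifted PMF
#'
#' The coordinate is oriented from the luminal bulk (small xi) through
#' the selectivity filter toward the cytosol (large xi).  Reported
#' features:
#' * `sf_barrier`: maximum G within the selectivity-filter region;
#' * `global_minimum` and its position;
#' * `luminal_to_cytosolic_barrier`: the largest climb encountered when
#'   moving from the luminal end toward the cytosol, i.e. the maximum of
#'   G minus its running minimum — for a profile with a luminal well
#'   followed by a barrier this is barrier minus well depth; for a
#'   profile without a well it reduces to the barrier height itself.
#'
#' @param profile a bulk-shifted `pmf_profile`.
#' @param sf_region numeric length-2 xi-interval of the selectivity
#'   filter; default = the 10% of the covered coordinate nearest the
#'   luminal (small-xi) end.
#' @return object of class `pmf_features`.
#' @export
extract_features <- function(profile, sf_region = NULL) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (!isTRUE(profile$shifted))
    warning("profile has not been bulk-shifted; features are relative to ",
            "an arbitrary zero")
  fin <- is.finite(profile$G)
  if (!any(fin)) stop("profile has no covered bins")
  xi <- profile$xi[fin]
  G <- profile$G[fin]
  if (is.null(sf_region))
    sf_region <- c(min(xi), min(xi) + 0.1 * diff(range(xi)))
  stopifnot(length(sf_region) == 2L, sf_region[1] <= sf_region[2])
  in_sf <- xi >= sf_region[1] & xi <= sf_region[2]
  if (!any(in_sf)) stop("sf_region contains no covered bins")
  i_min <- which.min(G)
  structure(list(
    sf_barrier = max(G[in_sf]),
    global_minimum = G[i_min],
    minimum_xi = xi[i_min],
    luminal_to_cytosolic_barrier = max(G - cummin(G)),
    sf_region = sf_region), class = "pmf_features")
}

#' @export
print.pmf_features <- function(x, ...) {
  cat(sprintf(paste0("PMF features: SF barrier %.2f kcal/mol; minimum %.2f at ",
                     "xi = %.2f A; luminal-to-cytosolic barrier %.2f kcal/mol\n"),
              x$sf_barrier, x$global_minimum, x$minimum_xi,
              x$luminal_to_cytosolic_barrier))
  invisible(x)
}
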