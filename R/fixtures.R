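#' Script of scheduled membrane crossings
#'
#' Declares, per ion, when and in which direction a complete passage
#' through the selectivity-filter slab occurs.  [make_crossing_trajectories()]
#' turns the script into z(t) series whose crossing counts equal the
#' schedule exactly, so the permeation counter can be verified against
#' ground truth.
#'
#' @param crossings data.frame with columns `ion` (integer id),
#'   `direction` (`"up"` = increasing z or `"down"`), `t_start`, `t_end`
#'   (frame indices, 1-based, `t_start < t_end`).  Crossing windows of one
#'   ion must not overlap and consecutive crossings of one ion must
#'   alternate direction (an ion cannot cross upward twice without
#'   returning).
#' @param n_ions number of ions (ions without scheduled crossings just
#'   produce noise about their baseline).
#' @param n_frames trajectory length in frames.
#' @param slab numeric length-2, the slab bounds `c(z_lower, z_upper)`.
#' @param baseline_offset distance of the resting baselines beyond the
#'   slab planes (angstrom).
#' @param noise_sd standard deviation of the positional noise (angstrom);
#'   deviates are clamped at 3 sd so the schedule stays exactly countable.
#'   Must satisfy `3 * noise_sd < baseline_offset`.
#' @param box_length_z optional periodic box length; with `wrap = TRUE`
#'   the series is wrapped into `[0, box_length_z)` to exercise
#'   trajectory unwrapping downstream.
#' @param wrap wrap the output coordinates (requires `box_length_z`).
#' @param seed RNG seed for the noise.
#' @return object of class `crossing_script`.
#' @export
crossing_script <- function(crossings = NULL, n_ions = 1L, n_frames = 500L,
                            slab = c(-5, 5), baseline_offset = 5,
                            noise_sd = 0.5, box_length_z = NULL,
                            wrap = FALSE, seed = NULL) {
  stopifnot(length(slab) == 2L, slab[1] < slab[2],
            baseline_offset > 0, noise_sd >= 0, n_frames >= 2)
  if (3 * noise_sd >= baseline_offset)
    stop("noise_sd too large: need 3 * noise_sd < baseline_offset for exact counts")
  if (wrap && is.null(box_length_z))
    stop("wrap = TRUE requires box_length_z")
  if (is.null(crossings))
    crossings <- data.frame(ion = integer(), direction = character(),
                            t_start = integer(), t_end = integer())
  stopifnot(all(c("ion", "direction", "t_start", "t_end") %in% names(crossings)))
  if (nrow(crossings)) {
    stopifnot(all(crossings$direction %in% c("up", "down")),
              all(crossings$t_start >= 1), all(crossings$t_end <= n_frames),
              all(crossings$t_start < crossings$t_end),
              all(crossings$ion >= 1), all(crossings$ion <= n_ions))
    for (id in unique(crossings$ion)) {
      ci <- crossings[crossings$ion == id, , drop = FALSE]
      ci <- ci[order(ci$t_start), , drop = FALSE]
      if (nrow(ci) > 1L) {
        if (any(ci$t_start[-1] <= ci$t_end[-nrow(ci)]))
          stop("crossing windows overlap for ion ", id)
        if (any(ci$direction[-1] == ci$direction[-nrow(ci)]))
          stop("consecutive crossings of ion ", id,
               " must alternate direction (a full return is itself a crossing)")
      }
    }
  }
  structure(list(crossings = crossings, n_ions = as.integer(n_ions),
                 n_frames = as.integer(n_frames), slab = slab,
                 baseline_offset = baseline_offset, noise_sd = noise_sd,
                 box_length_z = box_length_z, wrap = wrap, seed = seed),
            class = "crossing_script")
}

#' Generate per-ion z(t) trajectories from a crossing script
#'
#' Each ion rests at a baseline `baseline_offset` beyond one slab plane
#' and traverses to the opposite baseline along a smooth ramp during each
#' scheduled window; clamped Gaussian noise is superimposed.  By
#' construction the number and direction of complete slab crossings
#' equals the schedule exactly.
#'
#' @param script a [crossing_script()].
#' @return list of numeric z(t) vectors, one per ion, with the slab and
#'   box geometry in attributes.
#' @export
make_crossing_trajectories <- function(script) {
  stopifnot(inherits(script, "crossing_script"))
  if (!is.null(script$seed)) set.seed(script$seed)
  lo <- script$slab[1] - script$baseline_offset
  hi <- script$slab[2] + script$baseline_offset
  out <- vector("list", script$n_ions)
  for (id in seq_len(script$n_ions)) {
    ci <- script$crossings[script$crossings$ion == id, , drop = FALSE]
    ci <- ci[order(ci$t_start), , drop = FALSE]
    start_low <- if (nrow(ci)) ci$direction[1] == "up" else TRUE
    z <- rep(if (start_low) lo else hi, script$n_frames)
    for (k in seq_len(nrow(ci))) {
      from <- if (ci$direction[k] == "up") lo else hi
      to <- if (ci$direction[k] == "up") hi else lo
      tt <- ci$t_start[k]:ci$t_end[k]
      ramp <- (1 - cos(pi * (tt - tt[1]) / (length(tt) - 1))) / 2
      z[tt] <- from + (to - from) * ramp
      if (ci$t_end[k] < script$n_frames)
        z[(ci$t_end[k] + 1):script$n_frames] <- to
    }
    if (script$noise_sd > 0) {
      eta <- pmin(pmax(rnorm(script$n_frames), -3), 3)
      z <- z + script$noise_sd * eta
    }
    if (script$wrap)
      z <- z %% script$box_length_z
    out[[id]] <- z
  }
  attr(out, "slab") <- script$slab
  attr(out, "box_length_z") <- script$box_length_z
  attr(out, "wrapped") <- script$wrap
  out
}

#' Geometric pore fixture with a known radius profile
#'
#' Builds rings of spheres of radius `atom_vdw` around the z axis with
#' ring radius `radius_profile(z) + atom_vdw`, so the accessible (largest
#' inscribed sphere) radius at each slice is exactly `radius_profile(z)`.
#' Used to verify the pore profiler against analytic geometry.
#'
#' @param radius_profile function of z returning the intended pore radius
#'   (angstrom, > 0).
#' @param z_range numeric length-2 `c(zmin, zmax)`; an empty range
#'   (`zmin > zmax`) yields no atoms.
#' @param dz slice spacing (angstrom).
#' @param atom_vdw van der Waals radius assigned to the fixture atoms.
#' @param n_ring atoms per ring.
#' @return data.frame with columns `x, y, z, vdw` (class `atom_set` via
#'   [as_atom_set()] is accepted directly by [pore_radius_profile()]).
#' @examples
#' atoms <- make_pore_geometry(function(z) 5, c(-10, 10), dz = 1)
#' @export
make_pore_geometry <- function(radius_profile, z_range, dz = 1,
                               atom_vdw = 1.5, n_ring = 24L) {
  stopifnot(is.function(radius_profile), length(z_range) == 2L,
            dz > 0, atom_vdw > 0, n_ring >= 3L)
  if (z_range[1] > z_range[2])
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      vdw = numeric()))
  zs <- seq(z_range[1], z_range[2], by = dz)
  ang <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  rows <- lapply(zs, function(zi) {
    r <- radius_profile(zi)
    if (!is.finite(r) || r <= 0)
      stop("radius_profile must be positive and finite (z = ", zi, ")")
    rc <- r + atom_vdw
    data.frame(x = rc * cos(ang), y = rc * sin(ang), z = zi, vdw = atom_vdw)
  })
  do.call(rbind, rows)
}

#' Write a pore fixture (or any atom table) as PDB
#'
#' Writes ATOM records with the per-atom van der Waals radius carried in
#' the occupancy column, the convention [as_atom_set()] reads back.
#'
#' @param atoms data.frame with `x, y, z, vdw`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_pore_pdb <- function(atoms, file) {
  stopifnot(all(c("x", "y", "z", "vdw") %in% names(atoms)))
  n <- nrow(atoms)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = seq_len(n), resid = rep("POR", n),
                   elety = rep("C", n), chain = rep("A", n),
                   o = atoms$vdw, b = rep(0, n))
  invisible(file)
}

#' Hydration-shell snapshot with exact coordination numbers
#'
#' Places `n_first` water oxygens at distance `r_first` from the ion and
#' `n_outer` at `r_outer`, in uniformly random directions, so a shell
#' count with any cutoff between `r_first` and `r_outer` returns exactly
#' `n_first`.
#'
#' @param ion_position numeric length-3.
#' @param n_first,n_outer non-negative oxygen counts.
#' @param r_first,r_outer shell distances (angstrom), `r_first < r_outer`.
#' @param seed RNG seed; fixed seeds give identical coordinates.
#' @return list with `ion` (length-3) and `oxygens` (matrix n x 3).
#' @export
make_hydration_snapshot <- function(ion_position = c(0, 0, 0), n_first, r_first,
                                    n_outer = 0L, r_outer = 2 * r_first,
                                    seed = NULL) {
  if (n_first < 0 || n_outer < 0) stop("shell counts must be non-negative")
  stopifnot(length(ion_position) == 3L, r_first > 0, r_outer > r_first)
  if (!is.null(seed)) set.seed(seed)
  place <- function(n, r) {
    if (n == 0L) return(matrix(numeric(), 0, 3))
    v <- matrix(rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    sweep(v * r, 2, ion_position, `+`)
  }
  list(ion = as.numeric(ion_position),
       oxygens = rbind(place(n_first, r_first), place(n_outer, r_outer)))
}
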