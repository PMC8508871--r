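## Bondi van der Waals radii (angstrom), by element symbol
.bondi <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
            F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
.bondi_default <- 1.70

#' Build an atom set for pore profiling
#'
#' Accepts a `bio3d` `pdb` object (from [bio3d::read.pdb()]) or a
#' data.frame with columns `x, y, z` and optionally `vdw`.  Radii are
#' assigned from a Bondi element table unless `use_occupancy = TRUE`, in
#' which case the PDB occupancy column is read as a per-atom radius (the
#' convention [write_pore_pdb()] writes).  Waters and other HETATM
#' records are excluded by default, matching standard pore-profiling
#' practice.
#'
#' @param x a `bio3d` pdb object or data.frame.
#' @param use_occupancy read per-atom radii from the occupancy column?
#' @param include_het keep HETATM records (waters, ions)?
#' @return object of class `atom_set`: list with `xyz` (n x 3 matrix)
#'   and `vdw` (length n).
#' @export
as_atom_set <- function(x, use_occupancy = FALSE, include_het = FALSE) {
  if (inherits(x, "atom_set")) return(x)
  if (inherits(x, "pdb")) {
    at <- x$atom
    if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
    if (!nrow(at)) stop("no atoms left after record filtering")
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (use_occupancy) {
      vdw <- at$o
      if (any(!is.finite(vdw) | vdw <= 0))
        stop("occupancy column does not hold positive radii")
    } else {
      el <- toupper(sub("^\\s+|\\s+$", "", at$elesy))
      bad <- is.na(el) | el == ""
      el[bad] <- toupper(substr(at$elety[bad], 1, 1))
      vdw <- unname(ifelse(el %in% names(.bondi), .bondi[el], .bondi_default))
    }
  } else if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    xyz <- as.matrix(x[, c("x", "y", "z")])
    vdw <- if ("vdw" %in% names(x)) x$vdw else rep(.bondi_default, nrow(x))
  } else stop("x must be a bio3d pdb object or a data.frame")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  if (any(!is.finite(vdw) | vdw <= 0)) stop("van der Waals radii must be > 0")
  structure(list(xyz = xyz, vdw = as.numeric(vdw)), class = "atom_set")
}

## accessible radius at point (x, y, z): distance to the nearest atom
## surface.  Negative inside an atom.
slice_radius <- function(p, z, xyz, vdw) {
  d <- sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - z)^2)
  min(d - vdw)
}

#' HOLE-style pore radius profile
#'
#' For each slice along z, finds the in-plane center (x, y) maximizing
#' the largest-inscribed-sphere radius
#' \eqn{f(x,y) = \min_i (|p - a_i| - r_i)} by multi-start Nelder-Mead,
#' seeding each slice from the previous slice's optimum so the center
#' path is continuous through connected pores.  Slices whose radius
#' exceeds `cap` (pore opens to bulk) are set to `cap` and flagged.
#'
#' @param atoms anything [as_atom_set()] accepts.
#' @param z_range numeric length-2 slice range (angstrom); default the
#'   structure's z extent.
#' @param dz slice spacing (angstrom).
#' @param restarts random restarts per slice in addition to the
#'   continuation start.
#' @param seed RNG seed for the restart jitter.
#' @param cap radius cap marking an unbounded slice (angstrom).
#' @param start in-plane starting center for the first slice.
#' @return object of class `pore_profile`: `z`, `r` (pore radius),
#'   `cx`, `cy` (center path), `flagged` (capped slices).
#' @examples
#' atoms <- make_pore_geometry(function(z) 5, c(-6, 6), dz = 1)
#' prof <- pore_radius_profile(atoms, c(-5, 5), dz = 1, seed = 1)
#' range(prof$r)  # 5 5
#' @export
pore_radius_profile <- function(atoms, z_range = NULL, dz = 0.5, restarts = 8L,
                                seed = NULL, cap = 15, start = c(0, 0)) {
  atoms <- as_atom_set(atoms)
  if (nrow(atoms$xyz) < 4L)
    stop("pore profiling needs at least 4 atoms")
  stopifnot(dz > 0, restarts >= 0L, cap > 0)
  if (is.null(z_range)) z_range <- range(atoms$xyz[, 3])
  if (!is.null(seed)) set.seed(seed)
  zs <- seq(z_range[1], z_range[2], by = dz)
  n <- length(zs)
  r <- cx <- cy <- numeric(n)
  flagged <- logical(n)
  prev <- start
  max_vdw <- max(atoms$vdw)
  for (i in seq_len(n)) {
    zi <- zs[i]
    near <- abs(atoms$xyz[, 3] - zi) <= cap + max_vdw
    if (!any(near)) {
      r[i] <- cap; flagged[i] <- TRUE; cx[i] <- prev[1]; cy[i] <- prev[2]
      next
    }
    xyz <- atoms$xyz[near, , drop = FALSE]
    vdw <- atoms$vdw[near]
    fn <- function(p) -slice_radius(p, zi, xyz, vdw)
    starts <- rbind(prev,
                    if (restarts > 0L)
                      cbind(prev[1] + rnorm(restarts, sd = 1.5),
                            prev[2] + rnorm(restarts, sd = 1.5)))
    ## a restart placed outside the pore walls runs off to unbounded radii;
    ## keep the best optimum that stays below the cap, and declare the slice
    ## open only when every start escapes
    best <- NULL
    escaped <- TRUE
    for (s in seq_len(nrow(starts))) {
      o <- optim(starts[s, ], fn, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 1000))
      if (-o$value <= cap) {
        if (escaped || o$value < best$value) best <- o
        escaped <- FALSE
      } else if (escaped && is.null(best)) best <- o
    }
    if (escaped) {
      r[i] <- cap; flagged[i] <- TRUE
      cx[i] <- prev[1]; cy[i] <- prev[2]
    } else {
      r[i] <- -best$value
      cx[i] <- best$par[1]; cy[i] <- best$par[2]
      prev <- best$par
    }
  }
  structure(list(z = zs, r = r, cx = cx, cy = cy, flagged = flagged, dz = dz),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("pore profile:", length(x$z), "slices over [", signif(min(x$z), 4), ",",
      signif(max(x$z), 4), "] A; min radius", signif(min(x$r), 4), "A at z =",
      signif(x$z[which.min(x$r)], 4), "\n")
  if (any(x$flagged)) cat(sum(x$flagged), "slice(s) capped (open to bulk)\n")
  invisible(x)
}

#' @export
as.data.frame.pore_profile <- function(x, ...) {
  data.frame(z = x$z, r = x$r, cx = x$cx, cy = x$cy, flagged = x$flagged)
}

#' Average pore profiles across replicas
#'
#' Profiles on mismatched z grids are resampled onto `grid` (default the
#' first profile's grid, restricted to the common overlap) by linear
#' interpolation; the per-z mean and standard error of the mean (n - 1
#' denominator) are returned.
#'
#' @param profiles list of `pore_profile` objects.
#' @param grid optional common z grid.
#' @return data.frame with `z`, `mean_r`, `sem` (NA when a single
#'   profile is supplied), `n`.
#' @export
average_profiles <- function(profiles, grid = NULL) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "pore_profile")))
  lo <- max(vapply(profiles, function(p) min(p$z), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$z), numeric(1)))
  if (lo > hi) stop("profiles share no z overlap")
  if (is.null(grid)) {
    grid <- profiles[[1]]$z
    grid <- grid[grid >= lo & grid <= hi]
  } else stopifnot(all(grid >= lo), all(grid <= hi))
  vals <- vapply(profiles, function(p) approx(p$z, p$r, xout = grid)$y,
                 numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- length(profiles)
  data.frame(z = grid,
             mean_r = rowMeans(vals),
             sem = if (n > 1L) apply(vals, 1, sd) / sqrt(n) else NA_real_,
             n = n)
}

#' Kabsch superposition RMSD
#'
#' Least-squares optimal superposition of two coordinate sets (proper
#' rotation enforced via the determinant sign correction of the SVD
#' solution) and the resulting root-mean-square deviation.
#'
#' @param coords_a,coords_b n x 3 matrices of matched atoms.
#' @param selection optional row indices (applied to both sets).
#' @return RMSD in angstrom, with the rotation matrix in attribute
#'   `rotation`.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' kabsch_rmsd(a, a)  # 0
#' @export
kabsch_rmsd <- function(coords_a, coords_b, selection = NULL) {
  A <- as.matrix(coords_a)
  B <- as.matrix(coords_b)
  if (!is.null(selection)) {
    A <- A[selection, , drop = FALSE]
    B <- B[selection, , drop = FALSE]
  }
  if (nrow(A) != nrow(B))
    stop("coordinate sets differ in atom count (", nrow(A), " vs ",
         nrow(B), ")")
  stopifnot(ncol(A) == 3L, ncol(B) == 3L, nrow(A) >= 1L)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(Ac, Bc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Ar <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ar - Bc)^2)))
  attr(rmsd, "rotation") <- R
  rmsd
}
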