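#' Selectivity-filter slab definition
#'
#' The slab between `z_lower` and `z_upper` bounds the selectivity
#' filter; an ion is counted as permeating only on a full passage from
#' strictly below the lower plane to strictly above the upper plane (or
#' the reverse).  The two-plane hysteresis prevents double counting of
#' ions rattling at a boundary; setting `z_lower == z_upper` recovers a
#' single-plane counter for comparison.
#'
#' @param z_lower,z_upper slab bounds (angstrom, `z_lower <= z_upper`).
#' @param box_length_z optional periodic box length; trajectories are
#'   unwrapped by minimum-image increments before counting.
#' @param cytosol which side (`"lower"` or `"upper"` z) is the cytosol;
#'   fixes the direction labels so that a positive applied voltage
#'   drives cations cytosol-to-lumen.
#' @return object of class `slab_spec`.
#' @export
slab_spec <- function(z_lower, z_upper, box_length_z = NULL,
                      cytosol = c("lower", "upper")) {
  cytosol <- match.arg(cytosol)
  stopifnot(is.finite(z_lower), is.finite(z_upper), z_lower <= z_upper)
  if (!is.null(box_length_z)) stopifnot(box_length_z > z_upper - z_lower)
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 box_length_z = box_length_z, cytosol = cytosol),
            class = "slab_spec")
}

#' Unwrap a periodic z trajectory
#'
#' Reconstructs a continuous trajectory from wrapped coordinates by
#' accumulating minimum-image frame-to-frame increments.
#'
#' @param z wrapped coordinates.
#' @param box_length_z periodic box length.
#' @return unwrapped coordinates (same length, same first value).
#' @export
unwrap_z <- function(z, box_length_z) {
  stopifnot(box_length_z > 0, length(z) >= 1L)
  if (length(z) == 1L) return(z)
  dz <- diff(z)
  dz <- dz - box_length_z * round(dz / box_length_z)
  c(z[1], z[1] + cumsum(dz))
}

#' Count complete permeation events in a z(t) series
#'
#' Two-plane hysteresis counter: an upward event is registered when an
#' ion last seen strictly below `z_lower` is next seen strictly above
#' `z_upper` (downward: vice versa).  After an event the ion must return
#' across the full slab before an opposite event can register, so
#' boundary oscillation inside the slab produces no events.  Periodic
#' series are unwrapped first when the slab carries a box length.
#'
#' @param z numeric z(t) series for one ion, or a list of such series
#'   (one per ion).
#' @param slab a [slab_spec()].
#' @return data.frame of events with columns `ion`, `frame` (frame at
#'   which the crossing completes), `direction_z` (`"up"`/`"down"`), and
#'   `direction` (`"cytosol_to_lumen"`/`"lumen_to_cytosol"` per the slab
#'   orientation).
#' @examples
#' z <- c(-8, -2, 3, 8)           # one upward passage through [-5, 5]
#' count_crossings(z, slab_spec(-5, 5))
#' @export
count_crossings <- function(z, slab) {
  stopifnot(inherits(slab, "slab_spec"))
  if (is.list(z)) {
    out <- lapply(seq_along(z), function(i) {
      ev <- count_crossings(z[[i]], slab)
      if (nrow(ev)) ev$ion <- i
      ev
    })
    return(do.call(rbind, out))
  }
  z <- as.numeric(z)
  if (any(!is.finite(z))) stop("trajectory contains non-finite coordinates")
  if (!is.null(slab$box_length_z)) {
    L <- slab$box_length_z
    z <- unwrap_z(z, L)
    if (any(abs(diff(z)) > 0.45 * L))
      warning("frame-to-frame jumps close to half the box after unwrapping; ",
              "crossing assignment may be ambiguous at the flagged frames")
    ## after unwrapping the slab recurs every box length; index the gaps
    ## between successive slab images so a passage through any image counts
    kf <- floor((z - slab$z_lower) / L)
    z_local <- z - kf * L              # in [z_lower, z_lower + L)
    gap <- ifelse(z_local <= slab$z_upper, NA_integer_, kf)
  } else {
    gap <- ifelse(z < slab$z_lower, -1L, ifelse(z > slab$z_upper, 0L, NA_integer_))
  }
  outside <- which(!is.na(gap))
  if (length(outside) < 2L)
    return(data.frame(ion = integer(), frame = integer(),
                      direction_z = character(), direction = character()))
  gg <- gap[outside]
  dg <- diff(gg)
  chg <- which(dg != 0L)
  # |dg| > 1 means several slab images were traversed between outside
  # sightings; count one event per image passed
  frame <- rep(outside[chg + 1L], abs(dg[chg]))
  up <- rep(dg[chg] > 0L, abs(dg[chg]))
  lab_up <- if (slab$cytosol == "lower") "cytosol_to_lumen" else "lumen_to_cytosol"
  lab_dn <- if (slab$cytosol == "lower") "lumen_to_cytosol" else "cytosol_to_lumen"
  data.frame(ion = rep(1L, length(frame)), frame = frame,
             direction_z = ifelse(up, "up", "down"),
             direction = ifelse(up, lab_up, lab_dn))
}

#' Summarize per-replica permeation counts
#'
#' Reports mean, standard deviation (n - 1 denominator), minimum,
#' maximum and median of per-replica event counts — the reporting style
#' of field-driven permeation tables (mean +/- SD, range, median).
#'
#' @param counts numeric vector of per-replica counts, or a data.frame
#'   with one column per direction (a `total` column of row sums is
#'   added).
#' @return data.frame with one row per column of `counts` and columns
#'   `mean`, `sd` (NA for a single replica), `min`, `max`, `median`,
#'   `n_replicas`.
#' @examples
#' summarize_flux(c(0, 4, 30, 31, 100))  # mean 33, median 30
#' @export
summarize_flux <- function(counts) {
  if (is.data.frame(counts)) {
    counts$total <- rowSums(counts)
    out <- do.call(rbind, lapply(names(counts), function(nm) {
      s <- summarize_flux(counts[[nm]])
      s$condition <- nm
      s
    }))
    return(out[, c("condition", setdiff(names(out), "condition"))])
  }
  stopifnot(is.numeric(counts), length(counts) >= 1L)
  n <- length(counts)
  data.frame(mean = mean(counts),
             sd = if (n > 1L) sd(counts) else NA_real_,
             min = min(counts), max = max(counts),
             median = median(counts), n_replicas = n)
}

#' Convert an applied electric field to a transmembrane voltage
#'
#' A uniform field E (kcal mol^-1 A^-1 e^-1) across a box of length L_z
#' corresponds to a potential difference E * L_z expressed in
#' kcal mol^-1 e^-1, i.e. `E * L_z * 4184 / F` volts (~0.0433641 V per
#' kcal mol^-1 e^-1).  A field of 0.180 kcal mol^-1 A^-1 e^-1 over a
#' ~128 A box is ~1 V.
#'
#' @param E field intensity (kcal mol^-1 A^-1 e^-1; sign preserved).
#' @param L_z box length along the field (angstrom, > 0).
#' @return voltage in volts.
#' @examples
#' field_to_voltage(0.180, 128.1)  # ~1.00 V
#' @export
field_to_voltage <- function(E, L_z) {
  stopifnot(is.numeric(E), L_z > 0)
  E * L_z * .KCALMOL_PER_E_IN_VOLT
}

#' Expected ion count from conductance, voltage and time
#'
#' Ohmic expectation N = G * dV * dt / (|z| * e): the number of charge
#' carriers a channel of conductance G passes at voltage dV during dt.
#' An 80 pS channel at 1 V passes ~250 monovalent ions in 500 ns.
#'
#' @param conductance_pS channel conductance (pS, > 0).
#' @param voltage transmembrane voltage (V, > 0).
#' @param time_ns observation interval (ns, > 0).
#' @param valence ion valence (non-zero integer).
#' @return list with `expected` (real) and `nearest` (nearest integer).
#' @examples
#' expected_crossings(80, 1, 500, 1)  # ~250 ions
#' @export
expected_crossings <- function(conductance_pS, voltage, time_ns, valence = 1L) {
  if (valence == 0) stop("valence must be non-zero")
  stopifnot(conductance_pS > 0, voltage > 0, time_ns > 0)
  n <- conductance_pS * 1e-12 * voltage * time_ns * 1e-9 /
    (abs(valence) * .ECHARGE)
  list(expected = n, nearest = as.integer(round(n)))
}
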