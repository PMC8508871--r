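#' Analytic 1D free-energy landscape
#'
#' Defines a one-dimensional potential of mean force as a sum of Gaussian
#' terms plus a constant offset,
#' \deqn{U(\xi) = o + \sum_i A_i \exp\{-(\xi - c_i)^2 / (2 w_i^2)\},}
#' with amplitudes in kcal/mol (negative = well, positive = barrier),
#' centers and widths in angstrom.  Such landscapes serve as exactly known
#' ground truth for the umbrella-sampling / WHAM recovery pipeline.
#'
#' @param amplitudes numeric vector of term amplitudes (kcal/mol).
#' @param centers numeric vector of term centers (angstrom).
#' @param widths numeric vector of Gaussian widths (angstrom), all > 0.
#' @param offset constant energy offset (kcal/mol).
#' @return an object of class `potential_spec`.
#' @examples
#' # a barrier at 4 A and a well at 7 A
#' spec <- potential_spec(c(3, -1.5), c(4, 7), c(1, 1))
#' eval_potential(spec, c(4, 7))$energy
#' @seealso [eval_potential()], [simulate_overdamped()]
#' @export
potential_spec <- function(amplitudes = numeric(), centers = numeric(),
                           widths = numeric(), offset = 0) {
  amplitudes <- as.numeric(amplitudes)
  centers <- as.numeric(centers)
  widths <- as.numeric(widths)
  if (length(amplitudes) != length(centers) || length(centers) != length(widths))
    stop("amplitudes, centers and widths must have equal length")
  if (length(widths) && any(!is.finite(widths) | widths <= 0))
    stop("Gaussian widths must be positive and finite")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
    stop("offset must be a single finite number")
  structure(list(amplitudes = amplitudes, centers = centers,
                 widths = widths, offset = offset),
            class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("potential_spec:", length(x$amplitudes), "Gaussian term(s), offset",
      x$offset, "kcal/mol\n")
  if (length(x$amplitudes))
    print(data.frame(amplitude = x$amplitudes, center = x$centers,
                     width = x$widths))
  invisible(x)
}

#' Evaluate a landscape and its exact gradient
#'
#' @param spec a [potential_spec()].
#' @param xi reaction-coordinate positions (angstrom); must be finite.
#' @return list with `energy` (kcal/mol) and `gradient`
#'   (kcal mol^-1 A^-1), each the length of `xi`.
#' @examples
#' spec <- potential_spec(2, 0, 1)
#' eval_potential(spec, 1)   # energy 2*exp(-0.5), gradient -2*exp(-0.5)
#' @export
eval_potential <- function(spec, xi) {
  stopifnot(inherits(spec, "potential_spec"))
  if (!is.numeric(xi) || any(!is.finite(xi)))
    stop("reaction coordinate must be finite numeric")
  energy <- rep(spec$offset, length(xi))
  gradient <- numeric(length(xi))
  for (i in seq_along(spec$amplitudes)) {
    d <- (xi - spec$centers[i]) / spec$widths[i]
    g <- spec$amplitudes[i] * exp(-0.5 * d * d)
    energy <- energy + g
    gradient <- gradient - g * d / spec$widths[i]
  }
  list(energy = energy, gradient = gradient)
}

## --- restraints -----------------------------------------------------------

new_bias <- function(kind, center, force_constant, radius) {
  if (!is.numeric(force_constant) || length(force_constant) != 1L ||
      force_constant < 0)
    stop("force_constant must be a single non-negative number")
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  structure(list(kind = kind, center = center,
                 force_constant = force_constant, radius = radius),
            class = "bias_spec")
}

#' Restraint (bias) potentials for biased sampling
#'
#' Three restraint shapes used in steered and umbrella simulations:
#' * `harmonic_bias()`: \eqn{W = k (\xi - \xi_0)^2 / 2} — the per-window
#'   umbrella restraint (the study design uses k = 10 kcal mol^-1 A^-2).
#' * `flat_bottom_bias()`: zero within `radius` of the center, harmonic in
#'   the excess distance outside — a containment restraint.
#' * `lower_bound_bias()`: zero beyond `floor` from the center, harmonic
#'   push-out inside — an exclusion restraint keeping particles away.
#'
#' @param center restraint center (angstrom).
#' @param force_constant k in kcal mol^-1 A^-2 (>= 0).
#' @param radius flat-bottom radius (angstrom).
#' @param floor minimum allowed distance from `center` (angstrom).
#' @return an object of class `bias_spec`.
#' @examples
#' bias_energy(harmonic_bias(0, 10), 1)      # 5
#' bias_energy(flat_bottom_bias(0, 10, 8), 7) # 0
#' @export
harmonic_bias <- function(center, force_constant) {
  new_bias("harmonic", center, force_constant, 0)
}

#' @rdname harmonic_bias
#' @export
flat_bottom_bias <- function(center, force_constant, radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius >= 0)
  new_bias("flat_bottom", center, force_constant, radius)
}

#' @rdname harmonic_bias
#' @export
lower_bound_bias <- function(center, force_constant, floor) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor >= 0)
  new_bias("lower_bound", center, force_constant, floor)
}

#' Restraint energy and gradient
#'
#' @param bias a `bias_spec`.
#' @param xi positions (angstrom).
#' @return numeric vector of energies (kcal/mol) or gradients
#'   (kcal mol^-1 A^-1).
#' @export
bias_energy <- function(bias, xi) {
  stopifnot(inherits(bias, "bias_spec"))
  d <- xi - bias$center
  k <- bias$force_constant
  switch(bias$kind,
    harmonic = 0.5 * k * d^2,
    flat_bottom = {
      ex <- pmax(abs(d) - bias$radius, 0)
      0.5 * k * ex^2
    },
    lower_bound = {
      de <- pmin(abs(d) - bias$radius, 0)
      0.5 * k * de^2
    })
}

#' @rdname bias_energy
#' @export
bias_gradient <- function(bias, xi) {
  stopifnot(inherits(bias, "bias_spec"))
  d <- xi - bias$center
  k <- bias$force_constant
  s <- sign(d)
  switch(bias$kind,
    harmonic = k * d,
    flat_bottom = {
      ex <- pmax(abs(d) - bias$radius, 0)
      k * ex * s
    },
    lower_bound = {
      de <- pmin(abs(d) - bias$radius, 0)
      k * de * s
    })
}

## matrix encoding handed to the C++ integrator
bias_matrix <- function(biases) {
  if (!length(biases)) return(matrix(numeric(), 0, 4))
  if (inherits(biases, "bias_spec")) biases <- list(biases)
  kinds <- c(harmonic = 0, flat_bottom = 1, lower_bound = 2)
  do.call(rbind, lapply(biases, function(b) {
    stopifnot(inherits(b, "bias_spec"))
    c(kinds[[b$kind]], b$center, b$force_constant, b$radius)
  }))
}
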