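#' Default first-shell ion-oxygen cutoffs
#'
#' First minima of typical ion-water-oxygen radial distribution
#' functions: K+ 3.5 A, Na+ 3.2 A, Ca2+ 3.2 A.  Always configurable;
#' the cutoff used is recorded in every profile.
#'
#' @param species ion name (`"K"`, `"Na"`, `"Ca"`; case-insensitive,
#'   charge suffixes ignored).
#' @return cutoff in angstrom.
#' @export
shell_cutoff <- function(species) {
  key <- toupper(gsub("[^A-Za-z]", "", species))
  cuts <- c(K = 3.5, NA. = 3.2, CA = 3.2)
  names(cuts) <- c("K", "NA", "CA")
  if (!key %in% names(cuts))
    stop("no default cutoff for species '", species,
         "'; supply one explicitly")
  unname(cuts[[key]])
}

#' Count water oxygens in an ion's hydration shell
#'
#' Counts oxygens within `cutoff` of the ion, using minimum-image
#' distances when periodic `box` lengths are given.
#'
#' @param ion_xyz numeric length-3 ion position.
#' @param water_oxygens_xyz n x 3 matrix of oxygen positions.
#' @param cutoff shell cutoff (angstrom, > 0).
#' @param box optional periodic box lengths (length 3, or a scalar for a
#'   cubic box).
#' @return integer count.
#' @examples
#' snap <- make_hydration_snapshot(c(0, 0, 0), 4, 2.8, 10, 6.0, seed = 1)
#' count_shell(snap$ion, snap$oxygens, 3.5)  # 4
#' @export
count_shell <- function(ion_xyz, water_oxygens_xyz, cutoff, box = NULL) {
  stopifnot(length(ion_xyz) == 3L, cutoff > 0)
  ox <- matrix(as.numeric(water_oxygens_xyz), ncol = 3L)
  if (!nrow(ox)) return(0L)
  d <- sweep(ox, 2, as.numeric(ion_xyz))
  if (!is.null(box)) {
    if (length(box) == 1L) box <- rep(box, 3L)
    stopifnot(length(box) == 3L, all(box > 0))
    d <- sweep(d, 2, box, function(x, L) x - L * round(x / L))
  }
  sum(sqrt(rowSums(d^2)) <= cutoff)
}

#' Hydration-number profile along the permeation coordinate
#'
#' For each umbrella window, counts the first-shell oxygens per frame,
#' averages within contiguous blocks of `block_length` frames, and
#' reports the across-block mean and SEM (n - 1 denominator) — the same
#' block convention the WHAM error analysis uses.
#'
#' @param windows list of windows; each a list with `xi` (the window's
#'   coordinate position), and `frames`: a list of frames, each a list
#'   with `ion` (length-3) and `oxygens` (n x 3).
#' @param cutoff shell cutoff (angstrom), possibly from [shell_cutoff()].
#' @param block_length frames per block (>= 2).
#' @param box optional periodic box lengths passed to [count_shell()].
#' @return data.frame with `xi`, `mean_count`, `sem`, `n_blocks`,
#'   `cutoff`.
#' @export
hydration_profile <- function(windows, cutoff, block_length, box = NULL) {
  stopifnot(length(windows) >= 1L, cutoff > 0, block_length >= 2L)
  rows <- lapply(windows, function(w) {
    if (!length(w$frames)) stop("empty window at xi = ", w$xi)
    counts <- vapply(w$frames, function(fr)
      count_shell(fr$ion, fr$oxygens, cutoff, box), numeric(1))
    n_blocks <- length(counts) %/% block_length
    if (n_blocks < 1L)
      stop("window at xi = ", w$xi, " is shorter than one block")
    bm <- vapply(seq_len(n_blocks), function(b)
      mean(counts[seq.int((b - 1L) * block_length + 1L, b * block_length)]),
      numeric(1))
    data.frame(xi = w$xi, mean_count = mean(bm),
               sem = if (n_blocks > 1L) sd(bm) / sqrt(n_blocks) else NA_real_,
               n_blocks = n_blocks, cutoff = cutoff)
  })
  do.call(rbind, rows)
}
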