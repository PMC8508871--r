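#' Write a reaction-coordinate series as annotated text
#'
#' One `#`-prefixed header line carrying the column names, units, the
#' step-to-nanosecond factor and the seed, then one row per frame —
#' enough metadata for downstream block splitting to reconstruct
#' "per-nanosecond" units.
#'
#' @param xi numeric series (angstrom).
#' @param file output path.
#' @param step_ns nanoseconds per step (defaults to the series'
#'   `timestep` attribute, else NA).
#' @param seed seed used to generate the series (defaults to the `seed`
#'   attribute).
#' @return invisibly, `file`.
#' @export
write_trajectory <- function(xi, file, step_ns = attr(xi, "timestep"),
                             seed = attr(xi, "seed")) {
  header <- sprintf("# columns=step,xi units=index,angstrom step_ns=%s seed=%s",
                    if (is.null(step_ns)) "NA" else format(step_ns),
                    if (is.null(seed)) "NA" else format(seed))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(data.frame(step = seq_along(xi) - 1L, xi = as.numeric(xi)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a reaction-coordinate series written by [write_trajectory()]
#'
#' @param file input path.
#' @return numeric series with `timestep` and `seed` attributes.
#' @export
read_trajectory <- function(file) {
  header <- readLines(file, n = 1L)
  if (!startsWith(header, "#"))
    stop("not a trajectory file: missing header line")
  get_field <- function(key) {
    m <- regmatches(header, regexpr(paste0(key, "=[^ ]+"), header))
    if (!length(m)) return(NULL)
    v <- sub(paste0(key, "="), "", m)
    if (v == "NA") NULL else as.numeric(v)
  }
  d <- read.table(file, comment.char = "#")
  xi <- d[[2]]
  attr(xi, "timestep") <- get_field("step_ns")
  attr(xi, "seed") <- get_field("seed")
  xi
}

#' Read a window manifest and assemble umbrella windows
#'
#' The manifest is a CSV with columns `center`, `force_constant`, `path`
#' (series files relative to the manifest's directory), and optional
#' `n_discard` and `block_length` columns applied to every window.
#'
#' @param manifest path to the CSV manifest.
#' @param n_discard,block_length defaults when the manifest lacks the
#'   columns.
#' @return list of [umbrella_window()] objects.
#' @export
read_window_manifest <- function(manifest, n_discard = 0L,
                                 block_length = NULL) {
  m <- read.table(manifest, header = TRUE, sep = ",",
                  stringsAsFactors = FALSE)
  stopifnot(all(c("center", "force_constant", "path") %in% names(m)))
  base <- dirname(manifest)
  lapply(seq_len(nrow(m)), function(i) {
    xi <- read_trajectory(file.path(base, m$path[i]))
    umbrella_window(m$center[i], m$force_constant[i], xi,
                    n_discard = if ("n_discard" %in% names(m))
                      m$n_discard[i] else n_discard,
                    block_length = if ("block_length" %in% names(m))
                      m$block_length[i] else block_length)
  })
}
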