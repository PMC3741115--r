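#' Construct a concentration field
#'
#' A `da_field` is a 3-D array of extracellular dopamine concentrations (nM,
#' referred to extracellular fluid) with its grid geometry and the simulated
#' time attached.
#'
#' @param values 3-D numeric array (or a scalar recycled over the grid).
#' @param grid A [grid_spec()].
#' @param time Simulated time in seconds.
#' @return A `da_field` object.
#' @examples
#' f <- da_field(0, grid_spec(16))
#' volume_stats(f)
#' @export
da_field <- function(values = 0, grid = grid_spec(), time = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1) values <- array(values, dim = grid$shape)
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("`values` dimensions do not match the grid", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(values, grid = grid, time = time, class = "da_field")
}

new_da_field <- function(values, grid, time) {
  # internal fast path: trusts the engine's output
  structure(values, grid = grid, time = time, class = "da_field")
}

#' @export
print.da_field <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<da_field> %d x %d x %d voxels at t = %g s\n",
              g$shape[1], g$shape[2], g$shape[3], attr(x, "time")))
  v <- volume_stats(x)
  cat(sprintf("  mean %.3g nM, sd %.3g, range [%.3g, %.3g]\n",
              v$mean, v$sd, v$min, v$max))
  invisible(x)
}

#' @export
`[.da_field` <- function(x, ...) {
  y <- NextMethod()
  y
}

field_grid <- function(field) attr(field, "grid")
field_time <- function(field) attr(field, "time")

#' Tidy a concentration field into a long tibble
#'
#' @param x A `da_field`.
#' @param ... Unused.
#' @return A tibble with voxel indices `x`, `y`, `z` (1-based), the physical
#'   centre coordinates in um, and `conc_nM`.
#' @method tidy da_field
#' @export
tidy.da_field <- function(x, ...) {
  g <- attr(x, "grid")
  idx <- expand_grid_indices(g)
  idx$conc_nM <- as.vector(unclass(x))
  idx
}

expand_grid_indices <- function(g) {
  sh <- g$shape
  tibble::tibble(
    x = rep.int(seq_len(sh[1]), sh[2] * sh[3]),
    y = rep.int(rep(seq_len(sh[2]), each = sh[1]), sh[3]),
    z = rep(seq_len(sh[3]), each = sh[1] * sh[2]))
}

# 1-based voxel (x, y, z) -> 0-based linear index, column-major
voxel_linear_index0 <- function(x, y, z, shape) {
  (x - 1L) + shape[1] * ((y - 1L) + shape[2] * (z - 1L))
}
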