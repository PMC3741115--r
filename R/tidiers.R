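#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into its scalar traces
#'
#' @param x A `da_trajectory`.
#' @param ... Unused.
#' @return The per-step traces tibble (`step`, `time`, `mean_nM`,
#'   `injected_mol`, `uptaken_mol`).
#' @method tidy da_trajectory
#' @export
tidy.da_trajectory <- function(x, ...) x$traces

#' One-row summary of a trajectory
#'
#' @param x A `da_trajectory`.
#' @param ... Unused.
#' @return A tibble with the simulated interval, site count, event count,
#'   final volume mean and the mass-ledger closure error.
#' @method glance da_trajectory
#' @export
glance.da_trajectory <- function(x, ...) {
  tibble::tibble(
    t0 = x$t0, t_end = x$t_end, n_sites = nrow(x$sites),
    n_events = if (is.null(x$events)) NA_integer_ else nrow(x$events),
    final_mean_nM = mean(as.numeric(x$final)),
    injected_mol = x$ledger$injected_mol,
    uptaken_mol = x$ledger$uptaken_mol,
    ledger_rel_error = x$ledger$rel_error)
}

#' Tidy a difference map into a long tibble
#'
#' @param x A `da_diff` from [difference_map()].
#' @param ... Unused.
#' @return A tibble: `x`, `y`, `z`, `abs_nM`, `rel_pct` (NA where the
#'   baseline was below the threshold).
#' @method tidy da_diff
#' @export
tidy.da_diff <- function(x, ...) {
  g <- attr(x$abs, "grid")
  idx <- expand_grid_indices(g)
  idx$abs_nM <- as.vector(unclass(x$abs))
  idx$rel_pct <- as.vector(unclass(x$rel))
  idx
}

#' Tidy an occupancy field
#'
#' @param x A `da_occupancy` from [receptor_occupancy()].
#' @param ... Unused.
#' @return A tibble: `x`, `y`, `z`, `occupancy`.
#' @method tidy da_occupancy
#' @export
tidy.da_occupancy <- function(x, ...) {
  g <- attr(x, "grid")
  idx <- expand_grid_indices(g)
  idx$occupancy <- as.vector(unclass(x))
  idx
}
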