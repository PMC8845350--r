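#' Clone-detection p-value for a hypothetical experiment
#'
#' The sgRNA-overlap p-value expected between two cells of the same clone,
#' as a function of library size `M` and guides per cell `k`, assuming clonal
#' cells share a fraction `r` of their detected guides. The assumed overlap is
#' `round(r * k)` (round-half-to-even) and both cells are assumed to carry
#' `k` guides, so the value is
#' `overlap_log10_pvalue(round(r * k), M, k, k)`.
#'
#' @param M Library size(s).
#' @param k Guides detected per cell.
#' @param r Assumed shared fraction in `[0, 1]` (default 0.75).
#' @return log10 p-value (vectorized over `M` and `k`).
#' @export
power_log10_pvalue <- function(M, k, r = 0.75) {
  if (any(r < 0) || any(r > 1)) stop("r must be in [0, 1]")
  if (any(k < 1) || any(k > M)) stop("need 1 <= k <= M")
  overlap_log10_pvalue(round(r * k), M, k, k)
}

#' Power surface over library size and guides per cell
#'
#' Evaluates [power_log10_pvalue()] on a grid. Along both axes the surface is
#' non-increasing wherever the assumed overlap count `round(r * k)` advances
#' between consecutive k values; on a unit-step k axis small plateaus (where
#' the rounded overlap does not advance) can tick upward, so k axes with
#' steps of at least `1 / r` are recommended for a strictly monotone display.
#'
#' @param M_values,k_values Grid axes (library sizes, guides per cell).
#' @param r Assumed shared fraction.
#' @return `power_grid`: list with `M_values`, `k_values`, `r` and `log10_p`
#'   (matrix, rows = library sizes, columns = guides per cell).
#' @export
power_grid <- function(M_values, k_values, r = 0.75) {
  if (!length(M_values) || !length(k_values)) stop("empty grid axis")
  lp <- outer(M_values, k_values,
              function(M, k) power_log10_pvalue(M, k, r = r))
  dimnames(lp) <- list(M = format(M_values, trim = TRUE, scientific = FALSE),
                       k = format(k_values, trim = TRUE))
  structure(list(M_values = M_values, k_values = k_values, r = r,
                 log10_p = lp),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("power_grid: %d library sizes x %d guides/cell, r = %g\n",
              length(x$M_values), length(x$k_values), x$r))
  cat(sprintf("  log10 p range [%.1f, %.1f]\n",
              min(x$log10_p), max(x$log10_p)))
  invisible(x)
}

#' @export
as.data.frame.power_grid <- function(x, ...) {
  data.frame(
    M = rep(x$M_values, times = length(x$k_values)),
    k = rep(x$k_values, each = length(x$M_values)),
    r = x$r,
    log10_p = as.vector(x$log10_p)
  )
}

#' Heatmap of a power grid
#'
#' Library size against guides per cell, colored by log10 p-value. Values are
#' clipped at `clip` for display only; the stored grid is unclipped.
#'
#' @param grid A [power_grid()].
#' @param clip Display clip for log10 p (default -100).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `grid`.
#' @export
plot_power_grid <- function(grid, clip = -100, ...) {
  z <- pmax(grid$log10_p, clip)
  graphics::image(x = seq_along(grid$M_values), y = seq_along(grid$k_values),
                  z = z, axes = FALSE,
                  xlab = "sgRNA library size", ylab = "sgRNAs per cell",
                  main = sprintf("log10 p of clonal sgRNA overlap (r = %g)",
                                 grid$r), ...)
  graphics::axis(1, at = seq_along(grid$M_values),
                 labels = rownames(grid$log10_p))
  graphics::axis(2, at = seq_along(grid$k_values),
                 labels = colnames(grid$log10_p))
  graphics::box()
  invisible(grid)
}
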