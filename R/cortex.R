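# Visual cortex: a rectangular grid of frequency x orientation tuned units.
# A stimulus activates the unit tuned to it maximally and its neighbors
# through a Gaussian receptive field measured in grid-index units.

#' Construct a cortical grid
#'
#' Units tile the normalized stimulus space uniformly; rows index spatial
#' frequency and columns orientation. Each unit's receptive field is a
#' Gaussian of height `height` (activation of the unit tuned exactly to the
#' stimulus) and spread `spread` measured in grid-index units, so a spread
#' of 0.8 confines appreciable activation to a roughly one-unit
#' neighborhood regardless of grid resolution.
#'
#' @param n_rows,n_cols Grid dimensions (default 20 x 20 = 400 units).
#' @param height Peak activation (default 600).
#' @param spread Receptive-field SD in index units (default 0.8).
#' @param space Range of the normalized stimulus space (both dimensions).
#' @return An object of class `cortical_grid`.
#' @export
cortical_grid <- function(n_rows = .striat$cortex$n_rows,
                          n_cols = .striat$cortex$n_cols,
                          height = .striat$cortex$height,
                          spread = .striat$cortex$spread,
                          space = .striat$cortex$space) {
  stopifnot(n_rows >= 1, n_cols >= 1, height > 0, spread > 0,
            length(space) == 2, space[2] > space[1])
  row_centers <- space[1] + (seq_len(n_rows) - 0.5) * diff(space) / n_rows
  col_centers <- space[1] + (seq_len(n_cols) - 0.5) * diff(space) / n_cols
  structure(list(n_rows = n_rows, n_cols = n_cols, height = height,
                 spread = spread, space = space,
                 row_centers = row_centers, col_centers = col_centers),
            class = "cortical_grid")
}

# Index (1-based) of the grid cell nearest a coordinate.
nearest_index <- function(x, space, n) {
  i <- floor((x - space[1]) / diff(space) * n) + 1
  min(max(i, 1), n)
}

#' Cortical activation for one stimulus
#'
#' Returns the input activations `I_K` over the grid:
#' `I_K = height * exp(-d_K^2 / (2 * spread^2))` where `d_K` is the
#' Euclidean grid-index distance from unit `K` to the unit tuned nearest to
#' the stimulus. Stimuli outside the normalized space are clipped to the
#' boundary with a warning.
#'
#' @param grid A `cortical_grid`.
#' @param stimulus Numeric (frequency, orientation) or a one-row data frame
#'   with `frequency`/`orientation` columns.
#' @return Numeric vector of length `n_rows * n_cols` (column-major over
#'   rows = frequency, cols = orientation), with attribute `peak_unit`.
#' @examples
#' g <- cortical_grid()
#' I <- activate(g, c(50, 50))
#' max(I)  # 600 at the best-matching unit
#' @export
activate <- function(grid, stimulus) {
  stopifnot(inherits(grid, "cortical_grid"))
  if (is.data.frame(stimulus))
    stimulus <- c(stimulus$frequency[1], stimulus$orientation[1])
  stimulus <- as.numeric(stimulus)
  stopifnot(length(stimulus) == 2)
  sp <- grid$space
  if (any(stimulus < sp[1]) || any(stimulus > sp[2])) {
    warning("stimulus outside the normalized space; clipped to boundary")
    stimulus <- pmin(pmax(stimulus, sp[1]), sp[2])
  }
  r0 <- nearest_index(stimulus[1], sp, grid$n_rows)
  c0 <- nearest_index(stimulus[2], sp, grid$n_cols)
  dr2 <- (seq_len(grid$n_rows) - r0)^2
  dc2 <- (seq_len(grid$n_cols) - c0)^2
  I <- grid$height * exp(-outer(dr2, dc2, "+") / (2 * grid$spread^2))
  out <- as.numeric(I)
  attr(out, "peak_unit") <- (c0 - 1) * grid$n_rows + r0
  out
}
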