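#' Miniature test geometry
#'
#' A scaled-down cell for fast tests and examples: 12x12 px mitochondria
#' (a 3x3 lattice with 6 px vertical and 12 px horizontal gaps, 6 px
#' margin, 72x60 px grid), with the same layout family variants as the
#' full-size cell. The irregular/gradient variants place 9 mitochondria
#' on the same grid; the low-density variant is a 2x2 lattice on the same
#' grid; the moving variant oscillates the outer ring with amplitude 6 px.
#'
#' @param layout one of `"regular"`, `"irregular"`, `"low_density"`,
#'   `"moving"`, `"gradient"`.
#' @param seed placement seed for the randomized variants.
#' @return a `cell_geometry`.
#' @export
make_mini_geometry <- function(layout = c("regular", "irregular",
                                          "low_density", "moving",
                                          "gradient"),
                               seed = 1) {
  layout <- match.arg(layout)
  reg <- make_regular_layout(rows = 3, cols = 3, mito_side = 12,
                             vgap = 6, hgap = 12, margin = 6)
  switch(layout,
         regular = reg,
         low_density = make_low_density_layout(rows = 2, cols = 2,
                                               reference = reg),
         irregular = make_irregular_layout(n = 9, seed = seed,
                                           grid_width = reg$grid_width,
                                           grid_height = reg$grid_height,
                                           mito_side = 12),
         gradient = make_gradient_layout(n = 9, seed = seed,
                                         grid_width = reg$grid_width,
                                         grid_height = reg$grid_height,
                                         mito_side = 12),
         moving = make_moving_layout(amplitude = 6, speed = 1, rows = 3,
                                     cols = 3, mito_side = 12, vgap = 6,
                                     hgap = 12, margin = 6))
}

# A mini mitochondrion (12x12 = 144 px) holds 144/2916 as many agents as
# a full-size one (54x54) at equal ROS density, so the raw-count reactive
# threshold is divided by 2916/144 = 20.25.
MINI_AREA_RATIO <- (54 * 54) / (12 * 12)

#' Geometrically scaled study setting
#'
#' Shrinks the canonical cell by an integer factor while preserving
#' geometric similarity: mitochondrion side, gaps, margin and injection
#' square divide by `factor`; diffusion speeds divide by `factor` so a
#' messenger's diffusive reach keeps the same proportion to the cell
#' size and to inter-mitochondrial distances, and a traversal takes the
#' same number of steps as at full scale; the raw-count reactive
#' threshold divides by `factor^2` (equal O2- density); per-step rates
#' (decay, respiration per pixel, reaction probabilities) are
#' scale-free and stay untouched. With `factor = 3` (the default) the
#' 9x9 cell becomes 324 x 228 px with 18 px mitochondria, running about
#' two orders of magnitude faster than full scale — the setting used for
#' the network-dependence analyses in the package's test suite.
#'
#' Doses are agent counts and should be chosen per setting; a full-scale
#' dose D corresponds to `D / factor^2` at equal H2O2 density.
#'
#' @param layout layout family (as [make_mini_geometry()]).
#' @param factor integer linear shrink factor; 54 must be divisible by
#'   `factor` and 18, 54, 27 must divide evenly (factor in 1, 3).
#' @param seed placement seed for randomized layouts.
#' @param ... [sim_params()] overrides applied after scaling.
#' @return list with `params` and `geometry`.
#' @export
make_scaled_setting <- function(layout = "regular", factor = 3, seed = 1,
                                ...) {
  side <- 54 / factor
  vgap <- 18 / factor
  hgap <- 54 / factor
  margin <- 27 / factor
  if (any(c(side, vgap, hgap, margin) != floor(c(side, vgap, hgap, margin))))
    stop("factor must divide 54, 18 and 27 evenly")
  reg <- make_regular_layout(rows = 9, cols = 9, mito_side = side,
                             vgap = vgap, hgap = hgap, margin = margin)
  geometry <- switch(match.arg(layout, c("regular", "irregular",
                                         "low_density", "moving",
                                         "gradient")),
    regular = reg,
    low_density = make_low_density_layout(rows = 5, cols = 5,
                                          reference = reg),
    irregular = make_irregular_layout(n = 81, seed = seed,
                                      grid_width = reg$grid_width,
                                      grid_height = reg$grid_height,
                                      mito_side = side),
    gradient = make_gradient_layout(n = 81, seed = seed,
                                    grid_width = reg$grid_width,
                                    grid_height = reg$grid_height,
                                    mito_side = side),
    moving = make_moving_layout(amplitude = vgap, speed = 1, rows = 9,
                                cols = 9, mito_side = side, vgap = vgap,
                                hgap = hgap, margin = margin))
  params <- sim_params(
    speed = c(O2minus = 11.66, H2O2 = 11.31, enzyme = 1.414) / factor,
    reactive_threshold = 50 / factor^2,
    injection_side = 108 / factor,
    ...)
  list(params = params, geometry = geometry)
}

#' Miniature simulation fixture
#'
#' A complete fast-running configuration: the [make_mini_geometry()]
#' regular cell, 200 steps, 2 replicates, a 300-agent H2O2 dose in a
#' 24 px injection square, default enzyme percent concentrations, and the
#' reactive threshold rescaled by mitochondrial area (50 * 144/2916 =
#' 2.469) so a mini mitochondrion is classified reactive at the same
#' internal O2- *density* as a full-size one, and diffusion speeds
#' rescaled by the linear ratio 12/54 (see [make_scaled_setting()]).
#' The leakage rule needs no rescaling: its engine default already
#' works in percent of mitochondrion area.
#'
#' @param ... overrides forwarded to [update_params()].
#' @return list with elements `params` and `geometry`.
#' @export
#' @examples
#' fx <- make_mini_fixture()
#' res <- run_replicates(fx$params, fx$geometry)
make_mini_fixture <- function(...) {
  base <- sim_params(initial_h2o2 = 300,
                     injection_side = 24,
                     n_steps = 200,
                     n_replicates = 2,
                     reactive_threshold = 50 / MINI_AREA_RATIO,
                     # geometric similarity: speeds shrink with the cell
                     # (12/54 of full scale) so diffusive reach keeps its
                     # proportion to cell size
                     speed = c(O2minus = 11.66, H2O2 = 11.31,
                               enzyme = 1.414) * (12 / 54))
  params <- if (...length() > 0) update_params(base, ...) else base
  list(params = params, geometry = make_mini_geometry("regular"))
}
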