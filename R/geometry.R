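#' Cell geometry constructor
#'
#' Builds the immutable description of a 2D cell: its pixel grid and the
#' set of axis-aligned square mitochondria it contains. Coordinates are
#' continuous with the origin at the top-left; a rectangle occupies the
#' half-open region `[x, x+w) x [y, y+h)`.
#'
#' @param layout_name one of `"regular"`, `"irregular"`, `"low_density"`,
#'   `"moving"`, `"gradient"`.
#' @param grid_width,grid_height grid dimensions in pixels.
#' @param mito data.frame with columns `id, x, y, w, h, amp, speed, y0`;
#'   `amp`/`speed` describe a vertical triangle-wave motion (0 = static),
#'   `y0` is the rest y position the wave is applied to.
#' @param margin margin (pixels) used when the layout was constructed.
#' @return an object of class `cell_geometry`.
#' @keywords internal
new_cell_geometry <- function(layout_name, grid_width, grid_height, mito,
                              margin = 0) {
  stopifnot(grid_width > 0, grid_height > 0)
  mito <- as.data.frame(mito)
  needed <- c("id", "x", "y", "w", "h", "amp", "speed", "y0")
  stopifnot(all(needed %in% names(mito)))
  mito <- mito[order(mito$id), needed, drop = FALSE]
  rownames(mito) <- NULL
  if (nrow(mito) > 0) {
    if (any(mito$w <= 0 | mito$h <= 0))
      stop("mitochondrion rectangles must have positive size")
    if (any(mito$x < 0 | mito$y < 0 |
            mito$x + mito$w > grid_width | mito$y + mito$h > grid_height))
      stop("mitochondrion rectangles must lie inside the grid")
    if (any_rect_overlap(mito))
      stop("mitochondrion rectangles overlap")
  }
  g <- structure(list(layout_name = layout_name,
                      grid_width = grid_width, grid_height = grid_height,
                      mito = mito, margin = margin, comp_grid = NULL),
                 class = "cell_geometry")
  g$comp_grid <- build_comp_grid(g)
  g
}

# Pixel-resolution compartment lookup table (integer vector of length
# W*H, 0 = cytosol). Exact only when every rect corner lies on the integer
# pixel raster — which all built-in layouts guarantee; otherwise NULL and
# compartment queries fall back to the per-rectangle scan.
build_comp_grid <- function(g) {
  m <- g$mito
  coords <- c(m$x, m$y, m$w, m$h, g$grid_width, g$grid_height)
  if (length(coords) > 0 && any(coords != floor(coords))) return(NULL)
  if (g$grid_width != floor(g$grid_width) ||
      g$grid_height != floor(g$grid_height)) return(NULL)
  W <- as.integer(g$grid_width)
  vec <- integer(W * as.integer(g$grid_height))
  for (i in seq_len(nrow(m))) {
    xs <- m$x[i]:(m$x[i] + m$w[i] - 1L)
    ys <- m$y[i]:(m$y[i] + m$h[i] - 1L)
    vec[rep(xs, times = length(ys)) + W * rep(ys, each = length(xs)) + 1L] <-
      m$id[i]
  }
  vec
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("cell_geometry: %s layout, %d x %d px, %d mitochondria\n",
              x$layout_name, x$grid_width, x$grid_height, nrow(x$mito)))
  invisible(x)
}

# TRUE if any two rectangles overlap with positive area (touching edges are
# allowed: rectangles are half-open so a shared edge is not shared pixels).
any_rect_overlap <- function(mito) {
  n <- nrow(mito)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    ox <- mito$x[i] < mito$x[j] + mito$w[j] & mito$x[j] < mito$x[i] + mito$w[i]
    oy <- mito$y[i] < mito$y[j] + mito$h[j] & mito$y[j] < mito$y[i] + mito$h[i]
    if (any(ox & oy)) return(TRUE)
  }
  FALSE
}

static_mito_df <- function(x, y, side) {
  n <- length(x)
  data.frame(id = seq_len(n), x = x, y = y, w = rep(side, n),
             h = rep(side, n), amp = rep(0, n), speed = rep(0, n), y0 = y)
}

#' Regular (cardiomyocyte-like) mitochondrial lattice
#'
#' Places `rows x cols` square mitochondria on a rectangular lattice with
#' fixed gaps, the geometry typical of cardiomyocytes. With the defaults
#' (54 px mitochondria, 18 px vertical and 54 px horizontal gaps, 27 px
#' margin) the 9x9 lattice spans a 972 x 684 px cell holding 81
#' mitochondria.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @param mito_side side length of each square mitochondrion, pixels.
#' @param vgap,hgap vertical / horizontal gap between mitochondria, pixels.
#' @param margin margin on all four sides, pixels.
#' @return a [new_cell_geometry()] object with `layout_name = "regular"`.
#' @export
#' @examples
#' g <- make_regular_layout()
#' nrow(g$mito)       # 81
#' g$grid_width       # 972
make_regular_layout <- function(rows = 9, cols = 9, mito_side = 54,
                                vgap = 18, hgap = 54, margin = 27) {
  if (mito_side <= 0) stop("mito_side must be positive")
  stopifnot(rows >= 1, cols >= 1, vgap >= 0, hgap >= 0, margin >= 0)
  gw <- cols * mito_side + (cols - 1) * hgap + 2 * margin
  gh <- rows * mito_side + (rows - 1) * vgap + 2 * margin
  xs <- margin + (rep(seq_len(cols), times = rows) - 1) * (mito_side + hgap)
  ys <- margin + (rep(seq_len(rows), each = cols) - 1) * (mito_side + vgap)
  new_cell_geometry("regular", gw, gh, static_mito_df(xs, ys, mito_side),
                    margin)
}

#' Low-density regular layout
#'
#' A 5x5 regular lattice occupying the SAME cell dimensions as the default
#' 9x9 layout: the mitochondrial count drops from 81 to 25 while spacing is
#' rescaled so the lattice still fills the cell uniformly. This models a
#' reduction in cytosolic mitochondrial density, not a smaller cell.
#'
#' @param rows,cols lattice dimensions of the sparse lattice.
#' @param reference geometry whose grid dimensions, mitochondrion size and
#'   margin are reused; defaults to `make_regular_layout()`.
#' @return a `cell_geometry` with `layout_name = "low_density"`.
#' @export
make_low_density_layout <- function(rows = 5, cols = 5,
                                    reference = make_regular_layout()) {
  side <- reference$mito$w[1]
  margin <- reference$margin
  gw <- reference$grid_width
  gh <- reference$grid_height
  hgap <- if (cols > 1) (gw - 2 * margin - cols * side) / (cols - 1) else 0
  vgap <- if (rows > 1) (gh - 2 * margin - rows * side) / (rows - 1) else 0
  if (hgap < 0 || vgap < 0) stop("sparse lattice does not fit the reference grid")
  xs <- margin + (rep(seq_len(cols), times = rows) - 1) * (side + hgap)
  ys <- margin + (rep(seq_len(rows), each = cols) - 1) * (side + vgap)
  g <- new_cell_geometry("low_density", gw, gh, static_mito_df(xs, ys, side),
                         margin)
  g
}

#' Irregular (random) mitochondrial layout
#'
#' Scatters `n` non-overlapping square mitochondria uniformly over the grid
#' interior by seeded rejection sampling, modeling a random cytosolic
#' distribution of mitochondria. The same seed always reproduces the same
#' layout.
#'
#' @param n number of mitochondria.
#' @param seed RNG seed for the placement.
#' @param grid_width,grid_height cell dimensions (default: the 9x9 cell).
#' @param mito_side mitochondrion side, pixels.
#' @param max_attempts total rejection-sampling attempts before giving up.
#' @return a `cell_geometry` with `layout_name = "irregular"`.
#' @export
make_irregular_layout <- function(n = 81, seed = 1,
                                  grid_width = 972, grid_height = 684,
                                  mito_side = 54, max_attempts = 1e5) {
  if (mito_side <= 0) stop("mito_side must be positive")
  stopifnot(n >= 0)
  set.seed(seed)
  placed <- place_random_rects(n, mito_side, grid_width, grid_height,
                               max_attempts, sampler = function(k) {
    cbind(stats::runif(k, 0, grid_width - mito_side),
          stats::runif(k, 0, grid_height - mito_side))
  })
  new_cell_geometry("irregular", grid_width, grid_height,
                    static_mito_df(placed[, 1], placed[, 2], mito_side))
}

#' Gradient (center-clustered) mitochondrial layout
#'
#' Mitochondrial positions are drawn from an isotropic Gaussian centered on
#' the cell center (default spread `sigma = grid_width / 6`), truncated to
#' the interior and thinned to avoid overlap. This emulates perinuclear
#' clustering of mitochondria.
#'
#' @inheritParams make_irregular_layout
#' @param sigma standard deviation of the placement Gaussian, pixels.
#' @return a `cell_geometry` with `layout_name = "gradient"`.
#' @export
make_gradient_layout <- function(n = 81, sigma = NULL, seed = 1,
                                 grid_width = 972, grid_height = 684,
                                 mito_side = 54, max_attempts = 1e5) {
  if (mito_side <= 0) stop("mito_side must be positive")
  stopifnot(n >= 0)
  if (is.null(sigma)) sigma <- grid_width / 6
  set.seed(seed)
  cx <- grid_width / 2
  cy <- grid_height / 2
  placed <- place_random_rects(n, mito_side, grid_width, grid_height,
                               max_attempts, sampler = function(k) {
    cbind(stats::rnorm(k, cx, sigma) - mito_side / 2,
          stats::rnorm(k, cy, sigma) - mito_side / 2)
  })
  new_cell_geometry("gradient", grid_width, grid_height,
                    static_mito_df(placed[, 1], placed[, 2], mito_side))
}

# Shared rejection-sampling core: draws candidate top-left corners from
# `sampler`, keeps those inside the grid and not overlapping anything
# already placed. Errors if max_attempts draws are exhausted.
place_random_rects <- function(n, side, gw, gh, max_attempts, sampler) {
  xs <- numeric(0)
  ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n) {
    if (attempts >= max_attempts)
      stop(sprintf("could not place %d rectangles in %d attempts (capacity)",
                   n, max_attempts))
    cand <- sampler(1L)
    attempts <- attempts + 1L
    # snap to the integer pixel raster so rectangles align with pixels
    x <- floor(cand[1, 1]); y <- floor(cand[1, 2])
    if (x < 0 || y < 0 || x + side > gw || y + side > gh) next
    if (length(xs) > 0) {
      hit <- x < xs + side & xs < x + side & y < ys + side & ys < y + side
      if (any(hit)) next
    }
    xs <- c(xs, x)
    ys <- c(ys, y)
  }
  cbind(xs, ys)
}

#' Rapidly-moving mitochondria layout
#'
#' The 9x9 regular lattice in which the outer ring of 32 peripheral
#' mitochondria oscillates vertically as a triangle wave (default amplitude
#' 18 px — one inter-mitochondrial gap, so neighbors are never entered —
#' at 1 px per step). Interior mitochondria are static.
#'
#' @param amplitude peak vertical excursion, pixels.
#' @param speed vertical speed, pixels per step.
#' @inheritParams make_regular_layout
#' @return a `cell_geometry` with `layout_name = "moving"`.
#' @export
make_moving_layout <- function(amplitude = 18, speed = 1, rows = 9, cols = 9,
                               mito_side = 54, vgap = 18, hgap = 54,
                               margin = 27) {
  stopifnot(amplitude >= 0, speed >= 0)
  if (amplitude > margin)
    stop("amplitude may not exceed the margin (mitochondria would exit the grid)")
  g <- make_regular_layout(rows, cols, mito_side, vgap, hgap, margin)
  row_i <- (g$mito$id - 1L) %/% cols + 1L
  col_i <- (g$mito$id - 1L) %% cols + 1L
  ring <- row_i == 1L | row_i == rows | col_i == 1L | col_i == cols
  g$mito$amp[ring] <- amplitude
  g$mito$speed[ring] <- speed
  g$layout_name <- "moving"
  g
}

# Triangle-wave vertical displacement at integer step t, starting at 0,
# rising to +amp, falling to -amp, period 4*amp/speed.
triangle_displacement <- function(t, amp, speed) {
  out <- numeric(length(amp))
  mv <- amp > 0 & speed > 0
  if (any(mv)) {
    u <- (speed[mv] * t) %% (4 * amp[mv])
    a <- amp[mv]
    out[mv] <- ifelse(u <= a, u, ifelse(u <= 3 * a, 2 * a - u, u - 4 * a))
  }
  out
}

#' Advance mitochondrial motion to a simulation step
#'
#' Returns the geometry with every moving mitochondrion displaced to its
#' triangle-wave position at step `t` (step 0 = rest). Static mitochondria
#' and rect sizes are untouched.
#'
#' @param geometry a `cell_geometry`.
#' @param t integer simulation step.
#' @return the displaced `cell_geometry`.
#' @export
advance_motion <- function(geometry, t) {
  if (nrow(geometry$mito) == 0 || all(geometry$mito$amp == 0))
    return(geometry)
  disp <- triangle_displacement(t, geometry$mito$amp, geometry$mito$speed)
  y_new <- geometry$mito$y0 + disp
  if (all(y_new == geometry$mito$y)) return(geometry)
  geometry$mito$y <- y_new
  geometry$comp_grid <- build_comp_grid(geometry)
  geometry
}

#' Compartment lookup for continuous points
#'
#' Maps each continuous 2D position to the mitochondrion containing it
#' (rectangle membership with the half-open convention) or to the cytosol.
#' The query is total over the grid; points outside the grid are an error.
#'
#' @param points numeric matrix with columns x, y (or a length-2 vector).
#' @param geometry a `cell_geometry`.
#' @return integer vector: mitochondrion id, or 0 for cytosol.
#' @export
compartment_of <- function(points, geometry) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  x <- points[, 1]
  y <- points[, 2]
  if (any(x < 0 | x >= geometry$grid_width | y < 0 | y >= geometry$grid_height))
    stop("point outside grid")
  if (!is.null(geometry$comp_grid)) {
    W <- as.integer(geometry$grid_width)
    return(geometry$comp_grid[floor(x) + W * floor(y) + 1])
  }
  out <- integer(length(x))
  m <- geometry$mito
  for (i in seq_len(nrow(m))) {
    inside <- x >= m$x[i] & x < m$x[i] + m$w[i] &
              y >= m$y[i] & y < m$y[i] + m$h[i]
    out[inside] <- m$id[i]
  }
  out
}

#' Per-mitochondrion agent counts
#'
#' Counts how many of the given agents lie inside each mitochondrion.
#'
#' @param points numeric matrix of positions (may have zero rows).
#' @param geometry a `cell_geometry`.
#' @return integer vector of length `nrow(geometry$mito)`.
#' @export
count_in_mito <- function(points, geometry) {
  n_mito <- nrow(geometry$mito)
  if (is.null(points) || nrow(points) == 0) return(integer(n_mito))
  comp <- compartment_of(points, geometry)
  tabulate(comp, nbins = n_mito)
}

#' Export a layout as JSON
#'
#' Serializes a `cell_geometry` to the interchange schema
#' `{layout_name, grid_width, grid_height, margin, mitochondria: [...]}`
#' with mitochondria ordered by id.
#'
#' @param geometry a `cell_geometry`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @export
layout_to_json <- function(geometry, path = NULL) {
  m <- geometry$mito
  obj <- list(layout_name = geometry$layout_name,
              grid_width = geometry$grid_width,
              grid_height = geometry$grid_height,
              margin = geometry$margin,
              mitochondria = data.frame(id = m$id, x = m$x, y = m$y0,
                                        w = m$w, h = m$h,
                                        motion_amplitude = m$amp,
                                        motion_speed = m$speed))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Import a layout from JSON
#'
#' @param path JSON file or string produced by [layout_to_json()].
#' @return a `cell_geometry`.
#' @export
layout_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  m <- obj$mitochondria
  if (is.null(m) || length(m) == 0) {
    mito <- static_mito_df(numeric(0), numeric(0), 1)[0, ]
  } else {
    mito <- data.frame(id = m$id, x = m$x, y = m$y, w = m$w, h = m$h,
                       amp = m$motion_amplitude, speed = m$motion_speed,
                       y0 = m$y)
  }
  new_cell_geometry(obj$layout_name, obj$grid_width, obj$grid_height, mito,
                    margin = if (is.null(obj$margin)) 0 else obj$margin)
}
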