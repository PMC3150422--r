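# Brute-force oracle: overlap area of two axis-aligned rects.
rect_overlap_area <- function(a, b) {
  ox <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  oy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  ox * oy
}

all_pairs_overlap_free <- function(geom) {
  m <- geom$mito
  n <- nrow(m)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (rect_overlap_area(m[i, ], m[j, ]) > 0) return(FALSE)
  TRUE
}

rects_inside_grid <- function(geom) {
  m <- geom$mito
  all(m$x >= 0, m$y >= 0, m$x + m$w <= geom$grid_width,
      m$y + m$h <= geom$grid_height)
}

test_that("regular lattice dimensions and counts follow the spacing arithmetic", {
  g <- make_regular_layout()
  expect_equal(nrow(g$mito), 81)
  expect_equal(g$grid_width, 9 * 54 + 8 * 54 + 2 * 27)   # 972
  expect_equal(g$grid_height, 9 * 54 + 8 * 18 + 2 * 27)  # 684
  expect_true(all(g$mito$w == 54 & g$mito$h == 54))
  expect_true(all_pairs_overlap_free(g))
  expect_true(rects_inside_grid(g))

  # degenerate 1x1 lattice with no margin fills the grid
  g1 <- make_regular_layout(rows = 1, cols = 1, margin = 0)
  expect_equal(c(g1$grid_width, g1$grid_height), c(54, 54))
  expect_equal(unlist(g1$mito[1, c("x", "y", "w", "h")], use.names = FALSE),
               c(0, 0, 54, 54))

  expect_error(make_regular_layout(mito_side = 0), "positive")
})

test_that("low-density layout keeps cell size and spreads 25 mitochondria uniformly", {
  g9 <- make_regular_layout()
  g5 <- make_low_density_layout()
  expect_equal(nrow(g5$mito), 25)
  expect_equal(g5$grid_width, g9$grid_width)
  expect_equal(g5$grid_height, g9$grid_height)
  # pixel coverage ratio of the dense over the sparse layout
  expect_equal(sum(g9$mito$w * g9$mito$h) / sum(g5$mito$w * g5$mito$h), 3.24)
  # uniform center spacing within rows and columns
  cx <- sort(unique(g5$mito$x)) + 27
  cy <- sort(unique(g5$mito$y)) + 27
  expect_equal(length(unique(round(diff(cx), 9))), 1)
  expect_equal(length(unique(round(diff(cy), 9))), 1)
  expect_true(all_pairs_overlap_free(g5))
})

test_that("irregular layout is seeded, overlap-free, and handles the empty case", {
  g1 <- make_irregular_layout(n = 81, seed = 7)
  g2 <- make_irregular_layout(n = 81, seed = 7)
  expect_identical(g1$mito, g2$mito)
  expect_false(identical(g1$mito, make_irregular_layout(n = 81, seed = 8)$mito))
  for (s in 1:5) {
    g <- make_irregular_layout(n = 81, seed = s)
    expect_true(all_pairs_overlap_free(g))
    expect_true(rects_inside_grid(g))
  }
  g0 <- make_irregular_layout(n = 0, seed = 1)
  expect_equal(nrow(g0$mito), 0)
  # overfull request exhausts the attempt budget
  expect_error(make_irregular_layout(n = 40, seed = 1, grid_width = 120,
                                     grid_height = 120, mito_side = 54,
                                     max_attempts = 2000),
               "capacity")
})

test_that("gradient layout clusters mitochondria around the cell center", {
  dist_to_center <- function(geom) {
    cx <- geom$grid_width / 2
    cy <- geom$grid_height / 2
    mean(sqrt((geom$mito$x + geom$mito$w / 2 - cx)^2 +
              (geom$mito$y + geom$mito$h / 2 - cy)^2))
  }
  d_grad <- vapply(1:20, function(s) dist_to_center(make_gradient_layout(n = 81, seed = s)),
                   numeric(1))
  d_irr <- vapply(1:20, function(s) dist_to_center(make_irregular_layout(n = 81, seed = s)),
                  numeric(1))
  expect_lt(mean(d_grad), mean(d_irr))
  # single mitochondrion lands near the center far more often than chance:
  # with sigma = 162 the radial mass inside 243 px is 1 - exp(-1.125) =
  # 0.675, versus 0.28 for uniform placement
  near <- vapply(1:100, function(s) {
    dist_to_center(make_gradient_layout(n = 1, seed = s)) < 972 / 4
  }, logical(1))
  expect_gt(mean(near), 0.5)
  # wide sigma (2x cell width: density varies < 4% across the grid)
  # approaches the irregular distribution
  d_wide <- vapply(1:20, function(s) {
    dist_to_center(make_gradient_layout(n = 81, sigma = 2000, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(d_wide) - mean(d_irr)) / mean(d_irr), 0.15)
  for (s in 1:5)
    expect_true(all_pairs_overlap_free(make_gradient_layout(n = 81, seed = s)))
})

test_that("moving layout oscillates the 32-mitochondrion outer ring as a triangle wave", {
  g <- make_moving_layout()
  moving <- g$mito$amp > 0
  expect_equal(sum(moving), 32)
  interior <- which(!moving)[1]
  periph <- which(moving)[1]
  y_start <- g$mito$y[periph]
  # full period = 4*amp/speed = 72 steps; the wave also re-crosses the
  # origin halfway through at 2*amp/speed = 36 steps
  for (t in c(36, 72)) {
    gt <- advance_motion(g, t)
    expect_equal(gt$mito$y[periph], y_start)
  }
  g1000 <- advance_motion(g, 1000)
  expect_equal(g1000$mito$y[interior], g$mito$y[interior])
  # exhaustive over one period: sizes intact, inside grid, overlap-free
  for (t in 0:72) {
    gt <- advance_motion(g, t)
    expect_true(rects_inside_grid(gt))
    expect_false(any_rect_overlap(gt$mito))
    expect_true(all(gt$mito$w == 54 & gt$mito$h == 54))
  }
})

test_that("compartment lookup uses the half-open convention and matches brute force", {
  g <- make_regular_layout()
  m1 <- g$mito[1, ]  # at (27, 27)
  expect_equal(compartment_of(c(m1$x, m1$y), g), m1$id)
  # just past the right edge, inside the gap
  expect_equal(compartment_of(c(m1$x + m1$w, m1$y), g), 0L)
  expect_error(compartment_of(c(-1, 10), g), "outside")

  brute <- function(pt, geom) {
    m <- geom$mito
    for (i in seq_len(nrow(m)))
      if (pt[1] >= m$x[i] && pt[1] < m$x[i] + m$w[i] &&
          pt[2] >= m$y[i] && pt[2] < m$y[i] + m$h[i]) return(m$id[i])
    0L
  }
  set.seed(42)
  pts <- cbind(runif(10000, 0, g$grid_width), runif(10000, 0, g$grid_height))
  fast <- compartment_of(pts, g)
  slow <- vapply(seq_len(nrow(pts)), function(i) brute(pts[i, ], g), integer(1))
  expect_identical(fast, slow)
})

test_that("layouts round-trip through the JSON interchange schema", {
  for (geom in list(make_moving_layout(), make_irregular_layout(n = 10, seed = 2))) {
    path <- withr::local_tempfile(fileext = ".json")
    layout_to_json(geom, path)
    back <- layout_from_json(path)
    expect_equal(back$layout_name, geom$layout_name)
    expect_equal(back$mito, geom$mito, tolerance = 1e-12)
    expect_equal(c(back$grid_width, back$grid_height),
                 c(geom$grid_width, geom$grid_height))
  }
})
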