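SWEEP_VARIABLES <- c("initial_H2O2", "MnSOD_mult", "CuZnSOD_mult", "Gpx_mult")

apply_sweep_value <- function(params, variable, value) {
  switch(variable,
         initial_H2O2 = update_params(params, initial_h2o2 = value),
         MnSOD_mult = {
           m <- params$enzyme_mult; m[["MnSOD"]] <- value
           update_params(params, enzyme_mult = m)
         },
         CuZnSOD_mult = {
           m <- params$enzyme_mult; m[["CuZnSOD"]] <- value
           update_params(params, enzyme_mult = m)
         },
         Gpx_mult = {
           # cytosolic Gpx intervention; mitochondrial Gpx has its own
           # multiplier in sim_params
           m <- params$enzyme_mult; m[["GpxCyto"]] <- value
           update_params(params, enzyme_mult = m)
         },
         stop("unknown sweep variable: ", variable))
}

#' Dose-response sweep
#'
#' Runs [run_replicates()] at each value of the swept variable (the
#' initial H2O2 dose or an antioxidant intervention multiplier) and
#' records the mean and standard deviation of the final-step reactive
#' fraction.
#'
#' @param params base [sim_params()].
#' @param geometry a `cell_geometry`.
#' @param variable one of `"initial_H2O2"`, `"MnSOD_mult"`,
#'   `"CuZnSOD_mult"`, `"Gpx_mult"` (cytosolic Gpx).
#' @param values numeric vector of sweep values, strictly increasing.
#' @return a `dose_response` data.frame with columns
#'   `x, mean, sd, n` and attribute `variable`.
#' @export
sweep_response <- function(params, geometry, variable, values) {
  variable <- match.arg(variable, SWEEP_VARIABLES)
  if (length(values) == 0) stop("values must be non-empty")
  if (is.unsorted(values, strictly = TRUE)) stop("values must be strictly increasing")
  rows <- lapply(values, function(v) {
    res <- run_replicates(apply_sweep_value(params, variable, v), geometry)
    ff <- res$final_fractions
    data.frame(x = v, mean = mean(ff),
               sd = if (length(ff) > 1) stats::sd(ff) else 0,
               n = length(ff))
  })
  out <- do.call(rbind, rows)
  attr(out, "variable") <- variable
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Polynomial least-squares fit
#'
#' Fits `y = A + Bx + Cx^2 (+ Dx^3)` by ordinary (unweighted) least
#' squares, the regression form used for RIRR dose-response curves.
#'
#' @param x,y numeric vectors; at least `order + 1` distinct x values.
#' @param order 2 or 3.
#' @return named coefficient vector `A, B, C` (and `D` for order 3);
#'   coefficients dropped by the fit for rank deficiency are an error.
#' @export
fit_polynomial <- function(x, y, order = 3) {
  stopifnot(order %in% c(2, 3), length(x) == length(y))
  if (length(unique(x)) < order + 1)
    stop("need at least order + 1 distinct x values")
  fit <- stats::lm(y ~ stats::poly(x, degree = order, raw = TRUE))
  co <- unname(stats::coef(fit))
  if (any(is.na(co))) stop("rank-deficient polynomial fit")
  stats::setNames(co, c("A", "B", "C", "D")[seq_len(order + 1)])
}

#' RIRR threshold from a dose-response curve
#'
#' Fits a polynomial (order 2 or 3) to the curve and solves
#' `fitted(x) = target` for the RIRR threshold: the smallest real root
#' within the sampled x range. With the default target, the threshold is
#' the dose at which the fitted reactive fraction reaches 20%.
#'
#' @param curve a `dose_response` (or any data.frame with `x` and `mean`).
#' @param order polynomial order, 2 or 3.
#' @param target reactive-fraction level defining the threshold, percent.
#' @return a `threshold_estimate` list: `order`, `coefficients`,
#'   `threshold_x` (NA when invalid), `valid`, `target`, `x_range`.
#' @export
#' @examples
#' curve <- data.frame(x = seq(0, 10000, 1000), mean = 0.002 * seq(0, 10000, 1000))
#' rirr_threshold(curve, order = 3)$threshold_x   # 10000
rirr_threshold <- function(curve, order = 3, target = 20) {
  co <- fit_polynomial(curve$x, curve$mean, order)
  roots <- polyroot(c(co[1] - target, co[-1]))
  re <- Re(roots)[abs(Im(roots)) < 1e-8 * pmax(1, abs(Re(roots)))]
  rng <- range(curve$x)
  inside <- re[re >= rng[1] - 1e-9 * diff(rng) & re <= rng[2] + 1e-9 * diff(rng)]
  valid <- length(inside) > 0
  structure(list(order = order, coefficients = co,
                 threshold_x = if (valid) min(inside) else NA_real_,
                 valid = valid, target = target, x_range = rng),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("RIRR threshold (order-%d fit, target %g%%): %s\n", x$order,
              x$target,
              if (x$valid) sprintf("%.4g", x$threshold_x) else "not reached"))
  invisible(x)
}

#' Theoretical mean-square displacement
#'
#' For a 2D random walk whose every step is a diagonal of per-axis length
#' `L`, the mean-square displacement after `N` steps is `2 N L^2`.
#'
#' @param n_steps N.
#' @param step_length L, pixels.
#' @return expected squared displacement, pixels^2.
#' @export
msd_theory <- function(n_steps, step_length) {
  stopifnot(n_steps >= 0, step_length >= 0)
  2 * n_steps * step_length^2
}

#' Monte-Carlo diagonal random walk
#'
#' Simulates the fixed-step diagonal walk used to validate the diffusion
#' law: each step every walker moves +L or -L on each axis independently.
#' Returns the empirical mean-square displacement and its ratio to
#' `N * L^2` (expected to be 2).
#'
#' @param n_walkers number of independent walkers.
#' @param n_steps steps per walker.
#' @param step_length per-axis step length L.
#' @return list `msd`, `coefficient` (= msd / (N L^2)), `se_coefficient`.
#' @export
simulate_diagonal_walk <- function(n_walkers = 10000, n_steps = 100,
                                   step_length = 1) {
  kx <- stats::rbinom(n_walkers, n_steps, 0.5)
  ky <- stats::rbinom(n_walkers, n_steps, 0.5)
  x <- step_length * (2 * kx - n_steps)
  y <- step_length * (2 * ky - n_steps)
  sq <- x^2 + y^2
  denom <- n_steps * step_length^2
  list(msd = mean(sq), coefficient = mean(sq) / denom,
       se_coefficient = stats::sd(sq / denom) / sqrt(n_walkers))
}

#' Fraction of pixels occupied by each enzyme
#'
#' Sparse approximation `n / total pixels` (default) or the exact Poisson
#' occupancy `1 - exp(-n / total)`; used by the messenger lifetime
#' calculator.
#'
#' @param params a [sim_params()].
#' @param geometry a `cell_geometry`.
#' @param exact use the exact occupancy formula.
#' @return named fraction per enzyme class.
#' @export
enzyme_occupancy <- function(params, geometry, exact = FALSE) {
  total_px <- geometry$grid_width * geometry$grid_height
  mito_px <- sum(geometry$mito$w * geometry$mito$h)
  share <- c(MnSOD = mito_px / REF_MITO_FRACTION,
             CuZnSOD = (total_px - mito_px) / REF_CYTO_FRACTION,
             GpxMito = mito_px / REF_MITO_FRACTION,
             GpxCyto = (total_px - mito_px) / REF_CYTO_FRACTION)
  n <- round(params$enzyme_conc * params$enzyme_mult * share / 100)
  lambda <- n / total_px
  if (exact) 1 - exp(-lambda) else lambda
}

#' Messenger lifetime and diffusive reach
#'
#' Combines the per-step removal channels of a ROS species — spontaneous
#' decay plus, for each relevant enzyme class, (occupied-pixel fraction x
#' per-encounter reaction probability) — into a total per-step decay
#' probability `p_total`. The expected lifetime is `N = 1/p_total` steps
#' and the diffusive reach within that lifetime is `sqrt(2 N L^2)` pixels,
#' with `L` the species' maximum speed.
#'
#' @param species `"O2minus"` or `"H2O2"`.
#' @param params a [sim_params()].
#' @param occupancy named occupied-pixel fractions of the enzyme classes
#'   that remove this species (SODs for O2-, Gpx for H2O2); defaults to
#'   none, i.e. spontaneous decay only. See [enzyme_occupancy()].
#' @return a `messenger_kinetics` list: `species`, `p_total`,
#'   `lifetime_steps`, `step_length`, `reach_px`.
#' @export
#' @examples
#' messenger_lifetime("O2minus", sim_params())$lifetime_steps  # ~130
messenger_lifetime <- function(species = c("O2minus", "H2O2"),
                               params = sim_params(),
                               occupancy = NULL) {
  species <- match.arg(species)
  p_react <- if (species == "O2minus") params$p_sod else params$p_gpx
  p_total <- params$decay[[species]]
  if (!is.null(occupancy) && length(occupancy) > 0)
    p_total <- p_total + sum(occupancy * p_react)
  if (p_total <= 0) stop("total decay probability is zero: infinite lifetime")
  if (p_total > 1) p_total <- 1
  n <- 1 / p_total
  len <- params$speed[[species]]
  structure(list(species = species, p_total = p_total, lifetime_steps = n,
                 step_length = len, reach_px = sqrt(msd_theory(n, len))),
            class = "messenger_kinetics")
}

#' @export
print.messenger_kinetics <- function(x, ...) {
  cat(sprintf("%s: p_total %.4g/step, lifetime %.1f steps, reach %.1f px\n",
              x$species, x$p_total, x$lifetime_steps, x$reach_px))
  invisible(x)
}

#' Read a dose-response table from CSV
#'
#' Accepts the standalone fitting format `x, mean, sd, n`.
#'
#' @param path CSV file.
#' @return a `dose_response` data.frame.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "mean") %in% names(df)))
  if (is.null(df$sd)) df$sd <- NA_real_
  if (is.null(df$n)) df$n <- NA_integer_
  class(df) <- c("dose_response", "data.frame")
  df
}

#' Write a dose-response table to CSV
#'
#' @param curve a `dose_response`.
#' @param path output CSV file.
#' @export
write_dose_response <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("x", "mean", "sd", "n")], path,
                   row.names = FALSE)
  invisible(path)
}
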