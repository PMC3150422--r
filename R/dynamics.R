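#' Random-walk diffusion step
#'
#' Displaces every agent by `speed * u` per axis, with `u` drawn
#' independently per axis and per agent from Uniform(-0.5, 0.5), then
#' reflects at the grid walls. The agent count never changes.
#'
#' @param pos numeric matrix (n x 2) of positions.
#' @param speed maximum species speed, pixels per step.
#' @param geometry a `cell_geometry` (for the wall positions).
#' @return displaced position matrix of identical shape.
#' @export
diffuse <- function(pos, speed, geometry) {
  n <- nrow(pos)
  if (n == 0 || speed == 0) return(pos)
  x <- pos[, 1] + speed * (stats::runif(n) - 0.5)
  y <- pos[, 2] + speed * (stats::runif(n) - 0.5)
  cbind(reflect_coord(x, geometry$grid_width),
        reflect_coord(y, geometry$grid_height))
}

# Fold a coordinate back into [0, w) by mirror reflection at both walls.
# Handles arbitrarily large excursions; the measure-zero case of landing
# exactly on the far wall is nudged inside to preserve the half-open grid.
reflect_coord <- function(x, w) {
  x <- x %% (2 * w)
  x <- ifelse(x >= w, 2 * w - x, x)
  pmin(x, w * (1 - 1e-12))
}

#' Membrane crossing filter
#'
#' Compares each agent's compartment before and after a proposed move.
#' ROS agents whose move changes compartment keep the move only with the
#' direction-appropriate probability (`outward` to leave a mitochondrion,
#' `inward` to enter one, the product for a direct mitochondrion-to-
#' mitochondrion hop); otherwise the whole move is cancelled and the agent
#' keeps its pre-move position. Compartment-confined enzymes always keep
#' their pre-move position when the move would exit the home compartment.
#'
#' @param old,proposed position matrices before / after [diffuse()].
#' @param geometry a `cell_geometry` (current mitochondrial positions).
#' @param p_cross `c(inward=, outward=)` crossing probabilities, or the
#'   string `"mito"` / `"cyto"` to confine an enzyme to that compartment.
#' @return accepted position matrix.
#' @export
apply_membrane <- function(old, proposed, geometry, p_cross) {
  n <- nrow(old)
  if (n == 0) return(proposed)
  cn <- compartment_of(proposed, geometry)
  if (is.character(p_cross)) {
    bad <- if (p_cross == "mito") cn == 0L else cn > 0L
    proposed[bad, ] <- old[bad, , drop = FALSE]
    return(proposed)
  }
  co <- compartment_of(old, geometry)
  cross <- which(co != cn)
  if (length(cross) > 0) {
    p <- numeric(length(cross))
    out_move <- co[cross] > 0L & cn[cross] == 0L
    in_move  <- co[cross] == 0L & cn[cross] > 0L
    hop      <- co[cross] > 0L & cn[cross] > 0L
    p[out_move] <- p_cross[["outward"]]
    p[in_move]  <- p_cross[["inward"]]
    p[hop]      <- p_cross[["outward"]] * p_cross[["inward"]]
    reject <- cross[stats::runif(length(cross)) >= p]
    proposed[reject, ] <- old[reject, , drop = FALSE]
  }
  proposed
}

#' Spontaneous decay
#'
#' Removes each agent independently with the species' per-step
#' degradation probability.
#'
#' @param pos position matrix.
#' @param p per-step removal probability.
#' @return list with `pos` (survivors) and `removed` (count).
#' @export
decay <- function(pos, p) {
  n <- nrow(pos)
  if (n == 0 || p == 0) return(list(pos = pos, removed = 0L))
  keep <- stats::runif(n) >= p
  list(pos = pos[keep, , drop = FALSE], removed = n - sum(keep))
}

pixel_key <- function(pos, grid_width) {
  floor(pos[, 1]) + grid_width * floor(pos[, 2])
}

#' Pixel-co-location enzymatic reactions
#'
#' Agents are binned to integer pixels (floor of each coordinate). Every
#' O2- agent sharing a pixel with at least one SOD agent (Mn-SOD inside
#' mitochondria, CuZn-SOD in the cytosol — each confined there by the
#' membrane rules) is dismutated with probability `p_sod`, producing H2O2
#' at the same position (one per conversion by default; one per two
#' conversions with 2:1 stoichiometry). Every H2O2 agent sharing a pixel
#' with at least one Gpx agent is reduced (removed) with probability
#' `p_gpx`. Enzymes are catalytic and never consumed; multiple enzymes in
#' one pixel do not raise the per-step probability.
#'
#' @param o2,h2o2 ROS position matrices.
#' @param enzymes named list of enzyme position matrices
#'   (`MnSOD`, `CuZnSOD`, `GpxMito`, `GpxCyto`).
#' @param params a [sim_params()].
#' @param geometry a `cell_geometry`.
#' @return list `o2`, `h2o2` (updated positions), `n_dismutated`,
#'   `n_h2o2_created`, `n_reduced` (event counts).
#' @export
react <- function(o2, h2o2, enzymes, params, geometry) {
  gw <- geometry$grid_width
  sod_keys <- unique(c(
    if (nrow(enzymes$MnSOD) > 0) pixel_key(enzymes$MnSOD, gw),
    if (nrow(enzymes$CuZnSOD) > 0) pixel_key(enzymes$CuZnSOD, gw)))
  gpx_keys <- unique(c(
    if (nrow(enzymes$GpxMito) > 0) pixel_key(enzymes$GpxMito, gw),
    if (nrow(enzymes$GpxCyto) > 0) pixel_key(enzymes$GpxCyto, gw)))

  n_dis <- 0L
  n_new <- 0L
  if (nrow(o2) > 0 && length(sod_keys) > 0) {
    hit <- pixel_key(o2, gw) %in% sod_keys
    conv <- hit & stats::runif(nrow(o2)) < params$p_sod
    n_dis <- sum(conv)
    if (n_dis > 0) {
      produced <- o2[conv, , drop = FALSE]
      if (params$sod_stoichiometry == 2) {
        n_new <- n_dis %/% 2L
        produced <- produced[seq_len(n_new), , drop = FALSE]
      } else {
        n_new <- n_dis
      }
      o2 <- o2[!conv, , drop = FALSE]
      if (n_new > 0) h2o2 <- rbind(h2o2, produced)
    }
  }

  n_red <- 0L
  if (nrow(h2o2) > 0 && length(gpx_keys) > 0) {
    hit <- pixel_key(h2o2, gw) %in% gpx_keys
    rem <- hit & stats::runif(nrow(h2o2)) < params$p_gpx
    n_red <- sum(rem)
    if (n_red > 0) h2o2 <- h2o2[!rem, , drop = FALSE]
  }

  list(o2 = o2, h2o2 = h2o2, n_dismutated = as.integer(n_dis),
       n_h2o2_created = as.integer(n_new), n_reduced = as.integer(n_red))
}
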