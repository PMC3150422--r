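SPECIES <- c("O2minus", "H2O2", "MnSOD", "CuZnSOD", "GpxMito", "GpxCyto")
ENZYMES <- c("MnSOD", "CuZnSOD", "GpxMito", "GpxCyto")
ENZYME_HOME <- c(MnSOD = "mito", CuZnSOD = "cyto",
                 GpxMito = "mito", GpxCyto = "cyto")

empty_pos <- function() matrix(numeric(0), ncol = 2)

# Integer apportionment by largest remainder: exact total, proportional
# to weights.
alloc_largest_remainder <- function(total, weights) {
  k <- length(weights)
  if (k == 0 || total == 0) return(integer(k))
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- as.integer(round(total - sum(base)))
  out <- as.integer(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  }
  out
}

sample_in_rects <- function(counts, mito) {
  tot <- sum(counts)
  if (tot == 0) return(empty_pos())
  idx <- rep.int(seq_len(nrow(mito)), counts)
  cbind(stats::runif(tot, mito$x[idx], mito$x[idx] + mito$w[idx]),
        stats::runif(tot, mito$y[idx], mito$y[idx] + mito$h[idx]))
}

# Uniform points in the cytosol by rejection from the whole grid.
sample_in_cytosol <- function(n, geometry) {
  if (n == 0) return(empty_pos())
  out <- empty_pos()
  while (nrow(out) < n) {
    k <- max(2L * (n - nrow(out)), 32L)
    cand <- cbind(stats::runif(k, 0, geometry$grid_width),
                  stats::runif(k, 0, geometry$grid_height))
    keep <- compartment_of(cand, geometry) == 0L
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Compartment area fractions of the reference 9x9 cardiomyocyte cell
# (81 x 54^2 mitochondrial pixels in a 972 x 684 grid). Enzyme loading is
# occupancy-invariant: concentrations are molarities, so the per-pixel
# occupancy inside a compartment — not the total count — is what carries
# across layouts of different mitochondrial mass.
REF_MITO_FRACTION <- (81 * 54^2) / (972 * 684)
REF_CYTO_FRACTION <- 1 - REF_MITO_FRACTION

#' Initialize the world state
#'
#' Creates all agents at step 0. Enzyme abundance follows the
#' percent-of-whole-grid-pixels convention on the reference 9x9 cell:
#' there, each enzyme gets `round(conc% * multiplier * grid pixels /
#' 100)` copies. Because the published concentrations are molarities,
#' the quantity held invariant across layouts is the *occupancy* of the
#' enzyme's home compartment: the count scales with the layout's
#' mitochondrial (or cytosolic) pixel share relative to the reference
#' cell's, so a sparse layout carries proportionally fewer mitochondrial
#' enzymes at identical intra-mitochondrial concentration.
#' Mitochondrial enzymes are apportioned across mitochondria
#' proportionally to area (largest-remainder rounding) and placed
#' uniformly inside their rectangle, cytosolic enzymes uniformly in the
#' cytosol; the H2O2 dose is placed uniformly inside a centered
#' injection square; there is no O2- at step 0.
#'
#' Callers are responsible for seeding the RNG ([run_simulation()] does).
#'
#' @param params a [sim_params()].
#' @param geometry a `cell_geometry`.
#' @return a `world` list: `pos` (per-species position matrices), `step`,
#'   `geometry`, `params`, cumulative event `counters`.
#' @export
initialize_world <- function(params, geometry) {
  gw <- geometry$grid_width
  gh <- geometry$grid_height
  side <- params$injection_side
  if (side > gw || side > gh)
    stop("injection square larger than the grid")
  total_px <- gw * gh
  m <- geometry$mito
  areas <- if (nrow(m) > 0) m$w * m$h else numeric(0)
  mito_px <- sum(areas)
  cyto_px <- total_px - mito_px
  pos <- stats::setNames(vector("list", length(SPECIES)), SPECIES)
  pos$O2minus <- empty_pos()

  for (enz in ENZYMES) {
    dens <- params$enzyme_conc[[enz]] * params$enzyme_mult[[enz]] / 100
    if (ENZYME_HOME[[enz]] == "mito") {
      n <- round(dens * mito_px / REF_MITO_FRACTION)
      pos[[enz]] <- sample_in_rects(alloc_largest_remainder(n, areas), m)
    } else {
      n <- round(dens * cyto_px / REF_CYTO_FRACTION)
      pos[[enz]] <- sample_in_cytosol(n, geometry)
    }
  }

  nd <- params$initial_h2o2
  cx <- gw / 2
  cy <- gh / 2
  pos$H2O2 <- if (nd > 0)
    cbind(stats::runif(nd, cx - side / 2, cx + side / 2),
          stats::runif(nd, cy - side / 2, cy + side / 2))
  else empty_pos()

  list(pos = pos, step = 0L, geometry = geometry, params = params,
       counters = c(leaked = 0L, dismutated = 0L, h2o2_created = 0L,
                    reduced = 0L, o2_decayed = 0L, h2o2_decayed = 0L,
                    injected = as.integer(nd)))
}

#' Advance the world by one step
#'
#' Applies, in a fixed documented order: mitochondrial motion, the
#' per-mitochondrion ROS tally, respiration (electron leakage), diffusion
#' of all species, membrane crossing, pixel reactions, spontaneous decay,
#' and reactive classification. Event counters are accumulated so the
#' per-step count bookkeeping is exact.
#'
#' @param world a world from [initialize_world()].
#' @return the world advanced one step, with a `metrics` entry
#'   (`step`, `reactive_fraction`, `n_o2minus`, `n_h2o2`, `mito_o2`).
#' @export
step_world <- function(world) {
  params <- world$params
  t <- world$step + 1L
  geom <- advance_motion(world$geometry, t)
  pos <- world$pos
  cnt <- world$counters

  # tally internal ROS, then respire
  n_o2_in <- count_in_mito(pos$O2minus, geom)
  n_h2o2_in <- count_in_mito(pos$H2O2, geom)
  resp <- respire_all(geom, n_h2o2_in, n_o2_in, params)
  if (resp$n > 0) pos$O2minus <- rbind(pos$O2minus, resp$pos)
  cnt[["leaked"]] <- cnt[["leaked"]] + resp$n

  # transport: diffuse, then the membrane filter
  for (sp in SPECIES) {
    old <- pos[[sp]]
    if (nrow(old) == 0) next
    spd <- if (sp %in% ENZYMES) params$speed[["enzyme"]] else params$speed[[sp]]
    prop <- diffuse(old, spd, geom)
    rule <- if (sp %in% ENZYMES) ENZYME_HOME[[sp]] else params$membrane[[sp]]
    pos[[sp]] <- apply_membrane(old, prop, geom, rule)
  }

  # reactions
  rx <- react(pos$O2minus, pos$H2O2,
              pos[c("MnSOD", "CuZnSOD", "GpxMito", "GpxCyto")], params, geom)
  pos$O2minus <- rx$o2
  pos$H2O2 <- rx$h2o2
  cnt[["dismutated"]] <- cnt[["dismutated"]] + rx$n_dismutated
  cnt[["h2o2_created"]] <- cnt[["h2o2_created"]] + rx$n_h2o2_created
  cnt[["reduced"]] <- cnt[["reduced"]] + rx$n_reduced

  # spontaneous decay
  d <- decay(pos$O2minus, params$decay[["O2minus"]])
  pos$O2minus <- d$pos
  cnt[["o2_decayed"]] <- cnt[["o2_decayed"]] + d$removed
  d <- decay(pos$H2O2, params$decay[["H2O2"]])
  pos$H2O2 <- d$pos
  cnt[["h2o2_decayed"]] <- cnt[["h2o2_decayed"]] + d$removed
  if (params$decay[["enzyme"]] > 0) {
    for (enz in ENZYMES) pos[[enz]] <- decay(pos[[enz]],
                                             params$decay[["enzyme"]])$pos
  }

  # classify
  loads <- count_in_mito(pos$O2minus, geom)
  cls <- classify_reactive(loads, params$reactive_threshold)

  world$pos <- pos
  world$step <- t
  world$geometry <- geom
  world$counters <- cnt
  world$metrics <- list(step = t, reactive_fraction = cls$fraction,
                        n_o2minus = nrow(pos$O2minus),
                        n_h2o2 = nrow(pos$H2O2), mito_o2 = loads)
  world
}

#' Run one simulation replicate
#'
#' Seeds the RNG, initializes the world and advances it `n_steps` steps,
#' recording per-step metrics. Identical seeds give bit-identical results.
#'
#' @param params a [sim_params()].
#' @param geometry a `cell_geometry`.
#' @param seed RNG seed for this replicate.
#' @return a `rirr_run`: `metrics` data.frame (`step, reactive_fraction,
#'   n_o2minus, n_h2o2`), `mito_o2` matrix (steps x mitochondria),
#'   `counters`, `seed`, and the final `world`.
#' @export
run_simulation <- function(params, geometry, seed = params$base_seed) {
  set.seed(seed)
  world <- initialize_world(params, geometry)
  ns <- params$n_steps
  nm <- nrow(geometry$mito)
  frac <- numeric(ns)
  n_o2 <- integer(ns)
  n_h <- integer(ns)
  loads <- matrix(0L, nrow = ns, ncol = nm)
  for (t in seq_len(ns)) {
    world <- step_world(world)
    mt <- world$metrics
    frac[t] <- mt$reactive_fraction
    n_o2[t] <- mt$n_o2minus
    n_h[t] <- mt$n_h2o2
    loads[t, ] <- mt$mito_o2
  }
  structure(list(metrics = data.frame(step = seq_len(ns),
                                      reactive_fraction = frac,
                                      n_o2minus = n_o2, n_h2o2 = n_h),
                 mito_o2 = loads, counters = world$counters, seed = seed,
                 params = params, world = world),
            class = "rirr_run")
}

#' Run replicate simulations and summarize
#'
#' Runs `n_replicates` independent simulations with seeds
#' `base_seed, base_seed+1, ...` and aggregates the per-step reactive
#' fraction into mean and standard deviation across replicates.
#'
#' @param params a [sim_params()].
#' @param geometry a `cell_geometry`.
#' @return a `rirr_result`: `runs` (list of [run_simulation()] results),
#'   `summary` data.frame (`step, mean, sd`), `final_fractions` (one per
#'   replicate), `params`, `geometry`.
#' @export
run_replicates <- function(params, geometry) {
  seeds <- params$base_seed + seq_len(params$n_replicates) - 1L
  runs <- lapply(seeds, function(s) run_simulation(params, geometry, s))
  fr <- vapply(runs, function(r) r$metrics$reactive_fraction,
               numeric(params$n_steps))
  fr <- matrix(fr, nrow = params$n_steps)
  mean_t <- rowMeans(fr)
  sd_t <- if (ncol(fr) > 1) apply(fr, 1, stats::sd) else rep(0, nrow(fr))
  structure(list(runs = runs,
                 summary = data.frame(step = seq_len(params$n_steps),
                                      mean = mean_t, sd = sd_t),
                 final_fractions = fr[params$n_steps, ],
                 params = params, geometry = geometry),
            class = "rirr_result")
}

#' @export
print.rirr_result <- function(x, ...) {
  ff <- x$final_fractions
  cat(sprintf(paste0("rirr_result: %s layout, %d replicates x %d steps; ",
                     "final reactive fraction %.2f%% (sd %.2f)\n"),
              x$geometry$layout_name, length(ff), x$params$n_steps,
              mean(ff), stats::sd(ff)))
  invisible(x)
}
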