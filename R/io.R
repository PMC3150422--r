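CONFIG_LAYOUTS <- c("regular", "irregular", "low_density", "moving",
                    "gradient", "mini")

#' Write a run configuration
#'
#' Serializes a parameter set plus a layout selection to YAML or JSON
#' (chosen by file extension). The representation round-trips losslessly
#' through [read_run_config()].
#'
#' @param params a [sim_params()].
#' @param layout layout name (one of the built-in layouts, or `"mini"`
#'   for the mini fixture), plus optional `layout_seed` for the
#'   randomized layouts.
#' @param path output file, `.yaml`/`.yml` or `.json`.
#' @param layout_seed seed for irregular/gradient placement.
#' @export
write_run_config <- function(params, layout, path, layout_seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  layout <- match.arg(layout, CONFIG_LAYOUTS)
  obj <- unclass(params)
  obj$leak <- unclass(obj$leak)
  obj$enzyme_conc <- as.list(obj$enzyme_conc)
  obj$enzyme_mult <- as.list(obj$enzyme_mult)
  obj$speed <- as.list(obj$speed)
  obj$decay <- as.list(obj$decay)
  obj$membrane <- lapply(obj$membrane, as.list)
  obj <- c(list(layout = layout, layout_seed = layout_seed), obj)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 15)
  } else if (grepl("\\.json$", path)) {
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  } else stop("config path must end in .yaml, .yml or .json")
  invisible(path)
}

#' Read a run configuration
#'
#' Parses a YAML or JSON configuration written by [write_run_config()]
#' (or by hand with the same field names). Unknown keys are rejected.
#'
#' @param path config file.
#' @return list with elements `params` (a [sim_params()]), `layout`,
#'   `layout_seed`, `geometry` (the constructed `cell_geometry`).
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
         else stop("config path must end in .yaml, .yml or .json")
  known <- c("layout", "layout_seed", "initial_h2o2", "injection_side",
             "enzyme_conc", "enzyme_mult", "reactive_threshold", "n_steps",
             "n_replicates", "base_seed", "speed", "decay", "membrane",
             "p_sod", "p_gpx", "sod_stoichiometry", "respiration_rate",
             "respiration_size", "leak")
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  layout <- match.arg(obj$layout, CONFIG_LAYOUTS)
  seed <- if (is.null(obj$layout_seed)) 1 else obj$layout_seed
  args <- obj[setdiff(names(obj), c("layout", "layout_seed"))]
  if (!is.null(args$leak)) args$leak <- do.call(leak_rule, args$leak)
  for (nm in c("enzyme_conc", "enzyme_mult", "speed", "decay"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (!is.null(args$membrane)) args$membrane <- lapply(args$membrane, unlist)
  params <- do.call(sim_params, args)
  geometry <- switch(layout,
                     regular = make_regular_layout(),
                     irregular = make_irregular_layout(seed = seed),
                     low_density = make_low_density_layout(),
                     moving = make_moving_layout(),
                     gradient = make_gradient_layout(seed = seed),
                     mini = make_mini_geometry("regular"))
  list(params = params, layout = layout, layout_seed = seed,
       geometry = geometry)
}

#' Write replicate metrics to CSV
#'
#' Long format: one row per step per replicate with columns
#' `step, replicate, reactive_fraction, n_o2minus, n_h2o2`. With
#' `per_mito = TRUE`, additional columns `mito_<id>` carry each
#' mitochondrion's internal O2- load.
#'
#' @param result a [run_replicates()] result.
#' @param path output CSV file.
#' @param per_mito include the per-mitochondrion load columns.
#' @export
write_metrics_csv <- function(result, path, per_mito = FALSE) {
  stopifnot(inherits(result, "rirr_result"))
  rows <- lapply(seq_along(result$runs), function(i) {
    df <- result$runs[[i]]$metrics
    df <- cbind(step = df$step, replicate = i,
                df[, c("reactive_fraction", "n_o2minus", "n_h2o2")])
    if (per_mito) {
      loads <- result$runs[[i]]$mito_o2
      colnames(loads) <- paste0("mito_", result$geometry$mito$id)
      df <- cbind(df, loads)
    }
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Debug dump of agent positions
#'
#' Writes every agent as a CSV row `species, x, y`.
#'
#' @param world a world state (see [initialize_world()]).
#' @param path output CSV file.
#' @export
write_positions_csv <- function(world, path) {
  rows <- lapply(names(world$pos), function(sp) {
    p <- world$pos[[sp]]
    if (nrow(p) == 0) return(NULL)
    data.frame(species = sp, x = p[, 1], y = p[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Render a world snapshot
#'
#' Rasterizes the world at its current step using the standard color
#' convention: black background, red mitochondrion squares, green O2-
#' agents, white H2O2 agents; enzymes optionally in dim blue/gray.
#' The raster has exactly the grid's pixel dimensions and is
#' deterministic given the world state.
#'
#' @param world a world state.
#' @param show_enzymes also draw enzyme agents in dim colors.
#' @return numeric array `grid_height x grid_width x 3` in `[0, 1]`.
#' @export
render_snapshot <- function(world, show_enzymes = FALSE) {
  geom <- world$geometry
  W <- as.integer(geom$grid_width)
  H <- as.integer(geom$grid_height)
  img <- array(0, dim = c(H, W, 3))
  m <- geom$mito
  for (i in seq_len(nrow(m))) {
    rows <- (floor(m$y[i]) + 1):min(H, ceiling(m$y[i] + m$h[i]))
    cols <- (floor(m$x[i]) + 1):min(W, ceiling(m$x[i] + m$w[i]))
    img[rows, cols, 1] <- 1  # red squares
  }
  paint <- function(img, pos, rgb) {
    if (nrow(pos) == 0) return(img)
    r <- floor(pos[, 2]) + 1
    c <- floor(pos[, 1]) + 1
    for (ch in 1:3) img[cbind(r, c, ch)] <- rgb[ch]
    img
  }
  if (show_enzymes) {
    img <- paint(img, world$pos$MnSOD, c(0.3, 0.3, 0.6))
    img <- paint(img, world$pos$CuZnSOD, c(0.3, 0.3, 0.6))
    img <- paint(img, world$pos$GpxMito, c(0.4, 0.4, 0.4))
    img <- paint(img, world$pos$GpxCyto, c(0.4, 0.4, 0.4))
  }
  img <- paint(img, world$pos$O2minus, c(0, 1, 0))  # green
  img <- paint(img, world$pos$H2O2, c(1, 1, 1))     # white
  img
}

#' Write a snapshot PNG
#'
#' @param world a world state.
#' @param path output PNG file.
#' @param show_enzymes also draw enzymes.
#' @export
write_snapshot_png <- function(world, path, show_enzymes = FALSE) {
  png::writePNG(render_snapshot(world, show_enzymes), path)
  invisible(path)
}
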