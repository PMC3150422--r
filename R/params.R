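#' Electron-leakage rule parameters
#'
#' The per-respiration-event probability that an electron leaks from the
#' transport chain and produces superoxide is a sigmoid function of the
#' ROS load inside the mitochondrion: a baseline `a0` during normal
#' respiration rising to `a0 + a1` when the mitochondrion is saturated
#' with ROS. Each internal H2O2 agent contributes `weight_h2o2` and each
#' internal O2- agent `weight_o2` to the sigmoid argument.
#'
#' Two variants are provided. `"as_printed"` is the literal published
#' form `a0 + a1 / (1 + exp(-wH*nH - wS*nS))`, whose value at zero ROS is
#' `a0 + a1/2` (10.5% with the defaults). `"rescaled"` re-anchors the same
#' sigmoid so that zero ROS maps exactly to `a0` (1%) while the saturation
#' limit stays `a0 + a1` (20%), consistent with the stated 1%-20% leakage
#' range; it is the default.
#'
#' The `units` field says what quantity the weights multiply. With
#' `"agents"` the sigmoid argument uses raw internal agent counts — the
#' literal printed form, and the default for this standalone calculator.
#' With `"percent_of_area"` each count is first converted to a
#' mitochondrion-local percent concentration, `100 * n / area`; this is
#' the simulation engine's default (see [sim_params()]), because raw
#' counts make the respiration feedback loop unstable at rest: a
#' 54x54 mitochondrion respiring `0.01 * 2916` events per step amplifies
#' its own baseline superoxide above the 50-agent reactive threshold with
#' no oxidative stimulus at all, whereas local percent units leave the
#' rest state quiescent and ignitable only by an external ROS load.
#'
#' @param a0 baseline leak probability at zero ROS (rescaled variant).
#' @param a1 sigmoid span; saturation probability is `a0 + a1`.
#' @param weight_h2o2 sigmoid weight per unit of internal H2O2.
#' @param weight_o2 sigmoid weight per unit of internal O2-.
#' @param variant `"rescaled"` (default) or `"as_printed"`.
#' @param units `"agents"` (raw counts) or `"percent_of_area"`
#'   (mito-local percent concentration).
#' @return an object of class `leak_rule`.
#' @export
leak_rule <- function(a0 = 0.01, a1 = 0.19, weight_h2o2 = 0.01,
                      weight_o2 = 0.09,
                      variant = c("rescaled", "as_printed"),
                      units = c("agents", "percent_of_area")) {
  variant <- match.arg(variant)
  units <- match.arg(units)
  stopifnot(a0 >= 0, a1 >= 0, a0 + a1 <= 1, weight_h2o2 >= 0, weight_o2 >= 0)
  structure(list(a0 = a0, a1 = a1, weight_h2o2 = weight_h2o2,
                 weight_o2 = weight_o2, variant = variant, units = units),
            class = "leak_rule")
}

#' Electron-leakage probability
#'
#' Evaluates the leakage rule for given internal ROS agent counts.
#' Vectorized over the counts. Monotone non-decreasing in both arguments
#' and bounded above by `a0 + a1`.
#'
#' @param n_h2o2,n_o2 non-negative agent counts inside the mitochondrion.
#' @param rule a [leak_rule()].
#' @param area mitochondrion pixel area, used only when the rule's units
#'   are `"percent_of_area"`; default 54^2.
#' @return leak probability (or vector thereof).
#' @export
#' @examples
#' leakage_probability(0, 0)                         # 0.01
#' leakage_probability(0, 1e6)                       # 0.20
#' leakage_probability(0, 0, leak_rule(variant = "as_printed"))  # 0.105
leakage_probability <- function(n_h2o2, n_o2, rule = leak_rule(),
                                area = 54^2) {
  stopifnot(all(n_h2o2 >= 0), all(n_o2 >= 0))
  if (rule$units == "percent_of_area") {
    n_h2o2 <- 100 * n_h2o2 / area
    n_o2 <- 100 * n_o2 / area
  }
  z <- rule$weight_h2o2 * n_h2o2 + rule$weight_o2 * n_o2
  s <- stats::plogis(z)
  switch(rule$variant,
         as_printed = rule$a0 + rule$a1 * s,
         rescaled   = rule$a0 + 2 * rule$a1 * (s - 0.5))
}

#' Simulation parameters
#'
#' Collects every constant of the model: species kinetics, membrane
#' permeabilities, enzyme concentrations and intervention multipliers, the
#' oxidative-stress dose, the leakage rule, and run control. Defaults are
#' the cardiomyocyte parameter set.
#'
#' Concentrations are in percent of whole-grid pixels: the number of enzyme
#' agents created is `round(conc/100 * mult * grid pixels)`, regardless of
#' the compartment the enzyme is then confined to.
#'
#' The per-encounter reaction probabilities preserve the ratio of the SOD
#' and Gpx rate constants (2.3e9 vs 5e7 /Ms): the faster SOD reaction
#' saturates at 1 and Gpx reacts with probability 5e7/2.3e9.
#'
#' @param initial_h2o2 H2O2 agents injected at step 0 ("oxidative dose").
#' @param injection_side side (px) of the centered injection square.
#' @param enzyme_conc named percent concentrations for `MnSOD`, `CuZnSOD`,
#'   `GpxMito`, `GpxCyto`.
#' @param enzyme_mult named intervention multipliers for the same enzymes.
#' @param reactive_threshold a mitochondrion is reactive when its internal
#'   O2- count strictly exceeds this.
#' @param n_steps simulation steps per replicate.
#' @param n_replicates independent replicates; replicate i uses seed
#'   `base_seed + i - 1`.
#' @param base_seed RNG seed of the first replicate.
#' @param speed named maximum speeds (px/step) for `O2minus`, `H2O2`,
#'   `enzyme`. Per-axis displacement each step is `speed * u`,
#'   `u ~ Uniform(-0.5, 0.5)`.
#' @param decay named spontaneous per-step removal probabilities.
#' @param membrane list of per-species crossing probabilities, each
#'   `c(inward=, outward=)`. H2O2 crosses readily in both directions
#'   (0.5); O2- leaves mitochondria at 0.2 per attempt — superoxide
#'   efflux through inner-membrane anion channels is the classical RIRR
#'   release route — but re-enters poorly (0.05). The outward value was
#'   calibrated once so a resting cell stays quiescent in every layout
#'   (see the package vignette).
#' @param p_sod,p_gpx per-encounter reaction probabilities.
#' @param sod_stoichiometry O2- consumed per H2O2 produced (1 or 2).
#' @param respiration_rate respiration events per step per unit of
#'   mitochondrion size (default 0.01).
#' @param respiration_size `"area"` (size = w*h, default) or `"length"`
#'   (size = h).
#' @param leak a [leak_rule()]; the engine default uses
#'   `units = "percent_of_area"` (see [leak_rule()] for why).
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(initial_h2o2 = 10000,
                       injection_side = 108,
                       enzyme_conc = c(MnSOD = 0.769, CuZnSOD = 0.914,
                                       GpxMito = 0.3, GpxCyto = 0.549),
                       enzyme_mult = c(MnSOD = 1, CuZnSOD = 1,
                                       GpxMito = 1, GpxCyto = 1),
                       reactive_threshold = 50,
                       n_steps = 3000,
                       n_replicates = 5,
                       base_seed = 1,
                       speed = c(O2minus = 11.66, H2O2 = 11.31,
                                 enzyme = 1.414),
                       decay = c(O2minus = 0.00769, H2O2 = 1e-5,
                                 enzyme = 0),
                       membrane = list(O2minus = c(inward = 0.05,
                                                   outward = 0.2),
                                       H2O2 = c(inward = 0.5,
                                                outward = 0.5)),
                       p_sod = 1,
                       p_gpx = 5e7 / 2.3e9,
                       sod_stoichiometry = 1,
                       respiration_rate = 0.01,
                       respiration_size = c("area", "length"),
                       leak = leak_rule(units = "percent_of_area")) {
  respiration_size <- match.arg(respiration_size)
  enz <- c("MnSOD", "CuZnSOD", "GpxMito", "GpxCyto")
  stopifnot(all(enz %in% names(enzyme_conc)),
            all(enz %in% names(enzyme_mult)),
            all(enzyme_conc >= 0), all(enzyme_mult >= 0),
            initial_h2o2 >= 0, injection_side > 0,
            reactive_threshold >= 0,
            n_steps >= 1, n_replicates >= 1,
            all(speed[c("O2minus", "H2O2", "enzyme")] > 0),
            all(decay >= 0 & decay <= 1),
            p_sod >= 0, p_sod <= 1, p_gpx >= 0, p_gpx <= 1,
            sod_stoichiometry %in% c(1, 2),
            respiration_rate >= 0,
            inherits(leak, "leak_rule"))
  for (sp in c("O2minus", "H2O2")) {
    pm <- membrane[[sp]]
    stopifnot(!is.null(pm), all(c("inward", "outward") %in% names(pm)),
              all(pm >= 0 & pm <= 1))
  }
  structure(list(initial_h2o2 = initial_h2o2,
                 injection_side = injection_side,
                 enzyme_conc = enzyme_conc[enz],
                 enzyme_mult = enzyme_mult[enz],
                 reactive_threshold = reactive_threshold,
                 n_steps = as.integer(n_steps),
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 speed = speed, decay = decay, membrane = membrane,
                 p_sod = p_sod, p_gpx = p_gpx,
                 sod_stoichiometry = sod_stoichiometry,
                 respiration_rate = respiration_rate,
                 respiration_size = respiration_size,
                 leak = leak),
            class = "sim_params")
}

#' Update fields of a parameter set
#'
#' Convenience wrapper: returns a copy of `params` with the named fields
#' replaced, re-validated through [sim_params()].
#'
#' @param params a `sim_params`.
#' @param ... fields to replace (same names as [sim_params()] arguments).
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "sim_params"))
  repl <- list(...)
  args <- unclass(params)
  for (nm in names(repl)) {
    if (!nm %in% names(args)) stop("unknown parameter: ", nm)
    args[[nm]] <- repl[[nm]]
  }
  do.call(sim_params, args)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("sim_params: dose %g H2O2 (square %g px), %d steps x %d",
                     " replicates (seed %d)\n"),
              x$initial_h2o2, x$injection_side, x$n_steps, x$n_replicates,
              x$base_seed))
  cat(sprintf("  leak rule: %s, a0=%g a1=%g wH=%g wS=%g\n", x$leak$variant,
              x$leak$a0, x$leak$a1, x$leak$weight_h2o2, x$leak$weight_o2))
  cat("  enzyme % of grid pixels:",
      paste(names(x$enzyme_conc),
            sprintf("%g x%g", x$enzyme_conc, x$enzyme_mult), collapse = ", "),
      "\n")
  invisible(x)
}
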