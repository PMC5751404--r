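#' Design of a synthetic multi-channel biofilm experiment
#'
#' Describes a population of flow-cell channels: a generating
#' [model_spec()] with fixed-effect parameter values, lognormal
#' inter-channel variability (CV% per parameter), additive residual
#' noise, dosing arms assigned to experiments, and the sampling grid.
#' [generate_dataset()] turns a design into data.
#'
#' Built-in arms (used by the two-drug population preset):
#' \describe{
#'   \item{control}{no agent;}
#'   \item{mem_single_24 / tob_single_24}{a single bolus of one drug at
#'     24 h (the other agent's concentration stays 0);}
#'   \item{mem_triple_74 / tob_triple_74}{three boluses of one drug at
#'     74, 82 and 90 h (8-h interval);}
#'   \item{single_24 / triple_74}{both drugs together on the same
#'     schedules;}
#'   \item{combined_72}{a 3-h MEM infusion plus a single TOB bolus at
#'     72 h.}
#' }
#' Arms are assigned to experiments by recycling `arms`; every channel
#' of an experiment shares its arm.
#'
#' @param spec Generating [model_spec()] (the agent effect, if any, is
#'   attached to drug arms; control arms drop it).
#' @param sampling_times Sampling grid (h), increasing.
#' @param n_experiments,channels_per_experiment Population size.
#' @param cv_percent Named vector of inter-channel CV% per parameter
#'   (lognormal; names as in [fit_single()] estimates).  CV% relates to
#'   the log-SD by \eqn{\omega = \sqrt{\ln(1 + (CV/100)^2)}}.
#' @param sigma Additive residual SD (measurement units).
#' @param arms Character vector of arm names recycled over experiments.
#' @param include_dead Also emit dead-compartment series (requires a
#'   dead model in `spec`).
#' @param variable,unit Metadata for the emitted series.
#' @param seed Default seed used by [generate_dataset()].
#' @return An object of class `population_design`.
#' @export
population_design <- function(spec, sampling_times,
                              n_experiments = 1, channels_per_experiment = 1,
                              cv_percent = numeric(0), sigma = 0,
                              arms = "control", include_dead = FALSE,
                              variable = "biomass", unit = "um^3/um^2", seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.unsorted(sampling_times, strictly = TRUE)) stop("sampling_times must be increasing")
  if (any(cv_percent < 0)) stop("CVs must be nonnegative")
  if (sigma < 0) stop("sigma must be nonnegative")
  drug_arms <- setdiff(arms, "control")
  if (length(drug_arms) && is.null(spec$agent_effect))
    stop("drug arms require a spec with an agent_effect")
  if (include_dead && spec$dead_model == "none")
    stop("include_dead requires a dead model in the spec")
  structure(list(spec = spec, sampling_times = as.numeric(sampling_times),
                 n_experiments = n_experiments,
                 channels_per_experiment = channels_per_experiment,
                 cv_percent = cv_percent, sigma = sigma, arms = arms,
                 include_dead = include_dead, variable = variable, unit = unit,
                 seed = seed),
            class = "population_design")
}

# per-arm model spec: control drops the agent; drug arms attach PK
.arm_spec <- function(base, arm) {
  if (arm == "control") {
    base$agent_effect <- NULL; base$pk <- list()
    if (base$dead_model == "rate_coupled" && base$growth$family == "gompertz")
      base$dead_model <- "gompertz_difference"
    return(base)
  }
  two <- inherits(base$agent_effect, "two_agent_params")
  trip <- c(74, 82, 90)
  pk <- switch(arm,
    single_24     = list(pk_preset("MEM", 24), pk_preset("TOB", 24)),
    mem_single_24 = list(pk_preset("MEM", 24), pk_preset("TOB", NULL)),
    tob_single_24 = list(pk_preset("MEM", NULL), pk_preset("TOB", 24)),
    triple_74     = list(pk_preset("MEM", trip), pk_preset("TOB", trip)),
    mem_triple_74 = list(pk_preset("MEM", trip), pk_preset("TOB", NULL)),
    tob_triple_74 = list(pk_preset("MEM", NULL), pk_preset("TOB", trip)),
    combined_72   = list(pk_preset("MEM", 72, mode = "infusion"), pk_preset("TOB", 72)),
    stop(sprintf("unknown arm '%s'", arm)))
  if (!two) pk <- pk[vapply(pk, function(p) nrow(p$events) > 0, logical(1))][1]
  base$pk <- pk
  base
}

#' Generate a synthetic dataset from a population design
#'
#' Per channel: draws lognormal parameter perturbations
#' (\eqn{p_{ch} = p \exp(\eta)}, \eqn{\eta \sim N(0, \omega^2)} with
#' \eqn{\omega} from the design CV%), simulates the live (and optionally
#' dead) trajectory, adds additive Gaussian residual noise and truncates
#' negative measurements at 0 (counted).  Fully reproducible from the
#' seed.
#'
#' @param design A [population_design()].
#' @param seed Overrides the design's seed.
#' @return List of `series_data` with attributes `truth` (data frame of
#'   every channel's true parameters and arm, plus `n_truncated`) and
#'   `specs` (per-channel [model_spec()]s, aligned with the live series
#'   order) for estimator round trips.
#' @export
generate_dataset <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "population_design"))
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  cv <- design$cv_percent
  omega <- sqrt(log(1 + (cv / 100)^2))
  tt <- design$sampling_times
  tg <- sort(unique(c(0, tt)))
  out <- list(); specs <- list(); truth <- list(); n_trunc <- 0L
  for (k in seq_len(design$n_experiments)) {
    arm <- design$arms[(k - 1L) %% length(design$arms) + 1L]
    arm_spec <- .arm_spec(design$spec, arm)
    for (cidx in seq_len(design$channels_per_experiment)) {
      eta <- stats::rnorm(length(omega), 0, omega)
      pert <- stats::setNames(exp(eta), names(cv))
      true_vals <- .current_values(design$spec, names(pert)) * pert
      applicable <- names(pert) %in% c(.growth_names, names(arm_spec$agent_effect))
      ch_spec <- .update_spec(arm_spec, as.list(true_vals[applicable]))
      if (design$include_dead || !.fast_path_ok(ch_spec)) {
        traj <- simulate_trajectory(ch_spec, tg)
        idx <- match(tt, traj$times)
        live <- traj$B[idx]
        dead <- if (design$include_dead) traj$D[idx]
      } else {
        live <- .predict_series(ch_spec, tt, "live", cache = .fast_cache(ch_spec, tt))
        dead <- NULL
      }
      eid <- sprintf("E%d", k); chid <- sprintf("C%d", cidx)
      emit <- function(path, comp) {
        y <- path + stats::rnorm(length(path), 0, design$sigma)
        n_trunc <<- n_trunc + sum(y < 0)
        series_data(tt, pmax(y, 0), experiment_id = eid, channel_id = chid,
                    variable = design$variable, compartment = comp, unit = design$unit)
      }
      out[[length(out) + 1L]] <- emit(live, "live")
      specs[[length(specs) + 1L]] <- ch_spec
      truth[[length(truth) + 1L]] <- data.frame(
        experiment_id = eid, channel_id = chid, arm = arm,
        t(true_vals))
      if (design$include_dead) out[[length(out) + 1L]] <- emit(dead, "dead")
    }
  }
  attr(out, "truth") <- list(channels = do.call(rbind, truth), n_truncated = n_trunc,
                             seed = seed)
  attr(out, "specs") <- specs
  out
}

#' Built-in study-design presets
#'
#' Named designs reproducing the package's reference simulation studies:
#' \describe{
#'   \item{fig1}{Noise-free logistic curve, B0 = 0.001, kb = 6,
#'     Bmax = 1, 25 points on [0, 2] (time in arbitrary units).}
#'   \item{fig2a / fig2b}{Same parameters with additive noise SD 0.1;
#'     logistic (a) or Gompertz (b) generating model.  Used for the
#'     model-indistinguishability study.}
#'   \item{fig3a / fig3b}{Bertalanffy generating model, kb = 4, kd = 2,
#'     delta = 1, lam = 0.25 (a) or 0.1 (b), B0 = 0.001, noise SD 0.1.
#'     Used for the model-discrimination study.}
#'   \item{table1}{Two-drug population design: logistic growth
#'     (B0 = 1, kb = 0.0425 1/h, Bmax = 39.5 um^3/um^2) with a
#'     linear-interaction kill (k1 = 0.00301, k2 = 0.00352 1/h/cu,
#'     k12 = 0.000473 1/h/cu^2; 1 cu = 1000 ng/mL = 1 mg/L, so the
#'     MEM/TOB presets in mg/L feed the model directly), inter-channel
#'     CVs 21.8/11.1/14.8/20.9/7.1 %, residual SD 8.02; 7 experiments
#'     of 2 channels sampled every 12 h over 0-168 h.  One arm per
#'     experiment: control, single MEM bolus at 24 h, single TOB bolus
#'     at 24 h, triple MEM at 74 h, triple TOB at 74 h, combined MEM
#'     infusion + TOB bolus at 72 h, control.  Administering the
#'     single- and triple-dose arms per drug keeps the individual kill
#'     rates k1 and k2 identifiable; only the 72-h arm combines drugs.}
#'   \item{example1_thickness}{Single-channel logistic average-thickness
#'     series, Bmax = 52.1 um, kb = 0.051 1/h, B0 = 1 um, residual SD
#'     8.02, 15 points over 0-168 h.}
#' }
#' Time grids not fixed by the reference designs are package choices
#' (see the methods vignette) and can be edited on the returned object.
#'
#' @param name Preset name.
#' @return A [population_design()].
#' @examples
#' d <- design_preset("fig2a")
#' dat <- generate_dataset(d, seed = 1)
#' @export
design_preset <- function(name = c("fig1", "fig2a", "fig2b", "fig3a", "fig3b",
                                   "table1", "example1_thickness")) {
  if (missing(name) || !name[1] %in% eval(formals(design_preset)$name))
    stop("unknown preset; available: fig1, fig2a, fig2b, fig3a, fig3b, table1, example1_thickness")
  name <- match.arg(name)
  grid_fig <- seq(0, 2, length.out = 25)
  switch(name,
    fig1 = population_design(
      model_spec(growth_params("logistic", B0 = 0.001, kb = 6, Bmax = 1)),
      grid_fig, sigma = 0, variable = "biomass", unit = "au"),
    fig2a = population_design(
      model_spec(growth_params("logistic", B0 = 0.001, kb = 6, Bmax = 1)),
      grid_fig, sigma = 0.1, variable = "biomass", unit = "au"),
    fig2b = population_design(
      model_spec(growth_params("gompertz", B0 = 0.001, kb = 6, Bmax = 1)),
      grid_fig, sigma = 0.1, variable = "biomass", unit = "au"),
    fig3a = population_design(
      model_spec(growth_params("bertalanffy", B0 = 0.001, kb = 4, kd = 2,
                               lam = 0.25, delta = 1)),
      grid_fig, sigma = 0.1, variable = "biomass", unit = "au"),
    fig3b = population_design(
      model_spec(growth_params("bertalanffy", B0 = 0.001, kb = 4, kd = 2,
                               lam = 0.1, delta = 1)),
      grid_fig, sigma = 0.1, variable = "biomass", unit = "au"),
    table1 = population_design(
      model_spec(growth_params("logistic", B0 = 1, kb = 0.0425, Bmax = 39.5),
                 agent_effect = two_agent_params("linear_interaction",
                                                 theta1 = 0.00301, theta2 = 0.00352,
                                                 theta3 = 0.000473),
                 pk = list(pk_preset("MEM", 24), pk_preset("TOB", 24))),
      seq(0, 168, by = 12),
      n_experiments = 7, channels_per_experiment = 2,
      cv_percent = c(Bmax = 21.8, kb = 11.1, theta1 = 14.8,
                     theta2 = 20.9, theta3 = 7.1),
      sigma = 8.02,
      arms = c("control", "mem_single_24", "tob_single_24", "mem_triple_74",
               "tob_triple_74", "combined_72", "control"),
      variable = "biomass", unit = "um^3/um^2"),
    example1_thickness = population_design(
      model_spec(growth_params("logistic", B0 = 1, kb = 0.051, Bmax = 52.1)),
      seq(0, 168, by = 12), sigma = 8.02,
      variable = "avg_thickness", unit = "um"))
}
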