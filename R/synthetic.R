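#' Measurement noise model for synthetic experiments
#'
#' Synthetic samples are perturbed multiplicatively with a mean-one
#' lognormal factor whose coefficient of variation is `cv`; `kind = "none"`
#' returns the model trajectory exactly. The default cv of 12.5% sits at the
#' midpoint of the 10–15% spatial variability band estimated for serial
#' brain biopsies.
#'
#' @param kind `"multiplicative-lognormal"` or `"none"`.
#' @param cv coefficient of variation as a fraction (default 0.125).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative-lognormal", "none"),
                        cv = 0.125) {
  kind <- match.arg(kind)
  if (!is.finite(cv) || cv < 0) stop("cv must be a nonnegative fraction")
  structure(list(kind = kind, cv = cv), class = "noise_model")
}

# mean-one lognormal multipliers with coefficient of variation cv
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Infusion paradigm specification for synthetic experiments
#'
#' Describes one of the three experiment designs: a 15 mg/kg loading bolus
#' (150 mg kg^-1 min^-1 for 6 s) followed by washout, a one-hour constant
#' infusion at 2 mg kg^-1 min^-1, or a TCI session holding a targeted
#' brain concentration. Default sampling respects the in-vivo limits of at
#' most 8 brain biopsies and 3 blood draws per animal: brain biopsies are
#' spaced geometrically after a bolus (dense early, where the kinetics are
#' fast) and evenly through constant/TCI infusions; blood draws are two
#' interior punctures plus one terminal sample.
#'
#' @param kind `"bolus"`, `"constant"` or `"tci"`.
#' @param target targeted brain concentration (ug/g), required for
#'   `kind = "tci"`.
#' @param duration observation horizon in seconds (default 3600).
#' @param rate infusion rate for `"bolus"` / `"constant"` paradigms.
#' @param bolus_duration bolus length in seconds (default 6).
#' @param n_brain,n_blood sample counts (defaults 8 and 3; larger values
#'   warn).
#' @param brain_times,blood_times optional explicit sampling times
#'   (seconds), overriding the defaults.
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(kind = c("bolus", "constant", "tci"),
                          target = NULL, duration = 3600,
                          rate = NULL, bolus_duration = 6,
                          n_brain = 8, n_blood = 3,
                          brain_times = NULL, blood_times = NULL) {
  kind <- match.arg(kind)
  if (kind == "tci") {
    if (is.null(target) || !is.finite(target) || target <= 0)
      stop("a tci paradigm needs a positive target concentration")
  }
  if (is.null(rate)) rate <- switch(kind, bolus = 150, constant = 2, NA)
  stopifnot(duration > 0, n_brain >= 1, n_blood >= 0)
  if (is.null(brain_times)) {
    brain_times <- if (kind == "bolus")
      exp(seq(log(30), log(duration), length.out = n_brain))
    else
      seq(duration / n_brain, duration, length.out = n_brain)
  }
  if (is.null(blood_times) && n_blood > 0) {
    blood_times <- duration * seq_len(n_blood) / n_blood
  }
  structure(list(kind = kind, target = target, duration = duration,
                 rate = rate, bolus_duration = bolus_duration,
                 brain_times = sort(brain_times),
                 blood_times = sort(blood_times)),
            class = "paradigm_spec")
}

#' The standard four-paradigm design
#'
#' Bolus, one-hour constant infusion, and TCI at each validation target —
#' the combined design from which the model constants are identifiable.
#'
#' @param targets TCI brain targets in ug/g (default `c(10, 15)`).
#' @param duration horizon per experiment in seconds.
#' @return List of [paradigm_spec] objects.
#' @export
standard_paradigms <- function(targets = c(10, 15), duration = 3600) {
  c(list(paradigm_spec("bolus", duration = duration),
         paradigm_spec("constant", duration = duration)),
    lapply(targets, function(tg)
      paradigm_spec("tci", target = tg, duration = duration)))
}

# build the infusion schedule a paradigm prescribes under `params`
paradigm_schedule <- function(params, spec) {
  switch(spec$kind,
    bolus = bolus_schedule(rate = spec$rate, duration = spec$bolus_duration,
                           horizon = spec$duration),
    constant = constant_schedule(rate = spec$rate, duration = spec$duration),
    tci = plan_tci(params, target = spec$target,
                   duration = spec$duration)$schedule)
}

#' Generate one synthetic experiment
#'
#' Simulates an animal under the paradigm's infusion schedule with the
#' exact propagator, samples blood and brain at the paradigm's times, and
#' applies the measurement noise model. With `noise_model("none")` the
#' samples lie exactly on the model trajectory, so the fitting objective at
#' the generating parameters is zero.
#'
#' @param params generating [pk_params].
#' @param spec a [paradigm_spec].
#' @param noise a [noise_model].
#' @param weight body weight in grams (default 27.4, the adult mouse mean).
#' @param seed RNG seed; identical seeds give byte-identical experiments.
#' @param animal_id identifier for the generated animal.
#' @param plan_params parameters handed to the TCI planner when the
#'   paradigm is `"tci"` (default `params`). Passing a fitted parameter set
#'   here while `params` stays at the generating truth emulates a
#'   validation experiment: the pump follows the fitted model, the animal
#'   follows the true kinetics.
#' @return A [pk_experiment].
#' @examples
#' e <- sim_experiment(mouse_pk_params(), paradigm_spec("constant"),
#'                     noise_model("none"), seed = 1)
#' e
#' @export
sim_experiment <- function(params, spec, noise = noise_model(),
                           weight = 27.4, seed = NULL,
                           animal_id = "synthetic_1", plan_params = params) {
  stopifnot(inherits(params, "pk_params"), inherits(spec, "paradigm_spec"),
            inherits(noise, "noise_model"))
  schedule <- paradigm_schedule(plan_params, spec)
  if (max(c(spec$brain_times, spec$blood_times)) >
      schedule_duration(schedule))
    stop("sampling time beyond the schedule horizon")
  times <- c(spec$brain_times, spec$blood_times)
  comp <- c(rep("brain", length(spec$brain_times)),
            rep("blood", length(spec$blood_times)))
  tr <- simulate_lti(params, schedule, times)
  truth <- ifelse(comp == "brain", tr$x2, tr$x1)
  conc <- if (noise$kind == "none") truth else
    truth * with_seed(seed, lognormal_factors(length(truth), noise$cv))
  pk_experiment(animal_id, weight, schedule,
                data.frame(time_s = times, compartment = comp,
                           concentration = conc))
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n_per_spec[i]` animals under each paradigm, with per-animal seeds
#' derived deterministically from the master seed and body weights from a
#' truncated-positive normal (mean 27.4 g, sd 1.5 g, the adult mouse
#' range).
#'
#' @param params generating [pk_params].
#' @param specs list of [paradigm_spec] objects.
#' @param n_per_spec animals per paradigm (recycled to `length(specs)`).
#' @param noise a [noise_model].
#' @param seed master RNG seed.
#' @param weight_mean,weight_sd body-weight distribution in grams.
#' @return List of [pk_experiment] objects.
#' @examples
#' cohort <- sim_cohort(mouse_pk_params(), standard_paradigms(),
#'                      n_per_spec = 1, noise = noise_model("none"),
#'                      seed = 1)
#' length(cohort)
#' @export
sim_cohort <- function(params, specs, n_per_spec = 1,
                       noise = noise_model(), seed = 1,
                       weight_mean = 27.4, weight_sd = 1.5) {
  stopifnot(is.list(specs), length(specs) >= 1)
  n_per_spec <- rep_len(n_per_spec, length(specs))
  if (any(n_per_spec < 1)) stop("n_per_spec must be at least 1")
  total <- sum(n_per_spec)
  draws <- with_seed(seed, {
    w <- rnorm(total, weight_mean, weight_sd)
    while (any(w <= 0))
      w[w <= 0] <- rnorm(sum(w <= 0), weight_mean, weight_sd)
    list(weights = w, seeds = sample.int(.Machine$integer.max - 1L, total))
  })
  k <- 0L
  out <- list()
  for (s in seq_along(specs)) {
    for (a in seq_len(n_per_spec[s])) {
      k <- k + 1L
      out[[k]] <- sim_experiment(
        params, specs[[s]], noise,
        weight = draws$weights[k], seed = draws$seeds[k],
        animal_id = sprintf("%s%d_%d", specs[[s]]$kind, s, a))
    }
  }
  out
}
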