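#' Normalized prediction error of one experiment
#'
#' The per-animal error is the squared Euclidean distance between all
#' measurements of the experiment (blood and brain pooled with equal unit
#' weight) and the model predictions at the same times, divided by the
#' number of measurements in that experiment. Setting `squared = FALSE`
#' gives the unsquared reading (Euclidean distance over sample count)
#' instead; the squared norm is the default.
#'
#' @param params a [pk_params] object.
#' @param experiment a [pk_experiment].
#' @param squared use the squared norm (default) or the plain Euclidean
#'   distance in the numerator.
#' @return Nonnegative scalar; exactly 0 when every prediction equals the
#'   corresponding measurement.
#' @export
experiment_error <- function(params, experiment, squared = TRUE) {
  r <- experiment$samples$concentration - predict_samples(params, experiment)
  if (squared) sum(r^2) / length(r) else sqrt(sum(r^2)) / length(r)
}

#' Joint fitting objective over a cohort
#'
#' The cohort objective G is the arithmetic mean over animals of the
#' normalized per-experiment error, so every animal contributes equally
#' regardless of how many samples it carries.
#'
#' @inheritParams experiment_error
#' @param experiments nonempty list of [pk_experiment] objects.
#' @return Nonnegative scalar.
#' @export
pk_objective <- function(params, experiments, squared = TRUE) {
  if (!is.list(experiments) || length(experiments) < 1L)
    stop("at least one experiment is required")
  mean(vapply(experiments, function(e) experiment_error(params, e, squared),
              numeric(1)))
}

# Pre-digest a cohort for fast repeated objective evaluation: experiments
# sharing one (schedule, sample-time) design are simulated once per
# parameter set. Returns groups with rates/step/times (minutes) and, per
# member experiment, the compartment row (1 blood, 2 brain) and measured
# values at each time index.
compile_cohort <- function(experiments) {
  keys <- vapply(experiments, function(e) {
    paste(e$schedule$step, paste(e$schedule$rates, collapse = ","),
          paste(sort(unique(e$samples$time_s)), collapse = ","), sep = "|")
  }, character(1))
  lapply(split(seq_along(experiments), keys), function(idx) {
    e1 <- experiments[[idx[1]]]
    times <- sort(unique(e1$samples$time_s))
    sched <- pad_schedule(e1$schedule, max(times))
    members <- lapply(idx, function(i) {
      s <- experiments[[i]]$samples
      list(row = ifelse(s$compartment == "brain", 2L, 1L),
           col = match(s$time_s, times),
           measured = s$concentration,
           n = nrow(s))
    })
    list(rates = sched$rates, step_min = sched$step / 60,
         times_min = times / 60, members = members)
  })
}

# objective on the compiled cohort at log-parameter vector `theta`
# (order k10, k12, k13, k21, k31, s_inf); returns mean per-animal error
objective_compiled <- function(theta, cohort, n_animals, squared = TRUE) {
  p <- exp(theta)
  A <- matrix(c(-(p[2] + p[3] + p[1]), p[4], p[5],
                p[2], -p[4], 0,
                p[3], 0, -p[5]), nrow = 3, byrow = TRUE)
  b <- c(1 / p[6], 0, 0)
  total <- 0
  for (g in cohort) {
    states <- lti_propagate_cpp(A, b, g$rates, g$step_min, g$times_min,
                                c(0, 0, 0))
    for (m in g$members) {
      r <- m$measured - states[cbind(m$row, m$col)]
      total <- total + if (squared) sum(r^2) / m$n else sqrt(sum(r^2)) / m$n
    }
  }
  total / n_animals
}

param_order <- c("k10", "k12", "k13", "k21", "k31", "s_inf")

#' Fit the three-compartment model to a cohort of experiments
#'
#' Minimizes the joint objective [pk_objective] subject to the constraint
#' that all six constants are nonnegative, by constrained local minimization
#' (L-BFGS-B on log-transformed parameters) launched from `n_starts` random
#' starting parameter sets drawn log-uniformly — rate constants over
#' \eqn{[10^{-3}, 10]} min^-1 and `s_inf` over \eqn{[0.01, 5]} L/kg. The
#' best solutions of the round are retained (up to 100) so a later round can
#' restart from them via [refit_pk]. Runs a cheap first pass over all starts
#' and then polishes the leading solutions to tight tolerance.
#'
#' @param experiments nonempty list of [pk_experiment] objects.
#' @param n_starts number of random multi-starts (default 100).
#' @param seed RNG seed making the fit reproducible.
#' @param squared objective variant, see [experiment_error].
#' @param starts optional matrix of explicit starting parameter sets
#'   (columns `k10, k12, k13, k21, k31, s_inf`), used instead of random
#'   starts.
#' @param n_polish number of leading solutions re-optimized at tight
#'   tolerance after the first pass.
#' @return An object of class `pk_fit`: `params` (the best [pk_params]),
#'   `objective`, `per_experiment_errors`, `residuals` (per-sample data
#'   frame), `n_starts`, `best_starts` (up to top 100 solutions, ordered),
#'   `seed`, and `underdetermined` (TRUE when the cohort carries fewer
#'   samples than parameters, in which case many parameter sets reach an
#'   equal objective and a warning is raised).
#' @examples
#' \donttest{
#' p <- mouse_pk_params()
#' e <- sim_experiment(p, paradigm_spec("constant"), noise_model("none"),
#'                     seed = 1)
#' fit <- fit_pk(list(e), n_starts = 10, seed = 1)
#' fit$objective
#' }
#' @export
fit_pk <- function(experiments, n_starts = 100, seed = 1, squared = TRUE,
                   starts = NULL, n_polish = 5) {
  if (!is.list(experiments) || length(experiments) < 1L)
    stop("at least one experiment is required")
  if (is.null(starts) && n_starts < 1L)
    stop("n_starts must be at least 1")
  cohort <- compile_cohort(experiments)
  n_animals <- length(experiments)
  n_samples <- sum(vapply(experiments, function(e) nrow(e$samples),
                          integer(1)))
  underdetermined <- n_samples < length(param_order)
  if (underdetermined)
    warning("fewer samples than parameters: the fit is under-determined ",
            "(many parameter sets reach an equal objective)")

  fn <- function(theta) objective_compiled(theta, cohort, n_animals, squared)
  lo <- rep(log(1e-8), 6)
  hi <- rep(log(1e3), 6)

  if (is.null(starts)) {
    starts <- with_seed(seed, {
      k <- matrix(runif(5 * n_starts, log(1e-3), log(10)), ncol = 5)
      cbind(k, runif(n_starts, log(0.01), log(5)))
    })
  } else {
    starts <- log(as.matrix(starts)[, , drop = FALSE])
    if (ncol(starts) != 6L) stop("starts must have six columns")
  }

  run_start <- function(theta0, factr, maxit) {
    res <- tryCatch(
      optim(pmin(pmax(theta0, lo), hi), fn, method = "L-BFGS-B",
            lower = lo, upper = hi,
            control = list(factr = factr, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    list(theta = res$par, objective = res$value)
  }

  sols <- lapply(seq_len(nrow(starts)),
                 function(i) run_start(starts[i, ], factr = 1e7, maxit = 200))
  ok <- !vapply(sols, is.null, logical(1))
  if (!any(ok)) stop("no start converged")
  sols <- sols[ok]
  ord <- order(vapply(sols, `[[`, numeric(1), "objective"))
  sols <- sols[ord]

  # polish the leading solutions at tight tolerance (objective ~1e-10 scale)
  for (i in seq_len(min(n_polish, length(sols)))) {
    pol <- run_start(sols[[i]]$theta, factr = 10, maxit = 2000)
    if (!is.null(pol) && pol$objective <= sols[[i]]$objective)
      sols[[i]] <- pol
  }
  ord <- order(vapply(sols, `[[`, numeric(1), "objective"))
  sols <- sols[ord]

  best <- sols[[1]]
  params <- do.call(pk_params, as.list(stats::setNames(exp(best$theta),
                                                       param_order)))
  per_err <- vapply(experiments, function(e)
    experiment_error(params, e, squared), numeric(1))
  residuals <- do.call(rbind, lapply(experiments, function(e) {
    pred <- predict_samples(params, e)
    data.frame(animal_id = e$animal_id, time_s = e$samples$time_s,
               compartment = e$samples$compartment,
               measured = e$samples$concentration, predicted = pred,
               residual = e$samples$concentration - pred)
  }))
  best_starts <- lapply(head(sols, 100), function(s)
    list(params = stats::setNames(exp(s$theta), param_order),
         objective = s$objective))
  structure(list(params = params, objective = mean(per_err),
                 per_experiment_errors = per_err, residuals = residuals,
                 n_starts = nrow(starts), best_starts = best_starts,
                 seed = seed, squared = squared,
                 underdetermined = underdetermined),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("PK fit over %d experiment(s), %d starts, objective %.4g\n",
              length(x$per_experiment_errors), x$n_starts, x$objective))
  print(x$params)
  invisible(x)
}

#' Refit warm-started from a previous round's solutions
#'
#' Restarts the constrained minimization from the retained top solutions of
#' a previous fit, typically after new experiments have been added to the
#' cohort. The returned objective never exceeds the objective of any reused
#' start evaluated on the new experiment set.
#'
#' @param previous a `pk_fit` with nonempty `best_starts`.
#' @param experiments the (possibly extended) experiment list.
#' @param ... passed to [fit_pk] (e.g. `squared`, `n_polish`).
#' @return A `pk_fit`.
#' @export
refit_pk <- function(previous, experiments, ...) {
  stopifnot(inherits(previous, "pk_fit"))
  if (length(previous$best_starts) < 1L)
    stop("previous fit retained no solutions to restart from")
  starts <- do.call(rbind, lapply(previous$best_starts, `[[`, "params"))
  fit_pk(experiments, starts = starts, seed = previous$seed, ...)
}

#' Write a fit report as JSON (plus a residual table CSV)
#'
#' @param fit a `pk_fit`.
#' @param path JSON output path; the residual table is written next to it
#'   with suffix `_residuals.csv`.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pk_fit"))
  report <- list(params = unclass(fit$params), objective = fit$objective,
                 per_experiment_errors = as.list(fit$per_experiment_errors),
                 n_starts = fit$n_starts, seed = fit$seed,
                 underdetermined = fit$underdetermined)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  write_csv_full(fit$residuals, sub("\\.json$", "_residuals.csv", path))
  invisible(path)
}
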