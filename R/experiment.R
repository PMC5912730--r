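#' A single animal's infusion experiment
#'
#' Couples one animal's infusion schedule with its timed, labeled
#' concentration samples (brain biopsies in ug/g, blood draws in ug/mL).
#' Exceeding the practical in-vivo sampling limits — 8 brain biopsies and 3
#' blood draws per animal — raises a warning, not an error, so simulated
#' designs may explore denser sampling.
#'
#' @param animal_id identifier (character or numeric).
#' @param body_weight body weight in grams.
#' @param schedule an [infusion_schedule].
#' @param samples data frame with columns `time_s` (seconds from infusion
#'   start), `compartment` (`"blood"` or `"brain"`) and `concentration`
#'   (nonnegative).
#' @return An object of class `pk_experiment`.
#' @export
pk_experiment <- function(animal_id, body_weight, schedule, samples) {
  stopifnot(inherits(schedule, "infusion_schedule"),
            is.finite(body_weight), body_weight > 0)
  need <- c("time_s", "compartment", "concentration")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop("samples must be a data frame with columns: ",
         paste(need, collapse = ", "))
  if (nrow(samples) < 1L)
    stop("an experiment needs at least one sample")
  samples$compartment <- as.character(samples$compartment)
  if (!all(samples$compartment %in% c("blood", "brain")))
    stop("compartment must be 'blood' or 'brain'")
  if (any(samples$time_s < 0) || any(samples$concentration < 0))
    stop("sample times and concentrations must be nonnegative")
  if (any(samples$time_s > schedule_duration(schedule)))
    stop("sample time exceeds the schedule horizon")
  n_brain <- sum(samples$compartment == "brain")
  n_blood <- sum(samples$compartment == "blood")
  if (n_brain > 8L)
    warning(sprintf("animal %s: %d brain samples exceeds the 8-biopsy limit",
                    animal_id, n_brain))
  if (n_blood > 3L)
    warning(sprintf("animal %s: %d blood samples exceeds the 3-draw limit",
                    animal_id, n_blood))
  structure(list(animal_id = as.character(animal_id),
                 body_weight = body_weight,
                 schedule = schedule,
                 samples = samples[order(samples$time_s), need]),
            class = "pk_experiment")
}

#' @export
print.pk_experiment <- function(x, ...) {
  cat(sprintf(
    "PK experiment %s (%.1f g): %d brain + %d blood samples over %.1f min\n",
    x$animal_id, x$body_weight,
    sum(x$samples$compartment == "brain"),
    sum(x$samples$compartment == "blood"),
    max(x$samples$time_s) / 60))
  invisible(x)
}

#' Model predictions at an experiment's sample times
#'
#' Evaluates the exact model trajectory at each sample time and returns the
#' concentration of the sampled compartment (blood: x1, brain: x2).
#'
#' @param params a [pk_params] object.
#' @param experiment a [pk_experiment].
#' @return Numeric vector aligned with `experiment$samples`.
#' @export
predict_samples <- function(params, experiment) {
  tr <- simulate_lti(params, experiment$schedule, experiment$samples$time_s)
  ifelse(experiment$samples$compartment == "brain", tr$x2, tr$x1)
}

#' Read / write experiment cohorts as CSV
#'
#' Sample dialect: columns `animal_id, weight_g, time_s, compartment,
#' concentration`, one row per sample; each animal's schedule is supplied
#' separately (a single shared [infusion_schedule] or a named list keyed by
#' `animal_id`).
#'
#' @param path file path.
#' @param schedules an [infusion_schedule] shared by all animals, or a named
#'   list of schedules keyed by animal id.
#' @param experiments a list of [pk_experiment] objects.
#' @return `read_experiments` returns a list of [pk_experiment];
#'   `write_experiments` returns `path` invisibly.
#' @export
read_experiments <- function(path, schedules) {
  d <- read.csv(path)
  need <- c("animal_id", "weight_g", "time_s", "compartment", "concentration")
  if (!all(need %in% names(d)))
    stop("experiment CSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(as.character(d$animal_id))
  lapply(ids, function(id) {
    di <- d[as.character(d$animal_id) == id, ]
    sch <- if (inherits(schedules, "infusion_schedule")) schedules
           else schedules[[id]]
    if (is.null(sch))
      stop("no schedule supplied for animal ", id)
    pk_experiment(id, di$weight_g[1], sch,
                  di[, c("time_s", "compartment", "concentration")])
  })
}

#' @rdname read_experiments
#' @export
write_experiments <- function(experiments, path) {
  rows <- lapply(experiments, function(e)
    data.frame(animal_id = e$animal_id, weight_g = e$body_weight,
               e$samples))
  d <- do.call(rbind, rows)
  names(d) <- c("animal_id", "weight_g", "time_s", "compartment",
                "concentration")
  write_csv_full(d, path)
  invisible(path)
}
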