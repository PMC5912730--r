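#' Piecewise-constant infusion schedule
#'
#' An infusion schedule is an ordered vector of nonnegative rates
#' (mg kg^-1 min^-1) on a uniform time grid: `rates[i]` applies on the
#' half-open interval `[(i-1) step, i step)` seconds.
#'
#' @param rates nonnegative infusion rates (mg kg^-1 min^-1), one per grid
#'   interval.
#' @param step grid interval in seconds (default 10, the TCI time unit).
#'
#' @return An object of class `infusion_schedule`.
#' @examples
#' sch <- constant_schedule(rate = 2, duration = 3600)
#' total_dose(sch)  # 120 mg/kg over one hour
#' @export
infusion_schedule <- function(rates, step = 10) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("step must be a single positive number of seconds")
  rates <- as.numeric(rates)
  if (length(rates) < 1L || !all(is.finite(rates)))
    stop("rates must be a nonempty vector of finite numbers")
  if (any(rates < 0))
    stop("infusion rates must be nonnegative")
  structure(list(rates = rates, step = step), class = "infusion_schedule")
}

#' @export
print.infusion_schedule <- function(x, ...) {
  cat(sprintf(
    "Infusion schedule: %d x %gs steps (%.1f min), total dose %.4g mg/kg\n",
    length(x$rates), x$step, schedule_duration(x) / 60, total_dose(x)))
  invisible(x)
}

#' @rdname infusion_schedule
#' @param schedule an `infusion_schedule`.
#' @return `schedule_duration` returns the horizon in seconds;
#'   `total_dose` the delivered dose in mg kg^-1.
#' @export
schedule_duration <- function(schedule) {
  length(schedule$rates) * schedule$step
}

#' @rdname infusion_schedule
#' @export
total_dose <- function(schedule) {
  sum(schedule$rates) * schedule$step / 60
}

#' Standard infusion designs
#'
#' `bolus_schedule` delivers a brief high-rate infusion (default
#' 150 mg kg^-1 min^-1 for 6 s, i.e. a 15 mg kg^-1 bolus) followed by zero
#' rate up to `horizon`; the grid step equals the bolus duration so the dose
#' is represented exactly. `constant_schedule` holds one fixed rate (default
#' 2 mg kg^-1 min^-1 for one hour).
#'
#' @param rate infusion rate in mg kg^-1 min^-1.
#' @param duration bolus duration / infusion duration (seconds).
#' @param horizon schedule horizon in seconds (>= duration); the remainder
#'   is zero rate.
#' @param step grid step in seconds for `constant_schedule`.
#' @return An [infusion_schedule].
#' @export
bolus_schedule <- function(rate = 150, duration = 6, horizon = 3600) {
  stopifnot(duration > 0, horizon >= duration)
  n <- ceiling(horizon / duration)
  infusion_schedule(c(rate, rep(0, n - 1L)), step = duration)
}

#' @rdname bolus_schedule
#' @export
constant_schedule <- function(rate = 2, duration = 3600, step = 10,
                              horizon = duration) {
  stopifnot(horizon >= duration, duration >= step)
  n_on <- round(duration / step)
  n_off <- ceiling((horizon - duration) / step)
  infusion_schedule(c(rep(rate, n_on), rep(0, n_off)), step = step)
}

# extend a schedule with zero rate so that its horizon covers `horizon` s
pad_schedule <- function(schedule, horizon) {
  extra <- ceiling(max(0, horizon - schedule_duration(schedule)) /
                     schedule$step)
  if (extra > 0)
    schedule$rates <- c(schedule$rates, rep(0, extra))
  schedule
}

#' Read / write infusion schedules as CSV
#'
#' Dialect: columns `t_start_s, rate_mg_kg_min`, one row per grid interval;
#' a uniform grid step is enforced on read.
#'
#' @param path file path.
#' @param schedule an [infusion_schedule].
#' @return `read_schedule` returns an [infusion_schedule]; `write_schedule`
#'   returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  d <- read.csv(path)
  need <- c("t_start_s", "rate_mg_kg_min")
  if (!all(need %in% names(d)))
    stop("schedule CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$t_start_s), , drop = FALSE]
  if (nrow(d) == 1L)
    stop("schedule CSV needs at least two rows to define the grid step")
  steps <- diff(d$t_start_s)
  if (max(steps) - min(steps) > 1e-9 * max(steps))
    stop("schedule grid must be uniform")
  if (abs(d$t_start_s[1]) > 1e-9)
    stop("schedule must start at t = 0")
  infusion_schedule(d$rate_mg_kg_min, step = steps[1])
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "infusion_schedule"))
  d <- data.frame(
    t_start_s = (seq_along(schedule$rates) - 1L) * schedule$step,
    rate_mg_kg_min = schedule$rates)
  write_csv_full(d, path)
  invisible(path)
}

# CSV writer that preserves doubles to full precision (%.17g round-trips)
write_csv_full <- function(d, path) {
  num <- vapply(d, is.double, logical(1))
  d[num] <- lapply(d[num], function(x) sprintf("%.17g", x))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
}
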