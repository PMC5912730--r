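#' Predicted brain concentration of a schedule by convolution
#'
#' Because the model is linear and time-invariant, the brain response to any
#' schedule on the impulse-response grid is the discrete causal convolution
#' of the rate sequence with the brain impulse response:
#' `out[m] = sum_{i<=m} rates[i] h[m-i+1]`, the predicted concentration at
#' the end of grid interval `m`. `out[j]` depends only on rates up to `j`.
#'
#' @param schedule an [infusion_schedule].
#' @param impulse an [impulse_response] with the same grid step and horizon
#'   covering the schedule.
#' @param compartment which response series to convolve (default brain).
#' @return Numeric vector, concentration at grid-end times
#'   `step, 2 step, ...`.
#' @export
predict_brain <- function(schedule, impulse,
                          compartment = c("brain", "blood")) {
  stopifnot(inherits(schedule, "infusion_schedule"),
            inherits(impulse, "impulse_response"))
  compartment <- match.arg(compartment)
  if (abs(schedule$step - impulse$step) > 1e-9)
    stop("schedule and impulse response use different grid steps")
  h <- impulse[[compartment]]
  n <- length(schedule$rates)
  if (length(h) < n)
    stop("impulse response horizon shorter than the schedule")
  convolve_causal(schedule$rates, h[seq_len(n)])
}

# out[m] = sum_{i=1..m} r[i] h[m-i+1], via FFT convolution
convolve_causal <- function(r, h) {
  n <- length(r)
  if (n == 1L) return(r * h)
  stats::convolve(r, rev(h), type = "open")[seq_len(n)]
}

#' Plan a target-controlled infusion holding brain concentration
#'
#' Computes a piecewise-constant infusion schedule on a 10-s grid that
#' attains and then maintains a targeted brain concentration. The brain
#' impulse response peaks several steps after the impulse (drug must
#' transit the blood), so solving only for the end of the current step
#' would overshoot; instead each step's rate is chosen, peak-targeting
#' style, as the largest rate whose convolution-predicted brain
#' concentration never exceeds the target at any future grid point, and is
#' then polished by re-convolving the candidate schedule with the impulse
#' response until the constraint holds to floating precision. Rates are
#' clipped to `[0, max_rate]`. When the prediction already exceeds the
#' target the pump cannot withdraw drug: the rate floors at zero and the
#' excursion decays passively (reported, and exempt from the per-step
#' tolerance).
#'
#' @param params a [pk_params] object.
#' @param target brain concentration to hold (ug/g), nonnegative.
#' @param duration plan horizon in seconds (>= step).
#' @param step grid step in seconds (default 10, the TCI time unit).
#' @param tolerance maintenance tolerance as a fraction of target
#'   (default 0.05).
#' @param max_rate pump rate ceiling in mg kg^-1 min^-1 (default 150, the
#'   loading-bolus rate).
#' @param approach_cap maximum allowed approach time in seconds before the
#'   target is declared unreachable under `max_rate` (default 300).
#' @param max_iter per-step refinement iteration cap.
#' @return An object of class `tci_plan`: `target`, `params`, `schedule`,
#'   `predicted` (data frame `time_s, rate_mg_kg_min, brain, blood` at grid
#'   ends), `approach_end` (first grid time from which the prediction stays
#'   within tolerance), `max_relative_deviation` over the maintenance phase,
#'   and `tolerance`.
#' @examples
#' plan <- plan_tci(mouse_pk_params(), target = 10, duration = 600)
#' plan
#' @export
plan_tci <- function(params, target, duration = 3600, step = 10,
                     tolerance = 0.05, max_rate = 150, approach_cap = 300,
                     max_iter = 50) {
  stopifnot(inherits(params, "pk_params"), is.finite(target), target >= 0,
            duration >= step, tolerance > 0, max_rate > 0)
  n <- round(duration / step)
  if (abs(n * step - duration) > 1e-9)
    stop("duration must be a whole number of grid steps")
  imp <- impulse_response(params, step = step, horizon = duration)
  h <- imp$brain
  if (h[1] <= 0)
    stop("brain impulse gain is zero: k12 must be positive to target brain")

  rates <- numeric(n)
  # B[j]: brain concentration predicted at grid end j by convolving the
  # rates fixed so far with the impulse response (updated incrementally)
  B <- numeric(n)
  for (m in seq_len(n)) {
    js <- m:n
    hseg <- h[js - m + 1L]
    # largest rate that keeps every future predicted concentration at or
    # below target (closed form; the pump cannot withdraw drug, so 0 floors)
    r <- min(max_rate, max(0, min((target - B[js]) / hseg)))
    # polish: back off if accumulated rounding lets the peak creep above
    # target (exact arithmetic makes this loop a no-op)
    for (it in seq_len(max_iter)) {
      peak <- max(B[js] + r * hseg)
      if (peak <= target * (1 + 1e-12) || r == 0) break
      r <- max(0, r - (peak - target) / hseg[which.max(B[js] + r * hseg)])
    }
    rates[m] <- r
    if (r > 0) B[js] <- B[js] + r * hseg
  }
  pred <- B

  schedule <- infusion_schedule(rates, step = step)
  blood <- predict_brain(schedule, imp, compartment = "blood")
  grid <- seq_len(n) * step
  dev <- if (target > 0) abs(pred - target) / target else abs(pred)

  within <- dev <= tolerance + 1e-12
  ok_from <- if (all(within)) 1L else {
    last_bad <- max(which(!within))
    if (last_bad == n) NA_integer_ else last_bad + 1L
  }
  if (is.na(ok_from) || grid[ok_from] > approach_cap)
    stop(sprintf(
      "target %.3g unreachable within %.0f s under max rate %.3g",
      target, approach_cap, max_rate))
  approach_end <- grid[ok_from]
  maint <- seq.int(ok_from, n)
  structure(list(target = target, params = params, schedule = schedule,
                 predicted = data.frame(time_s = grid,
                                        rate_mg_kg_min = rates,
                                        brain = pred, blood = blood),
                 approach_end = approach_end,
                 max_relative_deviation = max(dev[maint]),
                 tolerance = tolerance),
            class = "tci_plan")
}

#' @export
print.tci_plan <- function(x, ...) {
  cat(sprintf(
    paste0("TCI plan: target %.3g ug/g over %.1f min (step %gs)\n",
           "  approach complete at %.0f s; ",
           "max maintenance deviation %.3g%%\n"),
    x$target, schedule_duration(x$schedule) / 60, x$schedule$step,
    x$approach_end, 100 * x$max_relative_deviation))
  invisible(x)
}

#' Convert a TCI plan to volumetric syringe-pump rates
#'
#' Converts each step's mass rate (mg kg^-1 min^-1) to the pump's
#' volumetric rate in mL/h for a given animal and drug dilution:
#' `mL/h = rate * weight_kg * 60 / drug_concentration`.
#'
#' @param plan a `tci_plan`.
#' @param body_weight_g animal body weight in grams (> 0).
#' @param drug_concentration syringe drug concentration in mg/mL
#'   (default 10, the standard propofol emulsion).
#' @return Data frame `t_start_s, rate_ml_h`, one row per grid interval.
#' @examples
#' plan <- plan_tci(mouse_pk_params(), target = 10, duration = 600)
#' head(export_pump_schedule(plan, body_weight_g = 27.4))
#' @export
export_pump_schedule <- function(plan, body_weight_g,
                                 drug_concentration = 10) {
  stopifnot(inherits(plan, "tci_plan"))
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("body weight must be positive")
  if (!is.finite(drug_concentration) || drug_concentration <= 0)
    stop("drug concentration must be positive")
  sch <- plan$schedule
  data.frame(
    t_start_s = (seq_along(sch$rates) - 1L) * sch$step,
    rate_ml_h = sch$rates * (body_weight_g / 1000) * 60 / drug_concentration)
}

#' Read / write TCI plans and pump tables as CSV
#'
#' Plan dialect: `t_start_s, rate_mg_kg_min, predicted_brain_ug_g,
#' predicted_blood_ug_ml`. Pump dialect: `t_start_s, rate_ml_h`;
#' `read_pump_schedule` inverts the unit conversion so the mass rates
#' round-trip exactly.
#'
#' @param plan a `tci_plan`.
#' @param path file path.
#' @param pump a pump table from [export_pump_schedule].
#' @param body_weight_g,drug_concentration conversion constants used when
#'   the table was exported.
#' @return Readers return data frames / schedules; writers return `path`
#'   invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "tci_plan"))
  d <- data.frame(
    t_start_s = (seq_along(plan$schedule$rates) - 1L) * plan$schedule$step,
    rate_mg_kg_min = plan$schedule$rates,
    predicted_brain_ug_g = plan$predicted$brain,
    predicted_blood_ug_ml = plan$predicted$blood)
  write_csv_full(d, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  d <- read.csv(path)
  need <- c("t_start_s", "rate_mg_kg_min", "predicted_brain_ug_g",
            "predicted_blood_ug_ml")
  if (!all(need %in% names(d)))
    stop("plan CSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname write_plan
#' @export
write_pump_schedule <- function(pump, path) {
  write_csv_full(pump, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_pump_schedule <- function(path, body_weight_g, drug_concentration = 10) {
  d <- read.csv(path)
  if (!all(c("t_start_s", "rate_ml_h") %in% names(d)))
    stop("pump CSV must have columns: t_start_s, rate_ml_h")
  steps <- diff(d$t_start_s)
  infusion_schedule(
    d$rate_ml_h * drug_concentration / (60 * body_weight_g / 1000),
    step = if (length(steps)) steps[1] else 10)
}
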