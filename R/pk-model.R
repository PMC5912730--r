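#' Right-hand side of the three-compartment model
#'
#' Evaluates the time derivative (per minute) of the blood, brain and
#' other-tissue concentrations:
#' \deqn{dx_1/dt = -(k_{12}+k_{13}+k_{10}) x_1 + k_{21} x_2 + k_{31} x_3 + I(t)/s_{inf}}
#' \deqn{dx_2/dt = k_{12} x_1 - k_{21} x_2}
#' \deqn{dx_3/dt = k_{13} x_1 - k_{31} x_3}
#' The derivative is linear both in the state and in the infusion rate.
#'
#' @param state numeric length-3 state `c(x1, x2, x3)`: blood (ug/mL),
#'   brain (ug/g), other tissue.
#' @param params a [pk_params] object.
#' @param rate infusion rate (mg kg^-1 min^-1), nonnegative.
#' @return Numeric length-3 derivative, per minute.
#' @export
pk_derivative <- function(state, params, rate = 0) {
  stopifnot(inherits(params, "pk_params"))
  if (length(state) != 3L || !all(is.finite(state)))
    stop("state must be three finite concentrations")
  if (!is.finite(rate) || rate < 0)
    stop("infusion rate must be finite and nonnegative")
  c(rate_matrix(params) %*% state + input_vector(params) * rate)
}

new_trajectory <- function(times, states, params) {
  stopifnot(ncol(states) == 3L, nrow(states) == length(times))
  structure(
    data.frame(time_s = times, x1 = states[, 1], x2 = states[, 2],
               x3 = states[, 3]),
    params = params, class = c("pk_trajectory", "data.frame"))
}

#' Exact trajectory of the model under a piecewise-constant infusion
#'
#' Because the model is linear and time-invariant (LTI), its solution over
#' each constant-rate grid interval is available in closed form through the
#' matrix exponential of an augmented system matrix. `simulate_lti`
#' propagates that closed form interval by interval and is exact to floating
#' precision for any piecewise-constant schedule; it serves as the reference
#' against which the adaptive integrator [simulate_pk] is checked, and as
#' the prediction engine of the fitting objective.
#'
#' @param params a [pk_params] object.
#' @param schedule an [infusion_schedule].
#' @param times evaluation times in seconds, nonnegative; times past the
#'   schedule horizon are simulated under zero rate (washout).
#' @param x0 initial state at t = 0 (default all-zero, drug-naive).
#' @return A `pk_trajectory` data frame with columns
#'   `time_s, x1, x2, x3` (blood ug/mL, brain ug/g, other tissue), rows in
#'   the order of `times`.
#' @examples
#' p <- mouse_pk_params()
#' tr <- simulate_lti(p, bolus_schedule(), times = c(30, 60, 300, 3600))
#' tr
#' @export
simulate_lti <- function(params, schedule, times, x0 = c(0, 0, 0)) {
  stopifnot(inherits(params, "pk_params"),
            inherits(schedule, "infusion_schedule"))
  times <- as.numeric(times)
  if (length(times) < 1L || !all(is.finite(times)) || any(times < 0))
    stop("times must be finite nonnegative seconds")
  if (length(x0) != 3L || !all(is.finite(x0)) || any(x0 < 0))
    stop("x0 must be three finite nonnegative concentrations")
  A <- rate_matrix(params)
  if (!all(is.finite(A)))
    stop("rate matrix has non-finite entries")
  schedule <- pad_schedule(schedule, max(times))
  ord <- order(times)
  out <- lti_propagate_cpp(A, input_vector(params), schedule$rates,
                           schedule$step / 60, times[ord] / 60, x0)
  states <- matrix(0, length(times), 3L)
  states[ord, ] <- t(out)
  new_trajectory(times, states, params)
}

#' Numerically integrated trajectory of the model
#'
#' Integrates the system with an adaptive solver (deSolve), restarting at
#' every rate changepoint so the discontinuous forcing never crosses an
#' integration step. Defaults follow common tight-tolerance practice
#' (`rtol = 1e-8`, `atol = 1e-10`); the exact propagator [simulate_lti] is
#' the reference implementation.
#'
#' @inheritParams simulate_lti
#' @param rtol,atol relative / absolute integration tolerances.
#' @param method a `deSolve` method name (default `"lsoda"`).
#' @return A `pk_trajectory` data frame, as [simulate_lti].
#' @export
simulate_pk <- function(params, schedule, times, x0 = c(0, 0, 0),
                        rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(params, "pk_params"),
            inherits(schedule, "infusion_schedule"))
  times <- as.numeric(times)
  if (length(times) < 1L || !all(is.finite(times)) || any(times < 0))
    stop("times must be finite nonnegative seconds")
  if (any(x0 < 0)) stop("x0 must be nonnegative")
  schedule <- pad_schedule(schedule, max(times))
  A <- rate_matrix(params)
  b <- input_vector(params)

  # merge consecutive equal rates into constant-rate segments (seconds)
  runs <- rle(schedule$rates)
  seg_rate <- runs$values
  seg_end <- cumsum(runs$lengths) * schedule$step
  seg_start <- c(0, seg_end[-length(seg_end)])

  rhs <- function(t, y, parms) list(c(A %*% y + b * parms) / 60)

  ord <- order(times)
  ts <- times[ord]
  states <- matrix(NA_real_, length(ts), 3L)
  x <- x0
  k <- 1L
  while (k <= length(ts) && ts[k] <= 0) {
    states[k, ] <- x0
    k <- k + 1L
  }
  for (s in seq_along(seg_rate)) {
    if (k > length(ts)) break
    inside <- which(ts > seg_start[s] & ts <= seg_end[s])
    tgrid <- unique(c(seg_start[s], ts[inside], seg_end[s]))
    sol <- deSolve::ode(y = x, times = tgrid, func = rhs,
                        parms = seg_rate[s], method = method,
                        rtol = rtol, atol = atol)
    if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
      stop("ODE solver failed to converge at the configured tolerance")
    if (length(inside)) {
      idx <- match(ts[inside], tgrid)
      states[inside, ] <- sol[idx, 2:4, drop = FALSE]
      k <- max(inside) + 1L
    }
    x <- sol[nrow(sol), 2:4]
  }
  out <- matrix(0, length(times), 3L)
  out[ord, ] <- states
  new_trajectory(times, pmax(out, 0), params)
}

#' Impulse response of the model on the TCI grid
#'
#' The impulse response is the modeled concentration response to a
#' unit-rate infusion (1 mg kg^-1 min^-1) applied for a single grid step,
#' starting from zero state. `h[j]` is the concentration at time `j * step`
#' seconds after the impulse onset; by linearity the response to any
#' schedule on the same grid is the discrete causal convolution of its rates
#' with `h` (see [predict_brain]).
#'
#' @param params a [pk_params] object.
#' @param step grid step in seconds (default 10).
#' @param horizon response horizon in seconds (>= step).
#' @return An object of class `impulse_response`: list with `step`, `times`
#'   (grid-end times, seconds) and the `brain` and `blood` response series.
#' @export
impulse_response <- function(params, step = 10, horizon = 3600) {
  stopifnot(horizon >= step)
  n <- ceiling(horizon / step)
  grid <- seq_len(n) * step
  tr <- simulate_lti(params, infusion_schedule(c(1, rep(0, n - 1L)), step),
                     times = grid)
  structure(list(step = step, times = grid, brain = tr$x2, blood = tr$x1),
            class = "impulse_response")
}

#' Read / write concentration trajectories as CSV
#'
#' Dialect: `time_s, x1_ug_per_ml, x2_ug_per_g, x3`.
#'
#' @param trajectory a `pk_trajectory`.
#' @param path file path.
#' @return `read_trajectory` returns a `pk_trajectory`; `write_trajectory`
#'   returns `path` invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  d <- data.frame(time_s = trajectory$time_s,
                  x1_ug_per_ml = trajectory$x1,
                  x2_ug_per_g = trajectory$x2,
                  x3 = trajectory$x3)
  write_csv_full(d, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path)
  need <- c("time_s", "x1_ug_per_ml", "x2_ug_per_g", "x3")
  if (!all(need %in% names(d)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  new_trajectory(d$time_s, cbind(d$x1_ug_per_ml, d$x2_ug_per_g, d$x3),
                 params = NULL)
}
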