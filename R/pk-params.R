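#' Pharmacokinetic parameter set for the three-compartment model
#'
#' Bundles the six constants of the mouse propofol model: five first-order
#' rate constants (min^-1) and the infusion scaling constant `s_inf`
#' (L kg^-1, litres of central compartment per kg body weight) that converts
#' a weight-normalized infusion rate (mg kg^-1 min^-1) into a concentration
#' rate in blood. Compartment 1 is blood, compartment 2 brain, compartment 3
#' other tissue; drug enters and leaves only via compartment 1.
#'
#' @param k10 elimination rate constant from blood (min^-1).
#' @param k12,k13 blood-to-brain and blood-to-other-tissue rate constants
#'   (min^-1).
#' @param k21,k31 brain-to-blood and other-tissue-to-blood rate constants
#'   (min^-1).
#' @param s_inf infusion scaling constant (L kg^-1); must be positive.
#'
#' @return An object of class `pk_params`.
#' @examples
#' p <- pk_params(k10 = 0.07, k12 = 1.55, k13 = 0.22,
#'                k21 = 2.71, k31 = 0.04, s_inf = 0.35)
#' p
#' @export
pk_params <- function(k10, k12, k13, k21, k31, s_inf) {
  x <- c(k10 = k10, k12 = k12, k13 = k13, k21 = k21, k31 = k31,
         s_inf = s_inf)
  if (!all(is.finite(x)))
    stop("all PK constants must be finite numbers")
  if (any(x < 0))
    stop("all PK constants must be nonnegative")
  if (s_inf <= 0)
    stop("s_inf must be strictly positive")
  structure(as.list(x), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Three-compartment PK parameters (blood | brain | other tissue)\n")
  cat(sprintf("  k10 = %g  k12 = %g  k13 = %g  k21 = %g  k31 = %g (min^-1)\n",
              x$k10, x$k12, x$k13, x$k21, x$k31))
  cat(sprintf("  s_inf = %g L/kg\n", x$s_inf))
  invisible(x)
}

#' Reference parameter set for propofol in the adult mouse
#'
#' Returns the packaged reference constants of the final fitted mouse
#' propofol model, read from the JSON fixture shipped in
#' `inst/extdata/propofol_mouse_pk.json`. These are the defaults used by the
#' TCI planner examples and the synthetic-experiment generator.
#'
#' @return A [pk_params] object.
#' @export
mouse_pk_params <- function() {
  read_pk_params(system.file("extdata", "propofol_mouse_pk.json",
                             package = "mousetci", mustWork = TRUE))
}

#' Read / write PK parameters as JSON
#'
#' The JSON dialect is a flat object with keys
#' `k10, k12, k13, k21, k31, s_inf`.
#'
#' @param path file path.
#' @param params a [pk_params] object.
#' @return `read_pk_params` returns a [pk_params]; `write_pk_params` returns
#'   `path` invisibly.
#' @export
read_pk_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k10", "k12", "k13", "k21", "k31", "s_inf")
  if (!all(need %in% names(x)))
    stop("parameter JSON must contain keys: ", paste(need, collapse = ", "))
  do.call(pk_params, as.list(unlist(x[need])))
}

#' @rdname read_pk_params
#' @export
write_pk_params <- function(params, path) {
  stopifnot(inherits(params, "pk_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# system matrix A (min^-1) of dx/dt = A x + b I(t)
rate_matrix <- function(params) {
  with(params, matrix(c(
    -(k12 + k13 + k10), k21,  k31,
    k12,               -k21,  0,
    k13,                0,   -k31), nrow = 3, byrow = TRUE))
}

# input direction b: infusion (mg/kg/min) enters blood scaled by 1/s_inf
input_vector <- function(params) {
  c(1 / params$s_inf, 0, 0)
}

#' Closed-form steady state under a constant infusion
#'
#' For a constant rate `I` with all return paths open the system settles at
#' `x1 = I / (s_inf k10)`, `x2 = (k12/k21) x1`, `x3 = (k13/k31) x1`. When
#' `k10`, `k21` or `k31` is zero no finite steady state exists and an error
#' is signalled.
#'
#' @param params a [pk_params] object.
#' @param rate constant infusion rate (mg kg^-1 min^-1).
#' @return Named numeric vector `c(x1, x2, x3)`.
#' @export
steady_state <- function(params, rate) {
  stopifnot(inherits(params, "pk_params"), is.finite(rate), rate >= 0)
  if (params$k10 == 0 || params$k21 == 0 || params$k31 == 0)
    stop("no finite steady state: k10, k21 and k31 must all be positive")
  x1 <- rate / (params$s_inf * params$k10)
  c(x1 = x1,
    x2 = params$k12 / params$k21 * x1,
    x3 = params$k13 / params$k31 * x1)
}
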