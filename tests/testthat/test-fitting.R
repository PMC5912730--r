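# build an experiment whose measurements are the model predictions plus a
# chosen residual vector (4 brain samples on a short constant infusion)
experiment_with_residuals <- function(params, resid, id = "crafted") {
  sch <- constant_schedule(2, 600)
  times <- seq(150, 600, length.out = length(resid))
  pred <- simulate_lti(params, sch, times)$x2
  pk_experiment(id, 27.4, sch,
                data.frame(time_s = times, compartment = "brain",
                           concentration = pred + resid))
}

test_that("experiment error is the normalized squared prediction distance", {
  p <- ref_params

  # noise-free samples give exactly zero
  e0 <- sim_experiment(p, paradigm_spec("constant"), noise_model("none"),
                       seed = 1)
  expect_identical(experiment_error(p, e0), 0)

  # one brain sample offset by +1 gives error 1
  e1 <- experiment_with_residuals(p, 1)
  expect_equal(experiment_error(p, e1), 1, tolerance = 1e-12)

  # residuals (1, -1, 2, 0) give (1+1+4+0)/4 = 1.5
  e2 <- experiment_with_residuals(p, c(1, -1, 2, 0))
  expect_equal(experiment_error(p, e2), 1.5, tolerance = 1e-12)

  # the unsquared reading: Euclidean distance over sample count
  expect_equal(experiment_error(p, e2, squared = FALSE),
               sqrt(6) / 4, tolerance = 1e-12)
})

test_that("cohort objective is the mean per-animal error", {
  p <- ref_params
  e_a <- experiment_with_residuals(p, rep(0, 2), "a")            # error 0
  e_b <- experiment_with_residuals(p, sqrt(3), "b")              # error 3
  expect_equal(pk_objective(p, list(e_a)), experiment_error(p, e_a))
  expect_equal(pk_objective(p, list(e_a, e_b)), 1.5, tolerance = 1e-12)

  # invariant to the ordering of experiments and of samples within one
  e_c <- experiment_with_residuals(p, c(2, -1, 0.5, 1), "c")
  expect_equal(pk_objective(p, list(e_a, e_b, e_c)),
               pk_objective(p, list(e_c, e_a, e_b)))
  shuf <- e_c
  shuf$samples <- shuf$samples[c(3, 1, 4, 2), ]
  expect_equal(experiment_error(p, shuf), experiment_error(p, e_c))

  expect_error(pk_objective(p, list()), "at least one")
})

test_that("a noise-free cohort is fit back to near-zero objective", {
  p <- ref_params
  cohort <- sim_cohort(p, list(paradigm_spec("bolus"),
                               paradigm_spec("constant")),
                       n_per_spec = 1, noise = noise_model("none"), seed = 3)
  expect_equal(pk_objective(p, cohort), 0)
  fit <- fit_pk(cohort, n_starts = 25, seed = 5)
  expect_lt(fit$objective, 1e-6)
  expect_equal(fit$objective, mean(fit$per_experiment_errors))
  expect_true(all(unlist(fit$params) >= 0))
  expect_true(all(rel_err(unlist(fit$params), unlist(p)) < 0.02))
  expect_lte(length(fit$best_starts), 100)
  objs <- vapply(fit$best_starts, `[[`, numeric(1), "objective")
  expect_true(!is.unsorted(objs))
})

test_that("a single-sample fit is flagged as under-determined", {
  p <- ref_params
  sch <- constant_schedule(2, 600)
  e <- pk_experiment("one", 27.4, sch,
                     data.frame(time_s = 300, compartment = "brain",
                                concentration = 5))
  expect_warning(fit <- fit_pk(list(e), n_starts = 5, seed = 2),
                 "under-determined")
  expect_true(fit$underdetermined)
  expect_true(is.finite(fit$objective))
})

test_that("warm-started refits never lose ground", {
  p <- ref_params
  cohort <- sim_cohort(p, list(paradigm_spec("constant")), n_per_spec = 2,
                       noise = noise_model(cv = 0.1), seed = 9)
  fit1 <- fit_pk(cohort, n_starts = 12, seed = 4)

  # identical experiment set: objective does not increase
  fit2 <- refit_pk(fit1, cohort)
  expect_lte(fit2$objective, fit1$objective + 1e-12)

  # adding a noise-free experiment generated from the fitted model leaves
  # the solution on the data manifold: objective does not increase
  extra <- sim_experiment(fit1$params, paradigm_spec("bolus"),
                          noise_model("none"), seed = 1, animal_id = "new")
  start_obj <- pk_objective(fit1$params, c(cohort, list(extra)))
  fit3 <- refit_pk(fit1, c(cohort, list(extra)))
  expect_lte(fit3$objective, start_obj + 1e-12)
})

test_that("a warm restart matches a cold multi-start on conflicting data", {
  p <- ref_params
  cohort <- sim_cohort(p, list(paradigm_spec("constant")), n_per_spec = 1,
                       noise = noise_model("none"), seed = 9)
  fit1 <- fit_pk(cohort, n_starts = 12, seed = 4)
  # conflicting data: same design generated from different kinetics
  other <- pk_params(k10 = 0.12, k12 = 1.0, k13 = 0.3, k21 = 1.8,
                     k31 = 0.06, s_inf = 0.5)
  conflict <- sim_experiment(other, paradigm_spec("constant"),
                             noise_model("none"), seed = 2,
                             animal_id = "conflict")
  both <- c(cohort, list(conflict))
  warm <- refit_pk(fit1, both)
  cold <- fit_pk(both, n_starts = 25, seed = 11)
  expect_equal(warm$objective, cold$objective, tolerance = 1e-4)
})

test_that("denser brain sampling does not hurt noisy recovery", {
  p <- ref_params
  err_for <- function(n_brain, seed) {
    specs <- list(
      paradigm_spec("bolus", n_brain = n_brain),
      paradigm_spec("constant", n_brain = n_brain))
    cohort <- sim_cohort(p, specs, n_per_spec = 1,
                         noise = noise_model(cv = 0.1), seed = seed)
    fit <- fit_pk(cohort, n_starts = 10, seed = seed + 100)
    mean(rel_err(unlist(fit$params), unlist(p)))
  }
  seeds <- c(2, 3, 4)
  err4 <- mean(vapply(seeds, function(s) err_for(4, s), numeric(1)))
  err8 <- mean(vapply(seeds, function(s) err_for(8, s), numeric(1)))
  expect_lte(err8, err4)
})

test_that("experiment CSV and fit report round-trip", {
  tmp <- withr::local_tempdir()
  p <- ref_params
  cohort <- sim_cohort(p, list(paradigm_spec("constant")), n_per_spec = 2,
                       noise = noise_model(cv = 0.1), seed = 6)
  path <- file.path(tmp, "cohort.csv")
  write_experiments(cohort, path)
  back <- read_experiments(path, schedules = cohort[[1]]$schedule)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$samples$concentration,
               cohort[[1]]$samples$concentration)
  expect_equal(back[[2]]$body_weight, cohort[[2]]$body_weight)

  fit <- fit_pk(cohort, n_starts = 5, seed = 8)
  fj <- file.path(tmp, "fit.json")
  write_fit(fit, fj)
  rep <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(rep$objective, fit$objective)
  expect_equal(rep$params$k12, fit$params$k12)
  expect_true(file.exists(file.path(tmp, "fit_residuals.csv")))
})

test_that("sampling-limit violations warn but do not error", {
  sch <- constant_schedule(2, 600)
  s <- data.frame(time_s = seq(50, 590, length.out = 9),
                  compartment = "brain", concentration = 1)
  expect_warning(pk_experiment("m", 27, sch, s), "8-biopsy")
})
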