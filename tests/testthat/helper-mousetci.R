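# shared fixtures: the packaged mouse reference constants and a small
# random-parameter generator for property sweeps
ref_params <- mouse_pk_params()

random_params <- function() {
  pk_params(k10 = runif(1, 0.02, 0.5), k12 = runif(1, 0.2, 3),
            k13 = runif(1, 0.02, 0.5), k21 = runif(1, 0.2, 3),
            k31 = runif(1, 0.02, 0.5), s_inf = runif(1, 0.1, 1))
}

random_schedule <- function(n = 30, step = 10, max_rate = 5) {
  infusion_schedule(runif(n, 0, max_rate), step = step)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
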