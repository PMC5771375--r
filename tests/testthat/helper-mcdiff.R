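# shared fixture builders (everything generated in code)

# simulate trials and attach the standard rt_s column name
sim_cell <- function(n, params, dt = 1e-4, drift = NULL) {
  tr <- simulate_trials(n, params, dt = dt, drift = drift)
  tr$rt_s <- tr$rt
  tr
}

# minimal hand-built trial table (safe for zero-row inputs)
make_trials <- function(subject_id = "s1", task = "symbolic",
                        rt_s, correct, group = "con",
                        item_index = seq_along(rt_s)) {
  n <- length(rt_s)
  data.frame(subject_id = rep_len(subject_id, n),
             group = rep_len(group, n), task = rep_len(task, n),
             item_index = item_index, correct = correct, rt_s = rt_s,
             stringsAsFactors = FALSE)
}

# scaled-down population configuration for cohort-level tests
small_config <- function(n_con = 30, n_dys = 12) {
  cfg <- default_population_config()
  cfg$groups$con$n <- n_con
  cfg$groups$dys$n <- n_dys
  cfg
}

light_fit <- list(reltol = 1e-4, maxit = 250)
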