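# Shared fixture builders: everything is generated in code at test time.

# a minimal valid cohort data.frame with canonical headers
make_cohort_df <- function(n = 3, group = "control") {
  i <- seq_len(n)
  data.frame(
    subject_id = sprintf("s%02d", i),
    group = group,
    total_sa = 54000 + 100 * (i %% 37),
    exposed_sa = 30000 + 50 * (i %% 37),
    ct = 1.2 + 0.01 * (i %% 11),
    supratentorial_volume = 350000 + 1000 * (i %% 37),
    pma_weeks = 39 + 0.5 * (i %% 10),
    ga_weeks = 38 + 0.2 * (i %% 10),
    sex = rep_len(c("female", "male"), n),
    multiple_birth = FALSE,
    birthweight_z = 0.1 * (i %% 7),
    stringsAsFactors = FALSE
  )
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# small two-group synthetic cohort for inference tests
small_sim <- function(seed = 1, n_control = 120, n_preterm = 40, ...) {
  generate_cohort(sim_config(
    n_per_group = c(control = n_control, preterm = n_preterm),
    seed = seed, ...
  ))
}
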