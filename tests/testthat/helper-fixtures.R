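# Fixtures are built in code: small hand-written portfolios where exact
# values matter, simulated ones where distributional behaviour matters.

# one arm row of the long trial table
arm_row <- function(trial_id, arm, n, control = "placebo",
                    drug = "alirocumab", trial_class = "lipid_lowering",
                    age_mean = NA, age_sd = NA, male_pct = NA,
                    ldl_mean = NA, ldl_sd = NA, bmi_mean = NA, bmi_sd = NA,
                    dm_pct = NA, smoking_pct = NA, htn_pct = NA) {
  data.frame(trial_id = trial_id, drug = drug, control = control,
             trial_class = trial_class, arm = arm, n = n,
             age_mean = age_mean, age_sd = age_sd, male_pct = male_pct,
             ldl_mean = ldl_mean, ldl_sd = ldl_sd, bmi_mean = bmi_mean,
             bmi_sd = bmi_sd, dm_pct = dm_pct, smoking_pct = smoking_pct,
             htn_pct = htn_pct, stringsAsFactors = FALSE)
}

# two complete trials, all characteristics reported
complete_fixture <- function() {
  trial_set(rbind(
    arm_row("T1", "drug", 100, age_mean = 60.1, age_sd = 9.6,
            male_pct = 65.0, ldl_mean = 120.5, ldl_sd = 30.2,
            bmi_mean = 29.1, bmi_sd = 5.0, dm_pct = 30.0,
            smoking_pct = 20.0, htn_pct = 65.6),
    arm_row("T1", "control", 50, age_mean = 59.8, age_sd = 9.6,
            male_pct = 60.0, ldl_mean = 121.0, ldl_sd = 29.8,
            bmi_mean = 29.3, bmi_sd = 5.1, dm_pct = 28.0,
            smoking_pct = 22.0, htn_pct = 63.9),
    arm_row("T2", "drug", 200, drug = "evolocumab", age_mean = 58.0,
            age_sd = 10.2, male_pct = 55.0, ldl_mean = 130.0,
            ldl_sd = 35.0, bmi_mean = 28.0, bmi_sd = 4.8, dm_pct = 35.0,
            smoking_pct = 25.0, htn_pct = 50.0),
    arm_row("T2", "control", 100, drug = "evolocumab", age_mean = 58.0,
            age_sd = 9.5, male_pct = 57.0, ldl_mean = 128.5,
            ldl_sd = 33.0, bmi_mean = 28.4, bmi_sd = 4.9, dm_pct = 33.0,
            smoking_pct = 24.0, htn_pct = 52.0)))
}

# portfolio of 26 placebo-only + 9 ezetimibe-only + 4 dual-control trials,
# mirroring the scope arithmetic 30 placebo / 13 ezetimibe / 43 combined
scope_fixture <- function() {
  rows <- list()
  add <- function(id, control) {
    rows[[length(rows) + 1L]] <<- rbind(
      arm_row(id, "drug", 100, control = control, age_mean = 60, age_sd = 10),
      arm_row(id, "control", 50, control = control, age_mean = 60,
              age_sd = 10))
  }
  for (i in 1:26) add(sprintf("P%02d", i), "placebo")
  for (i in 1:9) add(sprintf("E%02d", i), "ezetimibe")
  for (i in 1:4) { add(sprintf("D%02d", i), "placebo")
                   add(sprintf("D%02d", i), "ezetimibe") }
  trial_set(do.call(rbind, rows))
}

write_fixture_csv <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}

trial_csv_header <- paste("trial_id,drug,control,trial_class,arm,n,age_mean",
                          "age_sd,male_pct,ldl_mean,ldl_sd,bmi_mean,bmi_sd",
                          "dm_pct,smoking_pct,htn_pct", sep = ",")
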