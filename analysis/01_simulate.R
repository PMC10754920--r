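#!/usr/bin/env Rscript
# Stage 1 -- simulate the cohort.
#
# Builds the staged occlusion protocol (stability hour, then 1-h phases of
# 1-min occlusions every 5/3/2 min with a 5-min pause every 20 min), draws
# a nine-subject cohort around the default fetal-sheep configuration, and
# writes the shared schedule plus, for the first subject, the raw signal
# files (EDF EEG, delimited haemodynamics and gasometry). The ninth
# subject's gas trajectory breaches the pH 6.90 stop rule at the end of
# the moderate phase, so that subject's recording stops before the severe
# phase -- the cohort then mirrors a study losing one animal to the rule.

library(fetalqeeg)

seed <- as.integer(Sys.getenv("SEED", "1"))
out_dir <- "results"
dir.create(file.path(out_dir, "raw"), recursive = TRUE, showWarnings = FALSE)

protocol <- protocol_config()
schedule <- build_protocol(protocol)
write_schedule(schedule, file.path(out_dir, "schedule.json"))
print(schedule)

stop_traj <- data.frame(phase = c("S", "A", "B", "C"),
                        ph = c(7.39, 7.28, 6.88, 6.70),
                        pco2 = c(45.3, 50.6, 54.0, 64.9),
                        po2 = c(12, 16, 15, 16.5),
                        lactate = c(2.27, 6.0, 12.8, 15.9))
cohort <- simulate_cohort(
  9, subject_sim_config(), seed = seed,
  overrides = c(rep(list(NULL), 8), list(list(gas_trajectory = stop_traj))))

run_cfg <- default_run_config()
run_cfg$cohort$seed <- seed
write_run_config(run_cfg, file.path(out_dir, "run_config.yaml"))

# materialise subject 1's signals as interchange files
sub1 <- simulate_subject(cohort[[1]]$config, protocol)
write_eeg(sub1$eeg, file.path(out_dir, "raw", "subject1.edf"))
write_physio(sub1$physio, file.path(out_dir, "raw", "subject1"))

write_manifest(file.path(out_dir, "manifest.json"), run_cfg, seed,
               outputs = c(schedule = "results/schedule.json",
                           eeg = "results/raw/subject1.edf",
                           config = "results/run_config.yaml"))

cat(sprintf(
  "cohort of %d subjects drawn (seed %d); subject 1: %d EEG samples x %d channels at %d Hz\n",
  length(cohort), seed, nrow(sub1$eeg$samples), ncol(sub1$eeg$samples),
  sub1$eeg$sample_rate_hz))
cat(sprintf("gasometry of subject 1: pH %s\n",
            paste(round(sub1$physio$gasometry$ph, 2), collapse = " -> ")))
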