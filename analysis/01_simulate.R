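#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohorts.
#
# Three synthetic cohorts at the desk-scale analogue of the clinical design
# (training and testing sub-cohorts with disjoint seed streams, emulating
# the two-scanner split):
#   invasion : class 1 carries the muscle-invasive-like contrast (tissue
#              diffusivity lowered 30%, right-skewed within-tumor mixture)
#   grade    : class 1 carries the high-grade-like contrast (perfusion
#              fraction raised, diffusivity mildly lowered)
#   null     : no contrast at all (negative control)
# Writes the cohort manifests and one example patient's truth maps.

suppressMessages(library(ngdwi))
dir.create("results", showWarnings = FALSE)

seed <- 20240609L

cohorts <- list(
  invasion = generate_cohort(100, 25, spec0 = group_param_spec(),
                             spec1 = spec_mibc_like(), seed = seed),
  grade    = generate_cohort(100, 25, spec0 = group_param_spec(),
                             spec1 = spec_hg_like(), seed = seed + 1L),
  null     = generate_cohort(100, 25, seed = seed + 2L))

for (nm in names(cohorts)) {
  man <- cohorts[[nm]]$manifest
  man$task <- nm
  write.csv(man, sprintf("results/manifest_%s.csv", nm), row.names = FALSE)
  message(sprintf("%-8s %d patients (%d training / %d testing), VOI sizes %d-%d voxels",
                  nm, nrow(man), sum(man$cohort == "training"),
                  sum(man$cohort == "testing"),
                  min(vapply(cohorts[[nm]]$patients, function(p) sum(p$mask), 0L)),
                  max(vapply(cohorts[[nm]]$patients, function(p) sum(p$mask), 0L))))
}

# one example patient's ground-truth maps, as the plain-text map exchange
# format (bulky intermediate: kept out of results/)
dir.create("scratch", showWarnings = FALSE)
write_param_maps(cohorts$invasion$patients[[1]]$truth,
                 "scratch/example_patient_truth_maps.tsv")
message("wrote results/manifest_{invasion,grade,null}.csv and example truth maps")
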