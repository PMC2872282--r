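#!/usr/bin/env Rscript
# Step 1: generate the desk-scale synthetic survey.
#
# A BRFSS-like male survey on a 10 x 10 county lattice nested in 5 states:
# 20,000 respondents with age/race/education codes, informative telephone-
# survey weights, county covariates (poverty, log density, top-decile race
# composition) and outcomes drawn from the full shared-factor model at the
# anchored true parameter values. Writes the delimited inputs every later
# step consumes and prints the demographic cross-tabulations.

library(jointprev)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20100233)   # desk-scale defaults: 100 / 5 / 20,000
sim <- generate_dataset(cfg)

write_respondents(sim$respondents, file.path(out, "respondents.csv"))
write_counties(sim$counties, file.path(out, "counties.csv"))
write_adjacency_gal(sim$geography$county_graph,
                    file.path(out, "county_adjacency.gal"))
write_adjacency_gal(sim$geography$state_graph,
                    file.path(out, "state_adjacency.gal"))
# the generating parameters, for later recovery checks
truth <- sim$true_params
write.csv(data.frame(county = seq_along(truth$v), v_true = truth$v),
          file.path(out, "true_county_effects.csv"), row.names = FALSE)

cat("== simulated", nrow(sim$respondents), "respondents in",
    nrow(sim$counties), "counties /", sim$geography$n_states, "states ==\n\n")

cat("Observed prevalence (%) of the six weight-diabetes categories\n")
cat("by education (columns cat1..cat6; cat6 = normal weight, non-diabetic):\n")
ed <- crosstab_prevalence(sim$respondents, "education", weighted = TRUE)
print(round(as.data.frame(ed), 1))
write.csv(ed, file.path(out, "crosstab_education.csv"), row.names = FALSE)

cat("\nby race:\n")
ra <- crosstab_prevalence(sim$respondents, "race", weighted = TRUE)
print(round(as.data.frame(ra), 1))
write.csv(ra, file.path(out, "crosstab_race.csv"), row.names = FALSE)

cat("\nage-standardised, by state:\n")
st <- crosstab_prevalence(sim$respondents, "state", weighted = TRUE,
                          age_standardize = TRUE, counties = sim$counties)
print(round(as.data.frame(st), 1))
write.csv(st, file.path(out, "crosstab_state.csv"), row.names = FALSE)

cat("\nInputs written under", out, "\n")
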