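#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Emulates the acquisition design of the dried-blood-spot screen: 30
# within-run control samples plus the three family samples (affected
# siblings II.1 and II.3, heterozygous father I.1), each injected in
# triplicate with polarity switching over m/z 70-600. The two galactose-
# pathway markers of the case family (galactose-1-phosphate, galactitol)
# are spiked 8-fold in the affected samples; all other intensities follow
# the null lognormal model. Writes the peak lists, roles and truth table
# under results/cohort/.

library(metaboscreen)

ref <- dbs_reference()
spikes <- data.frame(metabolite_id = c("HMDB0000645", "HMDB0000107"),
                     fold_change = 8)
spec <- cohort_spec(spikes = spikes, seed = 20231110L)
cohort <- generate_cohort(spec, ref)
write_cohort(cohort, "results/cohort")

cat("Cohort:", nrow(cohort$roles), "samples (",
    sum(cohort$roles$role == "control"), "controls ),",
    nrow(cohort$peaks), "peaks written to results/cohort/\n")
cat("Spiked:", paste(spikes$metabolite_id, "x", spikes$fold_change,
                     collapse = ", "), "\n")
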