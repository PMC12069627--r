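#!/usr/bin/env Rscript

## Build the synthetic study cohort used by the downstream analyses: 75 MZ
## and 5 DZ twin pairs (160 individuals) in which mtDNAq causally lowers
## methylation at a target CpG, plus a qPCR plate for the mtDNAq assay and a
## 2000-CpG methylation matrix whose first-ranked signal should be the
## target CpG. Writes cohort, plate and matrix CSVs under results/.

library(mitotwin)
seed <- 20260926
dir.create("results", showWarnings = FALSE)

## mtDNAq (x) causally influences CpG methylation (y), beta = -0.45
sc <- sim_scenario(75, n_pairs_dz = 5, causal_mode = "x_causes_y",
                   beta_causal = -0.45, seed = seed)
cohort <- simulate_twin_cohort(sc)
names(cohort)[names(cohort) == "x"] <- "mtdnaq_latent"
names(cohort)[names(cohort) == "y"] <- "cpg_target_m"

## qPCR plate realizes the latent mtDNAq on the quantity scale, with 8%
## single-target dropouts
true_q <- exp(0.35 * cohort$mtdnaq_latent)
plate <- simulate_qpcr_plate(cohort, true_q, missing_rate = 0.08,
                             seed = seed)

## methylation matrix: the target CpG is injected as column-matched trait
meth <- simulate_methylation_matrix(cohort, "mtdnaq_latent", n_cpgs = 2000,
                                    n_causal = 10, effect = 0.5,
                                    seed = seed)

write.csv(cohort, "results/cohort.csv", row.names = FALSE)
write.csv(plate, "results/qpcr_ct.csv", row.names = FALSE)
write.csv(data.frame(cpg_id = rownames(meth$m), meth$m,
                     check.names = FALSE),
          "results/methylation_m.csv", row.names = FALSE)
write.csv(meth$truth, "results/methylation_truth.csv", row.names = FALSE)

cat("Cohort:", nrow(cohort), "individuals,",
    length(unique(cohort$pair_id)), "pairs (",
    sum(cohort$zygosity == "MZ") / 2, "MZ /",
    sum(cohort$zygosity == "DZ") / 2, "DZ )\n")
cat("Plate:", sum(is.na(plate$ct)), "missing target Cts of",
    nrow(plate), "records\n")
cat("Methylation:", nrow(meth$m), "CpGs x", ncol(meth$m), "samples,",
    sum(meth$truth$causal), "truly mtDNAq-associated\n")
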