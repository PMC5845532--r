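#!/usr/bin/env Rscript
# Heritability stage: exclusions, Blom normalization, twin correlations,
# the six sex-limitation ACE models with LRT/AIC selection, and profile
# CIs for the selected model. Mirrors the published workflow on the
# synthetic cohort from 01_simulate_cohort.R.

library(twinsua)

cohort <- read_cohort_tsv("results/cohort.tsv")

kept <- apply_exclusions(cohort)
log <- attr(kept, "removal_log")
write_tsv(log, "results/exclusions.tsv")
cat(sprintf("exclusions: %d of %d pairs removed (%s)\n", nrow(log),
            nrow(cohort) / 2,
            paste(unique(unlist(strsplit(log$reason, ","))),
                  collapse = ", ")))

write_tsv(describe_phenotype(kept), "results/phenotype_summary.tsv")
kept$sua_blom <- blom_transform(kept$sua)

# correlations on the residualized scale, as in the published analysis
X <- cbind(age = kept$age, male = as.numeric(kept$sex == "M"),
           bmi = kept$bmi)
kept$sua_adj <- adjust_covariates(kept$sua_blom, X)
cors <- cohort_correlations(kept, "sua_adj")
write_tsv(cors, "results/twin_correlations.tsv")
cat(sprintf("r_MZ = %.2f (%.2f-%.2f), r_DZ = %.2f (%.2f-%.2f)\n",
            cors$r[cors$group == "MZ"], cors$ci_low[cors$group == "MZ"],
            cors$ci_high[cors$group == "MZ"],
            cors$r[cors$group == "DZ"], cors$ci_low[cors$group == "DZ"],
            cors$ci_high[cors$group == "DZ"]))

# FIML model ladder (covariates in the means model, not residualized)
models <- c("I", "II", "III", "IV", "V", "VI")
fits <- lapply(models, fit_model, cohort = kept, value_col = "sua_blom",
               seed = 30L)
names(fits) <- models
best <- select_best(fits)
comp <- attr(best, "comparisons")

table1 <- do.call(rbind, lapply(fits, function(f)
  data.frame(model = f$model,
             A_f = f$shares["female", "A"], C_f = f$shares["female", "C"],
             E_f = f$shares["female", "E"], A_m = f$shares["male", "A"],
             C_m = f$shares["male", "C"], E_m = f$shares["male", "E"],
             neg2ll = f$neg2ll, df = f$df, aic = f$aic)))
write_tsv(table1, "results/model_fit_table.tsv")
write_tsv(comp, "results/model_comparisons.tsv")
cat(sprintf("best-fitting model: %s (AIC %.2f)\n", best,
            fits[[best]]$aic))

cis <- t(sapply(c("A_f", "C_f", "E_f", "A_m", "C_m", "E_m"),
                function(cm) profile_ci(fits[[best]], cm)))
ci_tab <- data.frame(component = rownames(cis),
                     estimate = c(fits[[best]]$shares["female", ],
                                  fits[[best]]$shares["male", ]),
                     ci_low = cis[, 1], ci_high = cis[, 2])
write_tsv(ci_tab, "results/best_model_cis.tsv")
print(round(ci_tab[, -1], 1))
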