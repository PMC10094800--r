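#!/usr/bin/env Rscript
# Group contrasts: Mann-Whitney for continuous parameters, Fisher exact /
# chi-square for categoricals, BH-FDR with critical values at q = 0.1,
# plus the sex/age/BMI confounder screen (|rho| > 0.5, p adj < 0.05).
# Reads the cohort written by 01_simulate.R.

suppressPackageStartupMessages(library(coagnet))

cohort <- read_cohort_table("results/data/cohort.csv")
panel <- read_panel_annotation("results/data/panel.tsv")
dir.create("results/contrasts", showWarnings = FALSE, recursive = TRUE)

res <- run_group_contrasts(cohort, panel, q = 0.1)
utils::write.table(res, "results/contrasts/contrasts.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

sig <- res[res$significant, ]
message(nrow(sig), " of ", nrow(res),
        " contrasts significant at q = 0.1; top hits:")
top <- sig[order(sig$p_adj), ][seq_len(min(10, nrow(sig))), ]
print(top[c("parameter", "group_a", "group_b", "summary_a", "summary_b",
            "p_adj")], row.names = FALSE)

screen <- confounder_screen(cohort)
utils::write.table(screen, "results/contrasts/confounder_screen.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
flg <- screen[screen$flagged & !is.na(screen$parameter), ]
message(nrow(flg), " covariate-parameter pairs flagged by the screen")
if (nrow(flg) > 0) print(flg[c("covariate", "parameter", "rho", "p_adj")],
                         row.names = FALSE)
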