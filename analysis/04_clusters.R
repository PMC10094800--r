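#!/usr/bin/env Rscript
# Per-group k-medoids clustering of inflammation, complement, hemostasis
# and endothelium proteins plus the hemostasis assay parameters, on the
# 1 - rho correlation distance; k chosen by the gap statistic (300
# Monte-Carlo references, 10 random initial medoid sets), then cluster
# correspondence between the two AMI arms.

suppressPackageStartupMessages(library(coagnet))

cohort <- read_cohort_table("results/data/cohort.csv")
panel <- read_panel_annotation("results/data/panel.tsv")
out <- "results/clusters"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260923 %% 2147483647

keep <- panel$parameter[panel$functional_class %in%
                          c("inflammation", "complement", "hemostasis",
                            "endothelium", "assay_parameter")]

solutions <- lapply(stats::setNames(nm = cohort_groups()), function(g) {
  X <- coagnet:::group_measurements(cohort, g, keep)
  curve <- gap_statistic(X, k_max = 8, B = 300, restarts = 10,
                         seed = seed + match(g, cohort_groups()))
  d <- suppressWarnings(
    correlation_distance(coagnet:::pairwise_spearman_matrix(X)))
  sol <- pam_cluster(d, curve$k_hat, restarts = 10,
                     seed = seed + 10 + match(g, cohort_groups()))
  utils::write.table(
    data.frame(parameter = names(sol$membership),
               cluster = unname(sol$membership)),
    file.path(out, paste0("clusters_", g, ".tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(k = curve$k_values, log_w = curve$log_w, gap = curve$gap,
               s_k = curve$s_k),
    file.path(out, paste0("gap_curve_", g, ".tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  message(g, ": gap-selected k = ", curve$k_hat)
  sol
})

m <- match_clusters_across_groups(solutions$ami_control,
                                  solutions$ami_post_covid)
utils::write.table(m$best, file.path(out, "cluster_matching_ami.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
message("AMI control vs AMI post-COVID cluster correspondence:")
print(m$best, row.names = FALSE)
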