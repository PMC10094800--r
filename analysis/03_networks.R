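#!/usr/bin/env Rscript
# Per-group pairwise-deletion Spearman matrices and Fisher-z differential
# correlation networks for the two contrasts of interest (AMI control vs
# AMI post-COVID; control vs control post-COVID), with the
# fibrinolysis - inflammation/complement subnetwork slices.

suppressPackageStartupMessages(library(coagnet))

cohort <- read_cohort_table("results/data/cohort.csv")
panel <- read_panel_annotation("results/data/panel.tsv")
out <- "results/networks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mats <- lapply(stats::setNames(nm = cohort_groups()), function(g) {
  m <- correlation_matrix(cohort, g)
  write_correlation_matrix(m, file.path(out, paste0("correlation_", g)))
  m
})

pairs <- list(c("ami_control", "ami_post_covid"),
              c("control", "control_post_covid"))
for (ct in pairs) {
  nets <- build_differential_network(mats[[ct[1]]], mats[[ct[2]]],
                                     rho_min = 0.5, delta_min = 0.4,
                                     alpha = 0.05)
  for (net in nets) {
    base <- file.path(out, paste0("network_", net$present_in))
    export_network(net, paste0(base, ".tsv"), "tsv")
    export_network(net, paste0(base, ".graphml"), "graphml", panel = panel)
    sub <- functional_subnetwork(net, panel, "assay_parameter",
                                 c("inflammation", "complement"),
                                 params_a = fibrinolysis_parameters())
    export_network(sub, file.path(out, paste0("subnetwork_",
                                              net$present_in, ".tsv")),
                   "tsv")
    message("present in ", net$present_in, ": ", nrow(net$edges),
            " differential edges (", nrow(sub$edges),
            " fibrinolysis-inflammation/complement)")
  }
}
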