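# End-to-end orchestration: config -> cohort -> contrasts -> confounder
# screen -> correlation matrices -> differential networks -> functional
# subnetworks -> clustering -> cross-group cluster matching.

#' Build a run configuration
#'
#' Collects every tunable of the pipeline: the input mode (synthetic spec
#' or cohort/panel file paths), the analysis thresholds (FDR level `q` for
#' group contrasts, `alpha` for correlations and differential edges,
#' `rho_min`, `delta_min`), the cluster settings (`k_max`, bootstrap count
#' `B`, PAM `restarts`), the master `seed`, and the output directory.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param spec A `synthetic_spec` (synthetic mode).
#' @param cohort_path,panel_path Input files (file mode).
#' @param q FDR level for group contrasts (default 0.1).
#' @param alpha Significance level for correlations and differential edges
#'   (default 0.05).
#' @param rho_min,delta_min Differential-edge thresholds (defaults 0.5,
#'   0.4).
#' @param k_max,B,restarts Cluster-stage settings (defaults 8, 300, 10).
#' @param cluster_parameters Optional parameter subset to cluster; default
#'   all measurements.
#' @param seed Master seed recorded in every output.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), spec = NULL,
                       cohort_path = NULL, panel_path = NULL,
                       q = 0.1, alpha = 0.05, rho_min = 0.5,
                       delta_min = 0.4, k_max = 8, B = 300, restarts = 10,
                       cluster_parameters = NULL, seed = 1,
                       out_dir = "results/pipeline") {
  mode <- match.arg(mode)
  stopifnot(q > 0, q < 1, alpha > 0, alpha < 1,
            rho_min >= 0, rho_min < 1, delta_min >= 0, delta_min <= 2)
  if (mode == "synthetic" && is.null(spec)) spec <- synthetic_spec(seed = seed)
  structure(
    list(mode = mode, spec = spec, cohort_path = cohort_path,
         panel_path = panel_path, q = q, alpha = alpha, rho_min = rho_min,
         delta_min = delta_min, k_max = k_max, B = B, restarts = restarts,
         cluster_parameters = cluster_parameters, seed = seed,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or generate the cohort; validate; group
#' contrasts with FDR control; covariate confounder screen; per-group
#' correlation matrices; differential networks for the two contrasts of
#' interest (AMI control vs AMI post-COVID; control vs control post-COVID);
#' fibrinolysis-inflammation-complement functional subnetworks; per-group
#' k-medoids clustering with gap-selected k; cross-group cluster matching.
#' All tables are written under `config$out_dir` together with a JSON
#' manifest recording the config, seed, and per-stage row counts. Outputs
#' are fully determined by config + seed.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   thresholds = list(q = config$q, alpha = config$alpha,
                                     rho_min = config$rho_min,
                                     delta_min = config$delta_min),
                   cluster = list(k_max = config$k_max, B = config$B,
                                  restarts = config$restarts),
                   stages = list())
  stage <- function(name, expr) {
    message("[coagnet] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # 1. load or generate
  if (config$mode == "synthetic") {
    gen <- stage("generate", {
      g <- generate_cohort(config$spec)
      cohort <- apply_missingness(g$cohort, g$panel,
                                  config$spec$missing_rates,
                                  seed = child_seed(config$seed, 11))
      list(cohort = cohort, panel = g$panel, truth = g$truth)
    })
    cohort <- gen$cohort; panel <- gen$panel
    write_cohort_table(cohort, file.path(config$out_dir, "cohort.csv"))
    write_panel_annotation(panel, file.path(config$out_dir, "panel.tsv"))
    jsonlite::write_json(gen$truth[c("true_shifted_parameters",
                                     "true_differential_edges")],
                         file.path(config$out_dir, "ground_truth.json"),
                         dataframe = "rows", digits = NA)
  } else {
    cohort <- stage("load", read_cohort_table(config$cohort_path))
    panel <- read_panel_annotation(config$panel_path)
    if (all(is.na(cohort$data$group))) cohort <- assign_groups(cohort)
  }
  manifest$stages$load <- list(n_subjects = nrow(cohort$data),
                               n_parameters = length(cohort$parameter_cols))

  # 2. validate
  report <- stage("validate", validate_cohort(cohort, panel))
  manifest$stages$validate <- list(
    n_per_group = as.list(stats::setNames(
      as.integer(report$n_subjects_per_group),
      names(report$n_subjects_per_group))),
    missing_fraction_by_assay = as.list(report$missing_fraction_by_assay),
    n_unannotated = length(report$unannotated_parameters))

  # 3. group contrasts
  contrasts <- stage("contrasts",
                     run_group_contrasts(cohort, panel, q = config$q))
  utils::write.table(contrasts, file.path(config$out_dir, "contrasts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$stages$contrasts <- list(n_tests = nrow(contrasts),
                                    n_significant = sum(contrasts$significant))

  # 4. confounder screen
  confounders <- stage("confounders", confounder_screen(cohort))
  utils::write.table(confounders,
                     file.path(config$out_dir, "confounders.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$stages$confounders <- list(n_flagged = sum(confounders$flagged))

  # 5. per-group correlation matrices
  mats <- stage("correlations", {
    lapply(stats::setNames(nm = cohort_groups()), function(g) {
      m <- correlation_matrix(cohort, g)
      write_correlation_matrix(m, file.path(config$out_dir,
                                            paste0("correlation_", g)))
      m
    })
  })
  manifest$stages$correlations <- list(
    n_pairs = choose(length(cohort$parameter_cols), 2))

  # 6. differential networks for the two contrasts of interest
  networks <- stage("networks", {
    nets <- list(
      ami = build_differential_network(
        mats$ami_control, mats$ami_post_covid, rho_min = config$rho_min,
        delta_min = config$delta_min, alpha = config$alpha),
      ctrl = build_differential_network(
        mats$control, mats$control_post_covid, rho_min = config$rho_min,
        delta_min = config$delta_min, alpha = config$alpha)
    )
    for (nm in names(nets)) {
      for (side in c("a", "b")) {
        net <- nets[[nm]][[side]]
        base <- file.path(config$out_dir,
                          paste0("network_", net$present_in))
        export_network(net, paste0(base, ".tsv"), "tsv")
        export_network(net, paste0(base, ".graphml"), "graphml",
                       panel = panel)
      }
    }
    nets
  })
  manifest$stages$networks <- list(
    n_edges = vapply(networks, function(n2) {
      nrow(n2$a$edges) + nrow(n2$b$edges)
    }, numeric(1)))

  # 7. fibrinolysis - inflammation/complement subnetworks
  subnets <- stage("subnetworks", {
    lapply(networks, function(n2) {
      lapply(n2, function(net) {
        sn <- functional_subnetwork(
          net, panel,
          classes_a = "assay_parameter",
          classes_b = c("inflammation", "complement"),
          params_a = fibrinolysis_parameters())
        export_network(sn, file.path(config$out_dir,
          paste0("subnetwork_", sn$present_in, ".tsv")), "tsv")
        sn
      })
    })
  })
  manifest$stages$subnetworks <- list(
    n_edges = vapply(subnets, function(n2) {
      nrow(n2$a$edges) + nrow(n2$b$edges)
    }, numeric(1)))

  # 8. per-group clustering with gap-selected k, then cross-group matching
  clusters <- stage("clusters", {
    cl_params <- config$cluster_parameters
    if (is.null(cl_params)) cl_params <- cohort$parameter_cols
    lapply(stats::setNames(nm = cohort_groups()), function(g) {
      X <- group_measurements(cohort, g, cl_params)
      curve <- gap_statistic(X, k_max = config$k_max, B = config$B,
                             restarts = config$restarts,
                             seed = child_seed(config$seed,
                                               match(g, cohort_groups())))
      d <- suppressWarnings(
        correlation_distance(pairwise_spearman_matrix(X)))
      sol <- pam_cluster(d, curve$k_hat, restarts = config$restarts,
                         seed = child_seed(config$seed,
                                           10 + match(g, cohort_groups())))
      utils::write.table(
        data.frame(parameter = names(sol$membership),
                   cluster = unname(sol$membership)),
        file.path(config$out_dir, paste0("clusters_", g, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(
        data.frame(k = curve$k_values, log_w = curve$log_w,
                   gap = curve$gap, s_k = curve$s_k),
        file.path(config$out_dir, paste0("gap_curve_", g, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
      list(curve = curve, solution = sol)
    })
  })
  matching <- stage("cluster_matching", {
    match_clusters_across_groups(clusters$ami_control$solution,
                                 clusters$ami_post_covid$solution)
  })
  utils::write.table(matching$best,
                     file.path(config$out_dir, "cluster_matching.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$stages$clusters <- list(
    k_hat = vapply(clusters, function(x) x$curve$k_hat, integer(1)))
  manifest$stages$cluster_matching <- list(n_matched = nrow(matching$best))

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, panel = panel, contrasts = contrasts,
                 confounders = confounders, matrices = mats,
                 networks = networks, subnetworks = subnets,
                 clusters = clusters, matching = matching,
                 manifest = manifest))
}
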