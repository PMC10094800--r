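# Synthetic cohort generator: Gaussian copula with planted group mean
# shifts, group-specific correlation edges, categorical covariate
# proportions, and MCAR missingness. Ground truth is returned for
# recovery testing of the downstream contrast/network/cluster stages.

#' Default panel annotation for the synthetic cohort
#'
#' Builds a panel mirroring the study design: 81 plasma proteins spread over
#' the eight functional classes (complement, inflammation, hemostasis,
#' endothelium, extracellular matrix, lipid metabolism, calcification,
#' steroid hormone transport) with field-standard names for the proteins the
#' analysis singles out (complement C3/C5/C6, CRP, haptoglobin, fibrinogen
#' chains, PEDF, ...), plus hemostasis assay parameters from
#' thrombodynamics (including the fibrinolysis set LOT, LP, CLT, LI, LTE),
#' rotational thromboelastometry, impedance aggregometry and coagulation
#' labs.
#'
#' @param n_proteins Number of protein parameters (default 81).
#' @param n_assay_params Number of hemostasis assay parameters (default 25).
#' @return A `panel_annotation`.
#' @export
default_panel <- function(n_proteins = 81, n_assay_params = 25) {
  # interleaved so that truncated panels still span several classes
  named <- c(
    CRP = "inflammation", complement_C3 = "complement",
    fibrinogen_beta = "hemostasis", haptoglobin = "inflammation",
    complement_C6 = "complement", PEDF = "endothelium",
    LBP = "inflammation", complement_factor_B = "complement",
    vitamin_K_dependent_protein_S = "hemostasis",
    angiogenin = "endothelium", complement_factor_I = "complement",
    fibrinogen_gamma = "hemostasis", hemopexin = "inflammation",
    C4b_binding_protein_alpha = "complement",
    vitronectin = "hemostasis",
    leucine_rich_alpha_2_glycoprotein = "inflammation",
    complement_C5 = "complement", prothrombin = "hemostasis",
    C1_inhibitor = "complement", coagulation_factor_IX = "hemostasis",
    complement_C8_alpha = "complement", antithrombin_III = "hemostasis",
    ficolin_2 = "complement", plasminogen = "hemostasis",
    MASP_2 = "complement", von_Willebrand_factor = "endothelium",
    alpha_1_antitrypsin = "inflammation",
    fibronectin = "extracellular_matrix", lumican = "extracellular_matrix",
    apolipoprotein_A1 = "lipid_metabolism",
    apolipoprotein_B = "lipid_metabolism",
    fetuin_A = "calcification",
    corticosteroid_binding_globulin = "steroid_hormone_transport",
    vitamin_D_binding_protein = "steroid_hormone_transport"
  )
  prot_classes <- setdiff(FUNCTIONAL_CLASSES,
                          c("assay_parameter", "clinical"))
  if (n_proteins <= length(named)) {
    prot <- named[seq_len(n_proteins)]
  } else {
    extra_n <- n_proteins - length(named)
    extra <- stats::setNames(
      rep_len(prot_classes, extra_n),
      sprintf("protein_%02d", seq_len(extra_n))
    )
    prot <- c(named, extra)
  }
  assay_params <- c(
    V = "thrombodynamics", Vi = "thrombodynamics", Vst = "thrombodynamics",
    Tlag = "thrombodynamics", CS = "thrombodynamics", D = "thrombodynamics",
    Tsp = "thrombodynamics", LOT = "thrombodynamics", LP = "thrombodynamics",
    CLT = "thrombodynamics", LI = "thrombodynamics", LTE = "thrombodynamics",
    CT = "rotem", CFT = "rotem", A10 = "rotem", A20 = "rotem", A30 = "rotem",
    MCF = "rotem", alpha_angle = "rotem", LI60 = "rotem", ML = "rotem",
    ASPI = "aggregometry", ADP = "aggregometry", TRAP = "aggregometry",
    APTT = "coag_lab", PT = "coag_lab"
  )
  if (n_assay_params > length(assay_params)) {
    extra_n <- n_assay_params - length(assay_params)
    assay_params <- c(assay_params, stats::setNames(
      rep("coag_lab", extra_n), sprintf("assay_param_%02d", seq_len(extra_n))
    ))
  }
  assay_params <- assay_params[seq_len(n_assay_params)]
  panel_annotation(
    parameter = c(names(prot), names(assay_params)),
    functional_class = c(unname(prot),
                         rep("assay_parameter", length(assay_params))),
    assay = c(rep("proteomics", length(prot)), unname(assay_params))
  )
}

#' Thrombodynamics fibrinolysis parameter names
#' @return Character vector `LOT, LP, CLT, LI, LTE` (clot-lysis kinetics).
#' @export
fibrinolysis_parameters <- function() c("LOT", "LP", "CLT", "LI", "LTE")

#' Specify a synthetic cohort
#'
#' Encodes the study conditions the generator emulates: the four group sizes
#' of the cohort, lognormal protein marginals, planted multiplicative group
#' mean shifts, group-specific planted correlation edges, per-group
#' categorical covariate proportions reproducing the study demographics, and
#' per-assay MCAR missingness rates (2.1% proteomics, 6.7% labs).
#'
#' @param group_sizes Named counts per group (default the cohort's
#'   27/31/22/44); each must be at least 4, the minimum for the Fisher-z
#'   comparison downstream.
#' @param n_proteins,n_assay_params Panel dimensions.
#' @param panel Optional `panel_annotation` overriding the default.
#' @param sdlog Lognormal shape parameter shared by the protein marginals.
#' @param planted_shifts Data frame `(parameter, group, effect)`;
#'   multiplicative effects on the group's marginal median.
#' @param planted_edges Data frame `(param_i, param_j, group, rho)`; latent
#'   correlations in (-1, 1) planted in one group's copula.
#' @param baseline_rho Background latent correlation for unplanted pairs.
#' @param categorical_spec Named list: per-covariate vector of per-group
#'   success probabilities. Defaults reproduce the study's male-sex and
#'   smoking proportions.
#' @param missing_rates Named per-assay MCAR cell rates in `[0, 1)`.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(group_sizes = c(control = 27,
                                           control_post_covid = 31,
                                           ami_control = 22,
                                           ami_post_covid = 44),
                           n_proteins = 81, n_assay_params = 25,
                           panel = NULL, sdlog = 0.5,
                           planted_shifts = NULL, planted_edges = NULL,
                           baseline_rho = 0,
                           categorical_spec = list(
                             sex = c(control = 0.37,
                                     control_post_covid = 0.26,
                                     ami_control = 0.73,
                                     ami_post_covid = 0.84),
                             smoking = c(control = 0.16,
                                         control_post_covid = 0.23,
                                         ami_control = 0.44,
                                         ami_post_covid = 0.65)),
                           missing_rates = c(proteomics = 0.021,
                                             rotem = 0.067,
                                             thrombodynamics = 0.067,
                                             aggregometry = 0.067,
                                             coag_lab = 0.067),
                           seed = 1) {
  stopifnot(all(cohort_groups() %in% names(group_sizes)))
  group_sizes <- group_sizes[cohort_groups()]
  if (any(group_sizes < 4)) {
    stop("every group size must be >= 4 (Fisher z needs n > 3)")
  }
  if (is.null(panel)) panel <- default_panel(n_proteins, n_assay_params)
  if (is.null(planted_shifts)) {
    planted_shifts <- data.frame(parameter = character(),
                                 group = character(), effect = numeric())
  }
  if (is.null(planted_edges)) {
    planted_edges <- data.frame(param_i = character(), param_j = character(),
                                group = character(), rho = numeric())
  }
  if (nrow(planted_edges) > 0 && any(abs(planted_edges$rho) >= 1)) {
    stop("planted rho must lie in (-1, 1)")
  }
  if (any(missing_rates >= 1) || any(missing_rates < 0)) {
    stop("missing rates must lie in [0, 1)")
  }
  if (abs(baseline_rho) >= 1) stop("baseline_rho must lie in (-1, 1)")
  structure(
    list(group_sizes = group_sizes, panel = panel, sdlog = sdlog,
         planted_shifts = planted_shifts, planted_edges = planted_edges,
         baseline_rho = baseline_rho, categorical_spec = categorical_spec,
         missing_rates = missing_rates, seed = seed),
    class = "synthetic_spec"
  )
}

#' Write a synthetic-cohort specification to YAML
#'
#' The panel is stored inline (parameter, class, assay columns), so the
#' file fully determines the generator together with the seed.
#'
#' @param spec A `synthetic_spec`.
#' @param path Output path (`.yaml`).
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  obj <- list(
    group_sizes = as.list(spec$group_sizes),
    panel = lapply(seq_len(nrow(spec$panel)), function(i) {
      as.list(spec$panel[i, c("parameter", "functional_class", "assay")])
    }),
    sdlog = spec$sdlog,
    planted_shifts = lapply(seq_len(nrow(spec$planted_shifts)), function(i) {
      as.list(spec$planted_shifts[i, ])
    }),
    planted_edges = lapply(seq_len(nrow(spec$planted_edges)), function(i) {
      as.list(spec$planted_edges[i, ])
    }),
    baseline_rho = spec$baseline_rho,
    categorical_spec = lapply(spec$categorical_spec, as.list),
    missing_rates = as.list(spec$missing_rates),
    seed = spec$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a synthetic-cohort specification from YAML
#'
#' @param path Path written by [write_synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  bind_rows0 <- function(lst, cols) {
    if (length(lst) == 0) {
      return(stats::setNames(
        data.frame(character(), character(), numeric())[, 0], NULL))
    }
    do.call(rbind, lapply(lst, function(r) as.data.frame(r)))
  }
  shifts <- if (length(obj$planted_shifts)) bind_rows0(obj$planted_shifts)
            else NULL
  edges <- if (length(obj$planted_edges)) bind_rows0(obj$planted_edges)
           else NULL
  panel_df <- bind_rows0(obj$panel)
  synthetic_spec(
    group_sizes = unlist(obj$group_sizes),
    panel = panel_annotation(panel_df$parameter, panel_df$functional_class,
                             panel_df$assay),
    sdlog = obj$sdlog,
    planted_shifts = shifts,
    planted_edges = edges,
    baseline_rho = obj$baseline_rho,
    categorical_spec = lapply(obj$categorical_spec, unlist),
    missing_rates = unlist(obj$missing_rates),
    seed = obj$seed
  )
}

# Eigenvalue-clipping positive-definite repair: clip eigenvalues at `eps`,
# reconstruct, renormalize to unit diagonal.
nearest_pd <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > eps) return(R)
  vals <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

#' Build one group's latent correlation matrix
#'
#' Starts from `baseline_rho` off the diagonal, plants this group's target
#' edges, and repairs to positive definite by eigenvalue clipping followed
#' by renormalization to unit diagonal. The largest absolute deviation of a
#' planted entry from its target after repair is recorded in the
#' `max_deviation` attribute.
#'
#' @param spec A `synthetic_spec`.
#' @param group Group label.
#' @return Correlation matrix over all panel parameters, with attributes
#'   `repaired` (logical) and `max_deviation`.
#' @export
build_group_correlation <- function(spec, group) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!group %in% cohort_groups()) stop("unknown group: ", group)
  params <- spec$panel$parameter
  n <- length(params)
  R <- matrix(spec$baseline_rho, n, n, dimnames = list(params, params))
  diag(R) <- 1
  pe <- spec$planted_edges[spec$planted_edges$group == group, , drop = FALSE]
  if (nrow(pe) > 0) {
    bad <- setdiff(unique(c(pe$param_i, pe$param_j)), params)
    if (length(bad) > 0) {
      stop("planted edge names not in panel: ", paste(bad, collapse = ", "))
    }
    if (any(abs(pe$rho) >= 1)) {
      stop("infeasible planted edges (|rho| >= 1): ",
           paste(pe$param_i[abs(pe$rho) >= 1],
                 pe$param_j[abs(pe$rho) >= 1], sep = "-", collapse = ", "))
    }
    for (r in seq_len(nrow(pe))) {
      R[pe$param_i[r], pe$param_j[r]] <- pe$rho[r]
      R[pe$param_j[r], pe$param_i[r]] <- pe$rho[r]
    }
  }
  target <- R
  R2 <- nearest_pd(R)
  repaired <- !isTRUE(all.equal(R2, R, tolerance = 1e-12))
  dev <- if (nrow(pe) > 0) {
    max(abs(R2[cbind(pe$param_i, pe$param_j)] -
            target[cbind(pe$param_i, pe$param_j)]))
  } else {
    0
  }
  attr(R2, "repaired") <- repaired
  attr(R2, "max_deviation") <- dev
  R2
}

# Per-group, per-parameter lognormal meanlog after planted shifts.
marginal_meanlog <- function(spec, group) {
  params <- spec$panel$parameter
  is_prot <- spec$panel$assay == "proteomics"
  base <- ifelse(is_prot, 3, 4)  # arbitrary abundance scales
  names(base) <- params
  ps <- spec$planted_shifts[spec$planted_shifts$group == group, ,
                            drop = FALSE]
  if (nrow(ps) > 0) {
    bad <- setdiff(ps$parameter, params)
    if (length(bad)) stop("shifted parameter not in panel: ",
                          paste(bad, collapse = ", "))
    base[ps$parameter] <- base[ps$parameter] + log(ps$effect)
  }
  base
}

#' Generate a synthetic cohort with ground truth
#'
#' Per group, latent Gaussian vectors are drawn with that group's planted
#' correlation matrix and mapped through the Gaussian copula to lognormal
#' marginals (proteins and assay parameters alike), so the planted latent
#' correlations translate to rank correlations by the standard copula
#' mapping `rho_S = (6/pi) asin(rho/2)`. Planted shifts act
#' multiplicatively on the group's marginal median. Clinical covariates are
#' drawn from per-group Bernoulli proportions (sex, smoking) and continuous
#' distributions centred on the study's per-group medians (age, BMI). The
#' anti-N IgG index is drawn below the 1.4 cutoff for control arms and above
#' it for post-COVID arms, and groups are then re-derived through
#' [assign_serostatus_group()]. Fully deterministic given `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @return List with elements `cohort` (a `cohort_table`), `panel`, and
#'   `truth` (planted shifts, planted differential edges, realized per-group
#'   latent correlation matrices).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- spec$panel$parameter
  age_med <- c(control = 48, control_post_covid = 49,
               ami_control = 65.5, ami_post_covid = 59)
  bmi_med <- c(control = 24.38, control_post_covid = 26.4,
               ami_control = 27.91, ami_post_covid = 26.73)
  R_list <- list()
  rows <- with_seed(spec$seed, {
    out <- list()
    idx <- 0
    for (g in cohort_groups()) {
      n_g <- spec$group_sizes[[g]]
      R_g <- build_group_correlation(spec, g)
      R_list[[g]] <- R_g
      Z <- MASS::mvrnorm(n_g, mu = rep(0, length(params)), Sigma = R_g)
      Z <- matrix(Z, nrow = n_g)
      U <- stats::pnorm(Z)
      ml <- marginal_meanlog(spec, g)
      X <- sapply(seq_along(params), function(j) {
        stats::qlnorm(U[, j], meanlog = ml[j], sdlog = spec$sdlog)
      })
      X <- matrix(X, nrow = n_g, dimnames = list(NULL, params))
      ami <- g %in% c("ami_control", "ami_post_covid")
      post <- g %in% c("control_post_covid", "ami_post_covid")
      igg <- if (post) 1.4 + stats::rlnorm(n_g, meanlog = 0.5, sdlog = 0.6)
             else stats::runif(n_g, 0, 1.3)
      cov_df <- data.frame(
        sex = ifelse(
          stats::rbinom(n_g, 1, spec$categorical_spec$sex[[g]]) == 1,
          "male", "female"),
        age = round(pmin(90, pmax(25,
          stats::rnorm(n_g, mean = age_med[[g]], sd = 8)))),
        bmi = round(exp(stats::rnorm(n_g, mean = log(bmi_med[[g]]),
                                     sd = 0.12)), 2),
        smoking = stats::rbinom(n_g, 1,
          spec$categorical_spec$smoking[[g]]) == 1,
        stringsAsFactors = FALSE
      )
      df <- cbind(
        data.frame(subject_id = sprintf("S%03d", idx + seq_len(n_g)),
                   anti_n_igg = round(igg, 3), ami_flag = ami,
                   stringsAsFactors = FALSE),
        cov_df, as.data.frame(X)
      )
      idx <- idx + n_g
      out[[g]] <- df
    }
    out
  })
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  cohort <- cohort_table(data, covariate_cols = c("sex", "age", "bmi",
                                                  "smoking"),
                         parameter_cols = params)
  cohort <- suppressWarnings(assign_groups(cohort))
  truth <- list(
    true_shifted_parameters = spec$planted_shifts,
    true_differential_edges = spec$planted_edges,
    realized_correlations = R_list
  )
  list(cohort = cohort, panel = spec$panel, truth = truth)
}

#' Knock out cells completely at random
#'
#' Sets each measurement cell to missing independently with its assay's
#' rate, emulating the study's overall missing-data burden under an MCAR
#' mechanism. Deterministic given `seed`.
#'
#' @param cohort A `cohort_table`.
#' @param panel The matching `panel_annotation` (maps parameters to assays).
#' @param rates Named per-assay cell rates in `[0, 1)`.
#' @param seed Integer seed.
#' @return The cohort with missing cells inserted.
#' @export
apply_missingness <- function(cohort, panel, rates, seed = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (any(rates >= 1) || any(rates < 0)) {
    stop("missing rates must lie in [0, 1)")
  }
  assay_of <- stats::setNames(panel$assay, panel$parameter)
  with_seed(seed, {
    for (a in names(rates)) {
      if (rates[[a]] <= 0) next
      cols <- intersect(names(assay_of)[assay_of == a],
                        cohort$parameter_cols)
      if (length(cols) == 0) next
      block <- as.matrix(cohort$data[cols])
      drop <- matrix(stats::runif(length(block)) < rates[[a]],
                     nrow = nrow(block))
      block[drop] <- NA_real_
      cohort$data[cols] <- as.data.frame(block)
    }
  })
  cohort
}
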