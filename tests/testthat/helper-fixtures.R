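# Programmatic fixtures shared across test files.

# Subjects x parameters matrix with 3 latent-factor blocks of `m`
# parameters each; within-block pairwise correlation `rho`.
make_block_data <- function(n, m = 6, rho = 0.8, n_blocks = 3) {
  Z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  X <- do.call(cbind, lapply(seq_len(n_blocks), function(b) {
    sapply(seq_len(m), function(i) {
      sqrt(rho) * Z[, b] + sqrt(1 - rho) * stats::rnorm(n)
    })
  }))
  colnames(X) <- sprintf("p%02d", seq_len(n_blocks * m))
  X
}

# Minimal synthetic spec for fast tests: small panel, no missingness.
small_spec <- function(n_proteins = 8, n_assay_params = 4, seed = 1, ...) {
  synthetic_spec(
    n_proteins = n_proteins, n_assay_params = n_assay_params,
    missing_rates = c(proteomics = 0, rotem = 0, thrombodynamics = 0,
                      aggregometry = 0, coag_lab = 0),
    seed = seed, ...
  )
}

# Two-group planted differential-edge fixture: `n_edges` disjoint pairs
# correlated at `rho` in group A only, among `n_params` parameters.
# Returns correlation_matrix objects for both groups plus the planted
# pair list.
make_diff_edge_fixture <- function(n_a = 44, n_b = 22, n_params = 20,
                                   n_edges = 10, rho = 0.7, seed = 1) {
  stopifnot(n_params >= 2 * n_edges)
  pairs <- data.frame(
    param_i = sprintf("v%02d", seq(1, 2 * n_edges, by = 2)),
    param_j = sprintf("v%02d", seq(2, 2 * n_edges, by = 2))
  )
  params <- sprintf("v%02d", seq_len(n_params))
  spec <- synthetic_spec(
    group_sizes = c(control = n_b, control_post_covid = 4,
                    ami_control = 4, ami_post_covid = n_a),
    panel = panel_annotation(params, rep("inflammation", n_params)),
    planted_edges = data.frame(pairs, group = "ami_post_covid", rho = rho),
    missing_rates = c(proteomics = 0),
    seed = seed
  )
  g <- generate_cohort(spec)
  list(
    mat_a = correlation_matrix(g$cohort, "ami_post_covid", params),
    mat_b = correlation_matrix(g$cohort, "control", params),
    pairs = pairs, params = params, cohort = g$cohort, panel = g$panel
  )
}

edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
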