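test_that("Fisher-z difference test matches the closed form", {
  expect_equal(differential_correlation_test(0.8, 30, 0.8, 40)$z_stat, 0)
  expect_equal(differential_correlation_test(0.8, 30, 0.8, 40)$p_value, 1)

  # classical transform (c = 1) against the hand computation
  res <- differential_correlation_test(0.8, 44, 0.1, 22, c_var = 1)
  z_hand <- (atanh(0.8) - atanh(0.1)) / sqrt(1 / 41 + 1 / 19)
  expect_equal(res$z_stat, z_hand, tolerance = 1e-12)
  expect_equal(res$z_stat, 3.597, tolerance = 1e-3)
  expect_equal(res$p_value, 3.2e-4, tolerance = 0.02)
  # the Spearman default shrinks the statistic by sqrt(1.06)
  res2 <- differential_correlation_test(0.8, 44, 0.1, 22)
  expect_equal(res2$z_stat, z_hand / sqrt(1.06), tolerance = 1e-12)

  # antisymmetric in the two groups
  fwd <- differential_correlation_test(0.6, 30, 0.2, 25)
  rev <- differential_correlation_test(0.2, 25, 0.6, 30)
  expect_equal(fwd$z_stat, -rev$z_stat)
  expect_equal(fwd$p_value, rev$p_value)

  expect_error(differential_correlation_test(0.5, 3, 0.5, 30), "n > 3")
  expect_error(differential_correlation_test(1, 30, 0.5, 30), "infinite")
})

test_that("difference test holds its type-I error at a common rho", {
  set.seed(77)
  n <- 30
  rej <- vapply(seq_len(2000), function(i) {
    z <- rnorm(n); x <- sqrt(0.5) * z + sqrt(0.5) * rnorm(n)
    z2 <- rnorm(n); x2 <- sqrt(0.5) * z2 + sqrt(0.5) * rnorm(n)
    ra <- cor(rank(z), rank(x))
    rb <- cor(rank(z2), rank(x2))
    differential_correlation_test(ra, n, rb, n)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("identical matrices produce empty networks", {
  fx <- make_diff_edge_fixture(n_a = 30, n_b = 30, n_params = 6,
                               n_edges = 2, seed = 3)
  nets <- build_differential_network(fx$mat_a, fx$mat_a)
  expect_equal(nrow(nets$a$edges), 0)
  expect_equal(nrow(nets$b$edges), 0)
})

test_that("the delta threshold gates edges regardless of significance", {
  # two strong significant correlations differing by less than 0.4:
  # no differential edge
  mk_mat <- function(rho_val, n, group) {
    params <- c("x", "y")
    rho <- matrix(c(1, rho_val, rho_val, 1), 2,
                  dimnames = list(params, params))
    n_eff <- matrix(n, 2, 2, dimnames = dimnames(rho))
    p <- matrix(c(NA, 1e-6, 1e-6, NA), 2, dimnames = dimnames(rho))
    structure(list(parameters = params, group = group, rho = rho,
                   n_eff = n_eff, p_raw = p, p_adj = p,
                   conditioning_set = character()),
              class = "correlation_matrix")
  }
  nets <- build_differential_network(mk_mat(0.55, 40, "a"),
                                     mk_mat(0.20, 40, "b"))
  expect_equal(nrow(nets$a$edges), 0)
  # |delta| = 0.55 >= 0.4 with a strong significant side: edge appears
  nets2 <- build_differential_network(mk_mat(0.75, 40, "a"),
                                      mk_mat(0.20, 40, "b"))
  expect_equal(nrow(nets2$a$edges), 1)
  expect_equal(nets2$a$edges$present_in, "a")
  expect_equal(nets2$a$edges$sign, "positive")
  expect_equal(nrow(nets2$b$edges), 0)
  # under the both-significant reading the same pair needs strength in B too
  nets3 <- build_differential_network(mk_mat(0.75, 40, "a"),
                                      mk_mat(0.20, 40, "b"),
                                      rule = "both_significant")
  expect_equal(nrow(nets3$a$edges), 0)
})

test_that("networks for (A,B) and (B,A) swap present_in labels exactly", {
  fx <- make_diff_edge_fixture(n_a = 44, n_b = 22, n_params = 10,
                               n_edges = 4, seed = 11)
  fwd <- build_differential_network(fx$mat_a, fx$mat_b)
  rev <- build_differential_network(fx$mat_b, fx$mat_a)
  expect_equal(fwd$a$edges[c("param_i", "param_j")],
               rev$b$edges[c("param_i", "param_j")])
  expect_equal(fwd$b$edges[c("param_i", "param_j")],
               rev$a$edges[c("param_i", "param_j")])
  expect_equal(fwd$a$edges$z_stat, -rev$b$edges$z_stat)
})

test_that("planted differential edges are recovered with few false edges", {
  sens <- fp <- numeric(10)
  for (s in seq_len(10)) {
    fx <- make_diff_edge_fixture(n_a = 44, n_b = 22, n_params = 20,
                                 n_edges = 10, rho = 0.7, seed = 100 + s)
    nets <- build_differential_network(fx$mat_a, fx$mat_b)
    found <- edge_key(nets$a$edges$param_i, nets$a$edges$param_j)
    truth <- edge_key(fx$pairs$param_i, fx$pairs$param_j)
    sens[s] <- mean(truth %in% found)
    fp[s] <- sum(!found %in% truth) + nrow(nets$b$edges)
  }
  expect_gte(median(sens), 0.7)
  expect_lte(median(fp), 1)
})

test_that("plain-Spearman differential networks equal the empty-conditioning
           partial pipeline", {
  fx <- make_diff_edge_fixture(n_a = 40, n_b = 30, n_params = 8,
                               n_edges = 3, seed = 17)
  m_a2 <- correlation_matrix(fx$cohort, "ami_post_covid", fx$params,
                             conditioning_set = character())
  expect_equal(m_a2$rho, fx$mat_a$rho)
  nets1 <- build_differential_network(fx$mat_a, fx$mat_b)
  nets2 <- build_differential_network(m_a2, fx$mat_b)
  expect_equal(nets1$a$edges, nets2$a$edges)
})

test_that("functional subnetworks keep exactly the cross-class edges", {
  panel <- panel_annotation(
    c("CLT", "LOT", "complement_C6", "CRP", "prot_x"),
    c("assay_parameter", "assay_parameter", "complement", "inflammation",
      "hemostasis"),
    c("thrombodynamics", "thrombodynamics", "proteomics", "proteomics",
      "proteomics"))
  edges <- data.frame(
    param_i = c("CLT", "CRP"), param_j = c("complement_C6", "prot_x"),
    rho_a = c(0.7, 0.8), rho_b = c(0.0, 0.1), n_a = 40, n_b = 20,
    delta = c(0.7, 0.7), z_stat = 3, p_raw_diff = 1e-4, p_adj_diff = 1e-3,
    present_in = "control", sign = "positive", stringsAsFactors = FALSE)
  net <- structure(list(contrast = c("control", "control_post_covid"),
                        present_in = "control", edges = edges,
                        thresholds = list()),
                   class = "differential_network")
  sub <- functional_subnetwork(net, panel,
                               classes_a = "assay_parameter",
                               classes_b = c("inflammation", "complement"),
                               params_a = fibrinolysis_parameters())
  expect_equal(nrow(sub$edges), 1)
  expect_equal(sub$edges$param_i, "CLT")
  empty <- functional_subnetwork(net, panel, classes_a = character(),
                                 classes_b = "complement")
  expect_equal(nrow(empty$edges), 0)
  expect_error(functional_subnetwork(net, panel, "nosuch", "complement"),
               "unknown class")
})

test_that("a planted fibrinolysis-complement edge lands only in its group's
           subnetwork", {
  params <- c("CLT", "LOT", "complement_C6", "CRP")
  panel <- panel_annotation(
    params,
    c("assay_parameter", "assay_parameter", "complement", "inflammation"),
    c("thrombodynamics", "thrombodynamics", "proteomics", "proteomics"))
  spec <- synthetic_spec(
    group_sizes = c(control = 44, control_post_covid = 44,
                    ami_control = 4, ami_post_covid = 4),
    panel = panel,
    planted_edges = data.frame(param_i = "CLT", param_j = "complement_C6",
                               group = "control", rho = 0.85),
    missing_rates = c(proteomics = 0), seed = 23)
  g <- generate_cohort(spec)
  m_ctl <- correlation_matrix(g$cohort, "control", params)
  m_pc <- correlation_matrix(g$cohort, "control_post_covid", params)
  nets <- build_differential_network(m_ctl, m_pc)
  sub_ctl <- functional_subnetwork(nets$a, panel, "assay_parameter",
                                   c("inflammation", "complement"),
                                   params_a = fibrinolysis_parameters())
  sub_pc <- functional_subnetwork(nets$b, panel, "assay_parameter",
                                  c("inflammation", "complement"),
                                  params_a = fibrinolysis_parameters())
  expect_true("complement_C6" %in% c(sub_ctl$edges$param_i,
                                     sub_ctl$edges$param_j))
  expect_equal(nrow(sub_pc$edges), 0)
})

test_that("network export round-trips through TSV and GraphML", {
  fx <- make_diff_edge_fixture(n_a = 44, n_b = 22, n_params = 8,
                               n_edges = 3, rho = 0.8, seed = 31)
  nets <- build_differential_network(fx$mat_a, fx$mat_b)
  net <- nets$a
  expect_gt(nrow(net$edges), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$rho_a, net$edges$rho_a, tolerance = 1e-9)
  expect_equal(back$sign, net$edges$sign)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml", panel = fx$panel)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sort(igraph::E(g)$delta), sort(net$edges$delta),
               tolerance = 1e-9)

  # an empty network still writes a valid file
  empty_tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(nets$b, empty_tsv, "tsv")
  expect_equal(nrow(read.delim(empty_tsv)), 0)
  empty_gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(nets$b, empty_gml, "graphml")
  g2 <- igraph::read_graph(empty_gml, format = "graphml")
  expect_equal(igraph::ecount(g2), 0)
})
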