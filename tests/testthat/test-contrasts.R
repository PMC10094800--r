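test_that("Mann-Whitney exact path matches full enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  set.seed(31)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:6, 1)), 4)
    y <- round(rnorm(sample(3:6, 1)), 4)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_exact_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney degenerate and large-sample behaviour", {
  expect_warning(res <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5)), "identical")
  expect_equal(res$p_value, 1)

  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(50)
    y <- rnorm(50, 0.3)
    res <- mann_whitney_u(x, y)
    expect_equal(res$method, "normal")
    expect_equal(res$p_value, mw_normal_oracle(x, y), tolerance = 1e-6)
  }
  # with ties
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1:5, 30, replace = TRUE)
    y <- sample(1:6, 40, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_normal_oracle(x, y),
                 tolerance = 1e-6)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(12)
  x <- rlnorm(15); y <- rlnorm(20, 0.4)
  p0 <- mann_whitney_u(x, y)$p_value
  expect_equal(mann_whitney_u(log(x), log(y))$p_value, p0)
  expect_equal(mann_whitney_u(x^3, y^3)$p_value, p0)
})

test_that("Mann-Whitney holds its type-I error under the global null", {
  set.seed(99)
  rej <- vapply(seq_len(5000), function(i) {
    mann_whitney_u(rnorm(22), rnorm(44))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("Fisher exact matches the hypergeometric-sum oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  p_diag <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_value
  expect_equal(p_diag, 2 / choose(20, 10), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t(tab))$p_value,
                 fisher_exact_2x2(tab)$p_value, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("chi-square independence matches the textbook formula", {
  expect_equal(chi_square_independence(rbind(c(5, 10), c(5, 10)))$statistic,
               0)
  res <- chi_square_independence(rbind(c(10, 20), c(20, 10)))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)

  set.seed(17)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 10) + 1, nrow = 3)
    o <- chisq_oracle(tab)
    r <- chi_square_independence(tab)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-8)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-8)
  }
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "expected")
})

test_that("BH adjustment and critical values follow the step-up rule", {
  res <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), q = 0.1)
  expect_equal(res$p_adj, rep(0.04, 4))
  expect_equal(res$critical, c(0.025, 0.05, 0.075, 0.1))
  expect_equal(bh_adjust(0.5)$p_adj, 0.5)

  set.seed(23)
  for (i in 1:10) {
    p <- runif(sample(5:40, 1))
    res <- bh_adjust(p, q = 0.1)
    expect_equal(res$p_adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(res$p_adj >= p - 1e-15))
    # monotone along sorted raw p, invariant to permutation
    o <- order(p)
    expect_true(all(diff(res$p_adj[o]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])$p_adj, res$p_adj[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("median and quartiles use linear interpolation", {
  expect_equal(unname(median_iqr(c(1, 2, 3, 4, 5))), c(3, 2, 4))
  expect_equal(unname(median_iqr(c(1, 2, 3, 4))), c(2.5, 1.75, 3.25))
  expect_equal(unname(median_iqr(7)), c(7, 7, 7))
  expect_error(median_iqr(c(NA_real_, NA_real_)), "empty")
})

test_that("group contrasts flag a planted shift and respect the null", {
  spec <- small_spec(
    n_proteins = 10, n_assay_params = 4, seed = 13,
    planted_shifts = data.frame(
      parameter = rep("CRP", 2),
      group = c("ami_control", "ami_post_covid"),
      effect = 2.5)
  )
  g <- generate_cohort(spec)
  res <- run_group_contrasts(g$cohort, g$panel, q = 0.1)
  crp <- res[res$parameter == "CRP" &
               res$group_b %in% c("control", "control_post_covid"), ]
  expect_true(all(crp$significant))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_true(all(res$significant == (res$p_adj < 0.1)))
  # categorical covariates run through Fisher
  expect_true(any(res$test == "fisher_exact" & res$parameter == "sex"))
  expect_error(run_group_contrasts(g$cohort, g$panel,
                                   contrasts = list(c("ami_control",
                                                      "nonsense"))),
               "unknown contrast group")
})

test_that("contrasts of two identical groups are never flagged", {
  spec <- small_spec(n_proteins = 8, n_assay_params = 2, seed = 29,
                     group_sizes = c(control = 22, control_post_covid = 4,
                                     ami_control = 22, ami_post_covid = 4))
  g <- generate_cohort(spec)
  co <- g$cohort
  # make ami_control a verbatim copy of control's measurements
  ctl <- co$data$group == "control"
  ami <- which(co$data$group == "ami_control")
  src <- which(ctl)[seq_along(ami)]
  co$data[ami, co$parameter_cols] <- co$data[src, co$parameter_cols]
  res <- run_group_contrasts(co, g$panel,
                             contrasts = list(c("ami_control", "control")),
                             include_covariates = FALSE)
  expect_false(any(res$significant))
})

test_that("confounder screen flags a monotone dependence and not noise", {
  spec <- small_spec(n_proteins = 6, n_assay_params = 2, seed = 19)
  g <- generate_cohort(spec)
  co <- g$cohort
  co$data$CRP <- co$data$bmi^2  # deterministic monotone function of BMI
  res <- confounder_screen(co)
  flagged <- res[res$flagged & !is.na(res$parameter), ]
  expect_true(any(flagged$covariate == "bmi" & flagged$parameter == "CRP"))
  expect_equal(res$rho[res$covariate == "bmi" & res$parameter == "CRP"], 1)
  # independent parameters should not be flagged for age
  expect_false(any(res$flagged[res$covariate == "age"]))
})

test_that("a planted BMI-complement correlation is recovered by the screen", {
  # emulate the observed BMI - complement C3 association by construction
  spec <- small_spec(n_proteins = 10, n_assay_params = 2, seed = 37)
  g <- generate_cohort(spec)
  co <- g$cohort
  n <- nrow(co$data)
  set.seed(37)
  z <- scale(log(co$data$bmi))
  co$data$complement_C3 <- exp(0.8 * z + sqrt(1 - 0.64) * rnorm(n))
  res <- confounder_screen(co)
  row <- res[res$covariate == "bmi" & res$parameter == "complement_C3", ]
  expect_true(row$flagged)
})
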