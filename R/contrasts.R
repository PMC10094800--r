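# Nonparametric group contrasts with BH-FDR control, summary statistics,
# and the covariate confounder screen.

#' Mann-Whitney U test for two independent samples
#'
#' Computes U from midranks and a two-sided p-value. For small tie-free
#' samples (both sizes at most 8 triggers when the smaller is) the exact
#' permutation distribution is used; otherwise the normal approximation
#' with tie correction and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples; `NA` removed. Each must be non-empty.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return List with `statistic` (U for the first sample), `p_value`,
#'   `method` ("exact" or "normal"), `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y, continuity = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  if (stats::var(pooled) == 0) {
    warning("all values identical across both samples; p = 1")
    U <- length(x) * length(y) / 2
    return(list(statistic = U, p_value = 1, method = "degenerate",
                n_x = length(x), n_y = length(y)))
  }
  exact <- !ties && min(length(x), length(y)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = continuity,
                       alternative = "two.sided")
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal",
       n_x = length(x), n_y = length(y))
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Two-tailed p-value by summation of hypergeometric probabilities not
#' exceeding that of the observed table; the conditional maximum-likelihood
#' odds ratio is reported.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return List with `odds_ratio`, `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  ft <- stats::fisher.test(table, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without Yates correction; degrees of freedom
#' `(r-1)(c-1)`.
#'
#' @param table r x c matrix of nonnegative integer counts, r, c >= 2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need at least a 2x2 table")
  if (any(table < 0)) stop("counts must be nonnegative")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("zero expected count")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Benjamini-Hochberg adjustment with critical values
#'
#' Step-up adjusted p-values (returned in input order) together with the
#' rank-matched critical values `i * q / m` of the BH procedure at level
#' `q`: each p-value's critical value corresponds to its rank among the
#' sorted raw p-values.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.1, the study's critical value for group
#'   contrasts).
#' @return List with `p_adj`, `critical` (both in input order), and
#'   `significant` (`p_adj < q`).
#' @export
bh_adjust <- function(p, q = 0.1) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  p_adj <- stats::p.adjust(p, method = "BH")
  critical <- numeric(m)
  critical[order(p)] <- seq_len(m) * q / m
  list(p_adj = p_adj, critical = critical, significant = p_adj < q)
}

#' Median and quartiles
#'
#' Median with first and third quartiles by linear interpolation
#' (`stats::quantile` type 7), the convention behind the reported
#' `median [Q1; Q3]` summaries.
#'
#' @param values Numeric sample; `NA` removed; must be non-empty.
#' @return Named numeric vector `(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty sample")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

format_median_iqr <- function(values, digits = 2) {
  s <- round(median_iqr(values), digits)
  sprintf("%s [%s; %s]", s[1], s[2], s[3])
}

# Default contrasts of the study: each AMI arm against its serostatus
# control and the two AMI arms against each other.
default_contrasts <- function() {
  list(c("ami_control", "ami_post_covid"),
       c("ami_control", "control"),
       c("ami_post_covid", "control_post_covid"),
       c("ami_post_covid", "control"))
}

#' Run all group contrasts with FDR control
#'
#' For every requested group pair and every tested column: continuous
#' parameters go through [mann_whitney_u()], binary categoricals through
#' [fisher_exact_2x2()], multi-category variables through
#' [chi_square_independence()]. P-values are BH-adjusted either within each
#' parameter block (assay) x contrast (default) or globally, and compared
#' with the critical value at level `q`.
#'
#' @param cohort A `cohort_table` with groups assigned.
#' @param panel A `panel_annotation` (defines the parameter blocks).
#' @param contrasts List of group pairs; defaults to the study's four.
#' @param q FDR level (default 0.1).
#' @param family `"per_block"` (default) or `"global"` BH family scope.
#' @param include_covariates Also contrast the clinical covariates
#'   (default `TRUE`).
#' @return Data frame of contrast results: one row per parameter x contrast
#'   with group sizes, `median [Q1; Q3]` summaries (continuous) or counts,
#'   test type and statistic, `p_raw`, `p_adj`, `bh_critical`,
#'   `significant`.
#' @export
run_group_contrasts <- function(cohort, panel, contrasts = NULL, q = 0.1,
                                family = c("per_block", "global"),
                                include_covariates = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  family <- match.arg(family)
  if (is.null(contrasts)) contrasts <- default_contrasts()
  for (ct in contrasts) {
    if (!all(ct %in% cohort_groups())) {
      stop("unknown contrast group: ", paste(setdiff(ct, cohort_groups()),
                                             collapse = ", "))
    }
  }
  assay_of <- stats::setNames(panel$assay, panel$parameter)
  cols <- cohort$parameter_cols
  if (include_covariates) cols <- c(cohort$covariate_cols, cols)
  rows <- list()
  for (ct in contrasts) {
    ga <- ct[1]; gb <- ct[2]
    da <- cohort$data[!is.na(cohort$data$group) & cohort$data$group == ga, ]
    db <- cohort$data[!is.na(cohort$data$group) & cohort$data$group == gb, ]
    for (col in cols) {
      va <- da[[col]]; vb <- db[[col]]
      block <- if (col %in% names(assay_of)) assay_of[[col]] else "clinical"
      is_cat <- is.logical(va) || is.character(va) || is.factor(va)
      if (!is_cat) {
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (length(va) == 0 || length(vb) == 0) next
        mw <- suppressWarnings(mann_whitney_u(va, vb))
        rows[[length(rows) + 1]] <- data.frame(
          parameter = col, group_a = ga, group_b = gb, block = block,
          test = "mann_whitney", n_a = length(va), n_b = length(vb),
          summary_a = format_median_iqr(va), summary_b = format_median_iqr(vb),
          statistic = mw$statistic, p_raw = mw$p_value,
          stringsAsFactors = FALSE
        )
      } else {
        fa <- factor(va[!is.na(va)]); fb <- factor(vb[!is.na(vb)])
        lev <- union(levels(fa), levels(fb))
        if (length(lev) < 2) next
        tab <- rbind(table(factor(fa, lev)), table(factor(fb, lev)))
        if (length(lev) == 2) {
          fe <- fisher_exact_2x2(tab)
          stat <- fe$odds_ratio; p <- fe$p_value; test <- "fisher_exact"
        } else {
          if (any(outer(rowSums(tab), colSums(tab)) == 0)) next
          cs <- chi_square_independence(tab)
          stat <- cs$statistic; p <- cs$p_value; test <- "chi_square"
        }
        rows[[length(rows) + 1]] <- data.frame(
          parameter = col, group_a = ga, group_b = gb, block = block,
          test = test, n_a = length(fa), n_b = length(fb),
          summary_a = paste0(sum(fa == lev[length(lev)]), "/", length(fa)),
          summary_b = paste0(sum(fb == lev[length(lev)]), "/", length(fb)),
          statistic = stat, p_raw = p, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame())
  }
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  res$bh_critical <- NA_real_
  fam_key <- if (family == "per_block") {
    paste(res$block, res$group_a, res$group_b)
  } else {
    rep("all", nrow(res))
  }
  for (k in unique(fam_key)) {
    idx <- fam_key == k
    adj <- bh_adjust(res$p_raw[idx], q = q)
    res$p_adj[idx] <- adj$p_adj
    res$bh_critical[idx] <- adj$critical
  }
  res$significant <- res$p_adj < q
  rownames(res) <- NULL
  res
}

#' Screen covariates for confounding of the measured parameters
#'
#' Pairwise-deletion Spearman correlation between each clinical covariate
#' (sex coded 0/1, smoking 0/1) and each measured parameter, BH-adjusted
#' within the screen; a covariate-parameter pair is flagged when
#' `|rho| > 0.5` and adjusted p < 0.05, the rule used to check that age and
#' gender did not drive the protein results while BMI correlated with
#' complement components.
#'
#' @param cohort A `cohort_table`.
#' @param covariates Covariate names (default the cohort's covariates).
#' @param parameters Parameter names (default all measurements).
#' @param rho_min Flagging threshold on `|rho|` (default 0.5).
#' @param alpha Flagging threshold on adjusted p (default 0.05).
#' @return Data frame `(covariate, parameter, rho, n_eff, p_raw, p_adj,
#'   flagged)`.
#' @export
confounder_screen <- function(cohort, covariates = NULL, parameters = NULL,
                              rho_min = 0.5, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(covariates)) covariates <- cohort$covariate_cols
  if (is.null(parameters)) parameters <- cohort$parameter_cols
  rows <- list()
  for (cv in covariates) {
    v <- cohort$data[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- as.numeric(factor(v)) - 1
    } else if (is.logical(v)) {
      v <- as.numeric(v)
    }
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("constant covariate: ", cv, " (not flagged)")
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, parameter = NA_character_, rho = NA_real_,
        n_eff = NA_integer_, p_raw = NA_real_, stringsAsFactors = FALSE)
      next
    }
    for (p in parameters) {
      sp <- spearman_pairwise(v, cohort$data[[p]])
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, parameter = p, rho = sp$rho, n_eff = sp$n_eff,
        p_raw = sp$p_value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  ok <- !is.na(res$p_raw)
  res$p_adj <- NA_real_
  if (any(ok)) res$p_adj[ok] <- bh_adjust(res$p_raw[ok], q = alpha)$p_adj
  res$flagged <- !is.na(res$rho) & abs(res$rho) > rho_min &
    !is.na(res$p_adj) & res$p_adj < alpha
  rownames(res) <- NULL
  res
}
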