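# Pairwise-deletion Spearman and partial correlation matrices.

#' Spearman correlation with pairwise deletion
#'
#' Correlation of midranks over the complete pairs of the two vectors. The
#' p-value uses the t approximation with `n_eff - 2` degrees of freedom.
#' Fewer than 4 complete pairs yields an unavailable (all-`NA`) result
#' rather than an error, so matrix assembly can continue.
#'
#' @param x,y Numeric vectors of equal length; `NA` marks missing.
#' @return List with `rho`, `n_eff`, `p_value`.
#' @export
spearman_pairwise <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4) {
    return(list(rho = NA_real_, n_eff = n, p_value = NA_real_))
  }
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, n_eff = n, p_value = NA_real_))
  }
  rho <- stats::cor(rx, ry)
  p <- spearman_p(rho, n)
  list(rho = rho, n_eff = as.integer(n), p_value = p)
}

# Two-sided p for a (partial) rank correlation via the t approximation,
# df = n - 2 - n_conditioned.
spearman_p <- function(rho, n, n_cond = 0) {
  df <- n - 2 - n_cond
  if (is.na(rho) || df < 1) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tval), df)
}

#' First-order partial correlation
#'
#' Correlation between x and y after removing the (rank-)linear effect of
#' z, from the three pairwise coefficients:
#' `(rho_xy - rho_xz rho_yz) / sqrt((1 - rho_xz^2)(1 - rho_yz^2))`.
#' Higher-order conditioning is obtained by recursion over the conditioning
#' set.
#'
#' @param rho_xy,rho_xz,rho_yz Pairwise correlation coefficients.
#' @return The partial coefficient, or `NA` if a denominator vanishes.
#' @export
partial_correlation <- function(rho_xy, rho_xz, rho_yz) {
  den <- (1 - rho_xz^2) * (1 - rho_yz^2)
  if (is.na(den) || den <= 0) return(NA_real_)
  (rho_xy - rho_xz * rho_yz) / sqrt(den)
}

# Partialize a full correlation matrix on the variables named in `cond`
# by recursive application of the first-order formula. Returns the matrix
# restricted to the non-conditioning variables.
partialize <- function(R, cond) {
  if (length(cond) == 0) return(R)
  z <- cond[1]
  keep <- setdiff(colnames(R), z)
  R2 <- R[keep, keep, drop = FALSE]
  for (i in seq_along(keep)) {
    for (j in seq_len(i - 1L)) {
      R2[i, j] <- R2[j, i] <- partial_correlation(
        R[keep[i], keep[j]], R[keep[i], z], R[keep[j], z])
    }
  }
  partialize(R2, cond[-1])
}

#' Per-group correlation matrix with pairwise deletion
#'
#' Computes the Spearman coefficient, effective pair count, and p-value for
#' every pair of the requested parameters within one group, with BH
#' adjustment over the complete list of available pairs in the matrix — the
#' adjustment family used for the full per-group correlation tables. A
#' non-empty `conditioning_set` yields partial correlations (recursively
#' partialized on those variables, which may be covariates such as age or
#' BMI); p-values then use `n_eff - 2 - |conditioning set|` degrees of
#' freedom.
#'
#' @param cohort A `cohort_table` with groups assigned.
#' @param group Group label.
#' @param parameters Parameter names (default all measurements).
#' @param conditioning_set Optional names (parameters or numeric
#'   covariates) to partialize on; empty means plain Spearman.
#' @return Object of class `correlation_matrix`: list with `parameters`,
#'   `group`, matrices `rho`, `n_eff`, `p_raw`, `p_adj`, and
#'   `conditioning_set`.
#' @export
correlation_matrix <- function(cohort, group, parameters = NULL,
                               conditioning_set = character()) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(parameters)) parameters <- cohort$parameter_cols
  all_cols <- c(parameters, conditioning_set)
  bad <- setdiff(all_cols, names(cohort$data))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  rows <- !is.na(cohort$data$group) & cohort$data$group == group
  X <- cohort$data[rows, all_cols, drop = FALSE]
  X <- as.data.frame(lapply(X, as.numeric))
  names(X) <- all_cols
  p <- length(all_cols)
  rho <- matrix(NA_real_, p, p, dimnames = list(all_cols, all_cols))
  n_eff <- matrix(0L, p, p, dimnames = dimnames(rho))
  diag(rho) <- 1
  diag(n_eff) <- as.integer(colSums(!is.na(X)))
  for (i in seq_len(p)) {
    for (j in seq_len(i - 1L)) {
      sp <- spearman_pairwise(X[[i]], X[[j]])
      rho[i, j] <- rho[j, i] <- sp$rho
      n_eff[i, j] <- n_eff[j, i] <- sp$n_eff
    }
  }
  k <- length(conditioning_set)
  if (k > 0) {
    # recursion needs a complete matrix; unavailable pairs enter as 0
    rho_fill <- rho
    rho_fill[is.na(rho_fill)] <- 0
    rho_part <- partialize(rho_fill, conditioning_set)
    keep <- parameters
    rho <- rho_part[keep, keep, drop = FALSE]
    rho[n_eff[keep, keep] < 4] <- NA_real_
    diag(rho) <- 1
    n_eff <- n_eff[keep, keep, drop = FALSE]
  }
  p_raw <- matrix(NA_real_, length(parameters), length(parameters),
                  dimnames = list(parameters, parameters))
  for (i in seq_along(parameters)) {
    for (j in seq_len(i - 1L)) {
      p_raw[i, j] <- p_raw[j, i] <- spearman_p(rho[i, j], n_eff[i, j], k)
    }
  }
  ut <- upper.tri(p_raw)
  p_adj <- p_raw
  avail <- ut & !is.na(p_raw)
  if (any(avail)) {
    adj <- bh_adjust(p_raw[avail], q = 0.05)$p_adj
    p_adj[avail] <- adj
    p_adj[t(avail)] <- t(p_adj)[t(avail)]
  }
  structure(
    list(parameters = parameters, group = group, rho = rho, n_eff = n_eff,
         p_raw = p_raw, p_adj = p_adj, conditioning_set = conditioning_set),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> group ", x$group, ", ",
      length(x$parameters), " parameters (",
      choose(length(x$parameters), 2), " pairs)",
      if (length(x$conditioning_set))
        paste0(", conditioned on ",
               paste(x$conditioning_set, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Write a correlation matrix as tidy and wide TSV
#'
#' @param mat A `correlation_matrix`.
#' @param path Base path; writes `<path>_wide.tsv` (rho) and
#'   `<path>_pairs.tsv` (pair, rho, n_eff, p_raw, p_adj).
#' @export
write_correlation_matrix <- function(mat, path) {
  utils::write.table(
    data.frame(parameter = rownames(mat$rho), mat$rho, check.names = FALSE),
    paste0(path, "_wide.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  idx <- which(upper.tri(mat$rho), arr.ind = TRUE)
  tidy <- data.frame(
    param_i = mat$parameters[idx[, 1]], param_j = mat$parameters[idx[, 2]],
    rho = mat$rho[idx], n_eff = mat$n_eff[idx], p_raw = mat$p_raw[idx],
    p_adj = mat$p_adj[idx]
  )
  utils::write.table(tidy, paste0(path, "_pairs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
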