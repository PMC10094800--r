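# Fisher-z differential correlation testing and network construction.

#' Compare two independent correlations by Fisher's z
#'
#' Transforms each coefficient by `atanh` and compares the difference
#' against its asymptotic standard error
#' `sqrt(c/(n_a - 3) + c/(n_b - 3))`, giving a two-sided normal p-value.
#' The default variance factor `c = 1.06` is the standard inflation for
#' Fisher-z of Spearman rank correlations (every coefficient this
#' pipeline compares is a Spearman coefficient); `c = 1` gives the
#' classical transform for Pearson correlations.
#'
#' @param rho_a,rho_b Correlation coefficients, `|rho| < 1`.
#' @param n_a,n_b Effective sample sizes, both > 3.
#' @param c_var Variance factor (default 1.06).
#' @return List with `z_stat` and `p_value`.
#' @export
differential_correlation_test <- function(rho_a, n_a, rho_b, n_b,
                                          c_var = 1.06) {
  if (any(c(n_a, n_b) <= 3)) stop("need n > 3 in both groups")
  if (any(abs(c(rho_a, rho_b)) >= 1)) {
    stop("|rho| = 1 gives an infinite z transform")
  }
  z <- (atanh(rho_a) - atanh(rho_b)) /
    sqrt(c_var / (n_a - 3) + c_var / (n_b - 3))
  list(z_stat = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Build differential-correlation networks for one contrast
#'
#' A pair forms an edge "present in A, absent in B" when (i) its
#' correlation in A is significant (adjusted p < `alpha`) and exceeds
#' `rho_min` in magnitude, (ii) the coefficients differ by at least
#' `delta_min`, and (iii) the Fisher-z difference test, BH-adjusted, is
#' below `alpha`; symmetrically for B. Under `rule = "both_significant"`
#' (the alternative reading in which an edge requires a significant
#' correlation in both groups) condition (i) must hold in both groups and
#' the edge is listed under the group with the larger `|rho|`.
#'
#' The BH family for the difference test is, by default, the screened
#' candidate pairs — those already passing (i) and (ii) for either group —
#' since only those are candidate differential edges;
#' `diff_family = "all"` adjusts over every testable pair instead.
#'
#' @param mat_a,mat_b `correlation_matrix` objects over the same parameters.
#' @param rho_min Minimum `|rho|` in the present group (default 0.5).
#' @param delta_min Minimum `|rho_a - rho_b|` (default 0.4).
#' @param alpha Significance level (default 0.05).
#' @param rule `"present_absent"` (default) or `"both_significant"`.
#' @param diff_family `"screened"` (default) or `"all"`.
#' @param c_var Fisher-z variance factor passed to
#'   [differential_correlation_test()].
#' @return List of two `differential_network` objects (`a`, `b`), each with
#'   the contrast, thresholds, and an edge table carrying `rho_a`, `rho_b`,
#'   `n_a`, `n_b`, `delta`, `z_stat`, `p_adj_diff`, `present_in`, `sign`.
#' @export
build_differential_network <- function(mat_a, mat_b, rho_min = 0.5,
                                       delta_min = 0.4, alpha = 0.05,
                                       rule = c("present_absent",
                                                "both_significant"),
                                       diff_family = c("screened", "all"),
                                       c_var = 1.06) {
  rule <- match.arg(rule)
  diff_family <- match.arg(diff_family)
  if (!identical(mat_a$parameters, mat_b$parameters)) {
    stop("correlation matrices have mismatched parameter sets")
  }
  params <- mat_a$parameters
  idx <- which(upper.tri(mat_a$rho), arr.ind = TRUE)
  df <- data.frame(
    param_i = params[idx[, 1]], param_j = params[idx[, 2]],
    rho_a = mat_a$rho[idx], rho_b = mat_b$rho[idx],
    n_a = mat_a$n_eff[idx], n_b = mat_b$n_eff[idx],
    p_adj_a = mat_a$p_adj[idx], p_adj_b = mat_b$p_adj[idx],
    stringsAsFactors = FALSE
  )
  df$delta <- df$rho_a - df$rho_b
  testable <- !is.na(df$rho_a) & !is.na(df$rho_b) &
    df$n_a > 3 & df$n_b > 3 & abs(df$rho_a) < 1 & abs(df$rho_b) < 1
  strong_a <- testable & !is.na(df$p_adj_a) & df$p_adj_a < alpha &
    abs(df$rho_a) > rho_min
  strong_b <- testable & !is.na(df$p_adj_b) & df$p_adj_b < alpha &
    abs(df$rho_b) > rho_min
  big_delta <- testable & abs(df$delta) >= delta_min
  cand_a <- strong_a & big_delta
  cand_b <- strong_b & big_delta
  if (rule == "both_significant") {
    both <- strong_a & strong_b & big_delta
    cand_a <- both & abs(df$rho_a) >= abs(df$rho_b)
    cand_b <- both & abs(df$rho_b) > abs(df$rho_a)
  }
  df$z_stat <- NA_real_
  df$p_raw_diff <- NA_real_
  tested <- if (diff_family == "screened") cand_a | cand_b else testable
  if (any(tested)) {
    for (r in which(tested)) {
      dt <- differential_correlation_test(df$rho_a[r], df$n_a[r],
                                          df$rho_b[r], df$n_b[r], c_var)
      df$z_stat[r] <- dt$z_stat
      df$p_raw_diff[r] <- dt$p_value
    }
    df$p_adj_diff <- NA_real_
    df$p_adj_diff[tested] <- bh_adjust(df$p_raw_diff[tested],
                                       q = alpha)$p_adj
  } else {
    df$p_adj_diff <- NA_real_
  }
  sig_diff <- !is.na(df$p_adj_diff) & df$p_adj_diff < alpha
  edge_a <- cand_a & sig_diff
  edge_b <- cand_b & sig_diff
  mk <- function(sel, present, rho_col) {
    e <- df[sel, c("param_i", "param_j", "rho_a", "rho_b", "n_a", "n_b",
                   "delta", "z_stat", "p_raw_diff", "p_adj_diff"),
            drop = FALSE]
    e$present_in <- rep(present, nrow(e))
    e$sign <- rep("", nrow(e))
    if (nrow(e) > 0) {
      e$sign <- ifelse(e[[rho_col]] >= 0, "positive", "negative")
    }
    rownames(e) <- NULL
    structure(
      list(contrast = c(group_a = mat_a$group, group_b = mat_b$group),
           present_in = present, edges = e,
           thresholds = list(rho_min = rho_min, delta_min = delta_min,
                             alpha = alpha, rule = rule,
                             diff_family = diff_family)),
      class = "differential_network"
    )
  }
  list(a = mk(edge_a, mat_a$group, "rho_a"),
       b = mk(edge_b, mat_b$group, "rho_b"))
}

#' @export
print.differential_network <- function(x, ...) {
  cat("<differential_network> present in ", x$present_in, " (contrast ",
      x$contrast[1], " vs ", x$contrast[2], "): ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Restrict a differential network to a class-by-class bipartite slice
#'
#' Keeps edges with one endpoint in `classes_a` and the other in
#' `classes_b` (per the panel annotation). Explicit parameter lists can
#' further restrict either side — e.g. side A limited to the fibrinolysis
#' assay parameters (`LOT, LP, CLT, LI, LTE`) against side B inflammation
#' plus complement, the slice shown for the fibrinolysis-inflammation-
#' complement subnetworks.
#'
#' @param network A `differential_network`.
#' @param panel A `panel_annotation`.
#' @param classes_a,classes_b Functional class sets for the two sides.
#' @param params_a,params_b Optional explicit parameter subsets for each
#'   side (applied after the class filter).
#' @return A `differential_network` with the filtered edge set.
#' @export
functional_subnetwork <- function(network, panel, classes_a, classes_b,
                                  params_a = NULL, params_b = NULL) {
  stopifnot(inherits(network, "differential_network"))
  bad <- setdiff(c(classes_a, classes_b), FUNCTIONAL_CLASSES)
  if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "))
  class_of <- stats::setNames(panel$functional_class, panel$parameter)
  side <- function(p, classes, subset) {
    in_class <- p %in% names(class_of) & class_of[p] %in% classes
    if (!is.null(subset)) in_class <- in_class & p %in% subset
    in_class
  }
  e <- network$edges
  keep <- (side(e$param_i, classes_a, params_a) &
             side(e$param_j, classes_b, params_b)) |
          (side(e$param_j, classes_a, params_a) &
             side(e$param_i, classes_b, params_b))
  network$edges <- e[keep, , drop = FALSE]
  rownames(network$edges) <- NULL
  network
}

#' Export a differential network
#'
#' `"tsv"` writes one edge per row with all attributes; `"graphml"` writes
#' an igraph GraphML file with node functional-class attributes and edge
#' attributes (`rho_a`, `rho_b`, `delta`, `sign`, `p_adj_diff`), with the
#' sign attribute carrying the positive/negative colouring of the
#' published network figures.
#'
#' @param network A `differential_network`.
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @param panel Optional `panel_annotation` for node class attributes.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml"),
                           panel = NULL) {
  stopifnot(inherits(network, "differential_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  nodes <- unique(c(e$param_i, e$param_j))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- if (length(nodes)) nodes else character()
  if (!is.null(panel) && length(nodes)) {
    class_of <- stats::setNames(panel$functional_class, panel$parameter)
    igraph::V(g)$functional_class <- unname(
      ifelse(nodes %in% names(class_of), class_of[nodes], "unknown"))
  }
  if (nrow(e) > 0) {
    g <- igraph::add_edges(g, rbind(match(e$param_i, nodes),
                                    match(e$param_j, nodes)))
    igraph::E(g)$rho_a <- e$rho_a
    igraph::E(g)$rho_b <- e$rho_b
    igraph::E(g)$delta <- e$delta
    igraph::E(g)$sign <- e$sign
    igraph::E(g)$p_adj_diff <- e$p_adj_diff
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
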