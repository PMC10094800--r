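# k-medoids clustering of parameters on a correlation-derived distance,
# with gap-statistic selection of the cluster number.

#' Turn a correlation matrix into a distance matrix
#'
#' `d = 1 - rho` (default; positively co-varying parameters are close) or
#' `d = 1 - |rho|`. Unavailable pairs are imputed as `rho = 0` with a
#' warning. The transform is recorded on the result.
#'
#' @param mat A `correlation_matrix`, or a plain symmetric correlation
#'   matrix.
#' @param transform `"one_minus_rho"` (default) or `"one_minus_abs_rho"`.
#' @return Symmetric nonnegative distance matrix with zero diagonal and a
#'   `transform` attribute.
#' @export
correlation_distance <- function(mat,
                                 transform = c("one_minus_rho",
                                               "one_minus_abs_rho")) {
  transform <- match.arg(transform)
  rho <- if (inherits(mat, "correlation_matrix")) mat$rho else as.matrix(mat)
  if (any(is.na(rho))) {
    warning("unavailable correlation pairs imputed as rho = 0")
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
  }
  d <- if (transform == "one_minus_rho") 1 - rho else 1 - abs(rho)
  diag(d) <- 0
  attr(d, "transform") <- transform
  d
}

# Total cost of a medoid set: sum of distances to the nearest medoid.
medoid_cost <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1, min))
}

#' k-medoids (PAM) with random restarts
#'
#' Runs the PAM swap phase from each of `restarts` random initial medoid
#' sets and keeps the lowest-cost solution. Deterministic given `seed`.
#'
#' @param d Distance matrix (as from [correlation_distance()]).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param restarts Number of random initializations (default 10, the
#'   study's setting).
#' @param seed Integer seed for the initial medoid draws.
#' @return Object of class `cluster_solution`: list with `k`, `medoids`
#'   (indices), `membership` (named integer vector), `total_cost`,
#'   `restarts`, `seed`.
#' @export
pam_cluster <- function(d, k, restarts = 10, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  params <- rownames(d)
  if (is.null(params)) params <- as.character(seq_len(n))
  if (k == n) {
    sol <- list(k = k, medoids = seq_len(n),
                membership = stats::setNames(seq_len(n), params),
                total_cost = 0, restarts = restarts, seed = seed)
    class(sol) <- "cluster_solution"
    return(sol)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- sample.int(n, k)
      fit <- cluster::pam(d, k, diss = TRUE, medoids = init,
                          do.swap = TRUE, cluster.only = FALSE,
                          keep.diss = FALSE, keep.data = FALSE)
      med <- as.integer(fit$id.med)
      cost <- medoid_cost(d, med)
      if (is.null(best) || cost < best$total_cost - 1e-12) {
        best <- list(medoids = med,
                     membership = as.integer(fit$clustering),
                     total_cost = cost)
      }
    }
  })
  sol <- list(k = k, medoids = best$medoids,
              membership = stats::setNames(best$membership, params),
              total_cost = best$total_cost, restarts = restarts, seed = seed)
  class(sol) <- "cluster_solution"
  sol
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k = ", x$k, ", total cost ",
      round(x$total_cost, 4), "\n", sep = "")
  print(table(x$membership))
  invisible(x)
}

# Within-cluster dispersion W_k = sum over clusters of (pairwise distance
# sum) / (2 * cluster size), on a precomputed distance matrix.
within_dispersion <- function(d, membership) {
  W <- 0
  for (cl in unique(membership)) {
    members <- which(membership == cl)
    if (length(members) > 1) {
      W <- W + sum(d[members, members]) / (2 * length(members))
    }
  }
  W
}

#' Gap statistic for the cluster number on correlation distance
#'
#' Clusters the parameters of a subjects-by-parameters data block on the
#' pairwise-deletion Spearman correlation distance for each `k`, and
#' compares the observed log within-cluster dispersion with that of `B`
#' Monte-Carlo reference datasets in which every parameter's subject values
#' are independently permuted (preserving marginals, destroying
#' correlation). `gap(k) = mean_b log W*_kb - log W_k`;
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`.
#'
#' @param data Numeric matrix, subjects x parameters (`NA` allowed;
#'   correlations use pairwise deletion).
#' @param k_max Largest k to evaluate (must be < number of parameters).
#' @param B Number of reference datasets (default 300, the study's
#'   setting).
#' @param restarts PAM restarts per clustering (default 10).
#' @param seed Integer seed; the whole curve is deterministic given it.
#' @param transform Correlation-to-distance transform.
#' @return Object of class `gap_curve`: `k_values`, `log_w`, `gap`, `s_k`,
#'   `B`, `k_hat` (selected by [select_k()]).
#' @export
gap_statistic <- function(data, k_max, B = 300, restarts = 10, seed = 1,
                          transform = "one_minus_rho") {
  data <- as.matrix(data)
  n_par <- ncol(data)
  if (k_max >= n_par) stop("k_max must be below the number of parameters")
  if (B < 2) stop("need B >= 2")
  if (all(apply(data, 2, function(v) stats::var(v, na.rm = TRUE) == 0))) {
    stop("degenerate data: all parameters constant")
  }
  dist_of <- function(X) {
    suppressWarnings(
      correlation_distance(pairwise_spearman_matrix(X), transform))
  }
  log_w_of <- function(d, sub_seed) {
    vapply(seq_len(k_max), function(k) {
      sol <- pam_cluster(d, k, restarts = restarts, seed = sub_seed + k)
      log(within_dispersion(d, sol$membership))
    }, numeric(1))
  }
  d_obs <- dist_of(data)
  log_w <- log_w_of(d_obs, child_seed(seed, 0))
  log_w_ref <- with_seed(child_seed(seed, 1), {
    t(vapply(seq_len(B), function(b) {
      Xb <- apply(data, 2, sample)
      log_w_of(dist_of(Xb), child_seed(seed, 1 + b))
    }, numeric(k_max)))
  })
  gap <- colMeans(log_w_ref) - log_w
  s_k <- apply(log_w_ref, 2, stats::sd) * sqrt(1 + 1 / B)
  curve <- structure(
    list(k_values = seq_len(k_max), log_w = log_w, gap = gap, s_k = s_k,
         B = B, k_hat = NA_integer_),
    class = "gap_curve"
  )
  curve$k_hat <- select_k(curve)
  curve
}

# Pairwise-deletion Spearman matrix of a plain numeric matrix. With
# complete data, ranking each column once and correlating is identical to
# per-pair ranking, so the vectorized path applies.
pairwise_spearman_matrix <- function(X) {
  if (!anyNA(X)) {
    R <- stats::cor(apply(X, 2, rank))
    dimnames(R) <- list(colnames(X), colnames(X))
    return(R)
  }
  p <- ncol(X)
  rho <- diag(1, p)
  dimnames(rho) <- list(colnames(X), colnames(X))
  for (i in seq_len(p)) {
    for (j in seq_len(i - 1L)) {
      rho[i, j] <- rho[j, i] <- spearman_pairwise(X[, i], X[, j])$rho
    }
  }
  rho
}

#' Select the cluster number from a gap curve
#'
#' First-standard-error rule: the smallest k with
#' `gap(k) >= gap(k+1) - s_{k+1}`; if no k satisfies it, the k maximising
#' the gap.
#'
#' @param curve A `gap_curve`.
#' @return Selected k.
#' @export
select_k <- function(curve) {
  gap <- curve$gap
  s <- curve$s_k
  k_max <- length(gap)
  if (k_max == 1) return(1L)
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) return(as.integer(k))
  }
  as.integer(which.max(gap))
}

#' @export
print.gap_curve <- function(x, ...) {
  print(data.frame(k = x$k_values, log_w = round(x$log_w, 4),
                   gap = round(x$gap, 4), s_k = round(x$s_k, 4)))
  cat("selected k =", x$k_hat, "(B =", x$B, "references)\n")
  invisible(x)
}

#' Match clusters across two group solutions
#'
#' Pairwise Jaccard index between every cluster of solution A and every
#' cluster of solution B over the shared parameter set, with each
#' A-cluster's best-matching B-cluster and the shared-member fraction
#' (|intersection| / |A-cluster|).
#'
#' @param sol_a,sol_b `cluster_solution` objects over the same parameters.
#' @return List with `jaccard` (matrix k_a x k_b) and `best` (data frame
#'   `cluster_a, cluster_b, jaccard, shared_fraction`).
#' @export
match_clusters_across_groups <- function(sol_a, sol_b) {
  pa <- names(sol_a$membership)
  pb <- names(sol_b$membership)
  shared <- intersect(pa, pb)
  if (length(shared) == 0) stop("solutions share no parameters")
  ma <- sol_a$membership[shared]
  mb <- sol_b$membership[shared]
  ka <- sort(unique(ma)); kb <- sort(unique(mb))
  J <- matrix(0, length(ka), length(kb),
              dimnames = list(paste0("a", ka), paste0("b", kb)))
  for (i in seq_along(ka)) {
    for (j in seq_along(kb)) {
      A <- shared[ma == ka[i]]
      B <- shared[mb == kb[j]]
      J[i, j] <- length(intersect(A, B)) / length(union(A, B))
    }
  }
  best <- data.frame(
    cluster_a = ka,
    cluster_b = kb[apply(J, 1, which.max)],
    jaccard = apply(J, 1, max)
  )
  best$shared_fraction <- vapply(seq_along(ka), function(i) {
    A <- shared[ma == ka[i]]
    B <- shared[mb == best$cluster_b[i]]
    length(intersect(A, B)) / length(A)
  }, numeric(1))
  list(jaccard = J, best = best)
}

#' Fraction of a designated parameter subset inside given clusters
#'
#' Supports statements of the form "85% of these proteins fall in clusters
#' 1 and 5": the share of `subset` members assigned to any of `clusters`.
#'
#' @param sol A `cluster_solution`.
#' @param subset Parameter names.
#' @param clusters Cluster ids.
#' @return Fraction in `[0, 1]`.
#' @export
cluster_subset_fraction <- function(sol, subset, clusters) {
  subset <- intersect(subset, names(sol$membership))
  if (length(subset) == 0) return(NA_real_)
  mean(sol$membership[subset] %in% clusters)
}
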