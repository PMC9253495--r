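#' Concatenated work/free rest-profile vector
#'
#' The clustering feature for one subject: the workday rest profile followed
#' by the free-day rest profile, each 288 slots anchored at 20:00
#' (20:00--19:59), 576 elements in total.
#'
#' @param work,free `rest_profile` objects with anchor 20.
#' @return Numeric vector of length 576.
#' @export
profile_vector <- function(work, free) {
  for (p in list(work, free)) {
    if (!inherits(p, "rest_profile") || length(p) != 288) {
      stop_input("inputs must be 288-slot rest profiles")
    }
    if (!identical(as.numeric(attr(p, "anchor")), 20)) {
      stop_input("profiles must be anchored at 20:00 for clustering")
    }
  }
  c(as.numeric(work), as.numeric(free))
}

# Within-cluster dispersion W_k = sum_m 1/(2 n_m) sum_{i,j in C_m} d(x_i,x_j)
# with d the squared Euclidean distance, i.e. the within-cluster sum of
# squares about the cluster centroids.
wk_dispersion <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(idx) {
    if (length(idx) < 2) return(0)
    D2 <- as.matrix(stats::dist(X[idx, , drop = FALSE]))^2
    sum(D2) / (2 * length(idx))
  }, 0))
}

#' Ward clustering of rest-profile vectors
#'
#' Agglomerative clustering with Ward's method on the Euclidean distance
#' between concatenated work/free rest profiles, with the within-cluster
#' dispersion `W_k` evaluated for each candidate number of clusters.
#'
#' @param X numeric matrix, one 576-element profile vector per row (row
#'   names = subject ids).
#' @param kmax largest number of clusters evaluated.
#' @return A `cluster_result`: list with `tree` (hclust), `wk` (named vector
#'   for k = 1..kmax), `k` (elbow choice, see [elbow_select()]),
#'   `labels` (membership at the chosen k) and `labels_by_k`.
#' @export
ward_cluster <- function(X, kmax = 8) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop_input("need at least 3 subjects to cluster")
  kmax <- min(kmax, nrow(X))
  tree <- stats::hclust(stats::dist(X), method = "ward.D2")
  labels_by_k <- lapply(seq_len(kmax), function(k) stats::cutree(tree, k))
  wk <- vapply(labels_by_k, function(lab) wk_dispersion(X, lab), 0)
  names(wk) <- seq_len(kmax)
  k <- elbow_select(wk)
  structure(list(tree = tree, wk = wk, k = k$k, no_elbow = k$no_elbow,
                 labels = labels_by_k[[k$k]], labels_by_k = labels_by_k),
            class = "cluster_result")
}

#' Elbow selection of the number of clusters
#'
#' Picks the k (2..kmax-1) maximizing the second difference
#' `W(k-1) - 2 W(k) + W(k+1)` -- the strongest flattening of the dispersion
#' curve; ties resolve to the smaller k.  A (near-)linear `W_k` sequence has
#' no elbow: k = 1 is returned flagged.
#'
#' @param wk within-cluster dispersion for k = 1..kmax (kmax >= 3).
#' @return List with `k` and `no_elbow`.
#' @export
elbow_select <- function(wk) {
  kmax <- length(wk)
  if (kmax < 3) stop_input("need W_k for at least k = 1..3")
  d2 <- wk[seq_len(kmax - 2)] - 2 * wk[seq_len(kmax - 2) + 1] +
    wk[seq_len(kmax - 2) + 2]                     # indexed by k = 2..kmax-1
  if (max(d2) <= 1e-8 * max(abs(wk), 1e-300)) {
    return(list(k = 1L, no_elbow = TRUE))
  }
  list(k = as.integer(which.max(d2) + 1L), no_elbow = FALSE)
}

#' Cluster sizes and shares
#'
#' @param labels integer cluster memberships.
#' @return A `data.frame` with cluster, n and percentage share (one
#'   decimal, e.g. an 11-member cluster of 63 subjects = 17.5).
#' @export
cluster_shares <- function(labels) {
  tab <- table(labels)
  data.frame(cluster = as.integer(names(tab)), n = as.integer(tab),
             share_pct = round(100 * as.integer(tab) / length(labels), 1))
}

#' Compare circadian parameters across clusters
#'
#' Kruskal-Wallis test of each parameter across cluster memberships, per
#' scope; singleton clusters are kept and flagged.
#'
#' @param result a [ward_cluster()] result.
#' @param params per-subject parameter `data.frame` containing `subject_id`,
#'   `scope` and numeric parameter columns; subject order must match the
#'   clustered matrix rows.
#' @param vars parameter columns to test.
#' @return A `data.frame` of Kruskal-Wallis p-values per scope and variable.
#' @export
cluster_summary <- function(result, params,
                            vars = c("p11", "rest_amount_h", "centre_time",
                                     "rhythm_index")) {
  if (length(unique(result$labels)) < 2) {
    stop_input("cluster comparison needs at least 2 clusters")
  }
  singletons <- names(which(table(result$labels) == 1))
  lab <- data.frame(subject_id = names(result$labels) %||%
                      rownames(as.matrix(result$labels)),
                    cluster = as.integer(result$labels))
  df <- merge(params, lab, by = "subject_id")
  out <- do.call(rbind, lapply(split(df, df$scope), function(d) {
    data.frame(scope = d$scope[1], variable = vars,
               p_value = vapply(vars, function(v) {
                 stats::kruskal.test(d[[v]], factor(d$cluster))$p.value
               }, 0))
  }))
  rownames(out) <- NULL
  attr(out, "singleton_clusters") <- as.integer(singletons)
  out
}
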