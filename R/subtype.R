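#' Partition cases into phenotypic subtypes by K-means
#'
#' Lloyd-style K-means on an individuals x items severity matrix with
#' missing-aware distances: the squared Euclidean distance between a row
#' `x` and a centroid `c` is computed over the observed items `O` of `x`
#' and rescaled by `p / |O|` (`p` = number of items), so individuals with
#' sparse missingness are clustered rather than dropped. Centroids are
#' per-cluster means over observed entries. The per-row rescaling does not
#' change which centroid is nearest, so the reported objective is the
#' unscaled total within-cluster observed sum of squares, which Lloyd
#' iterations never increase.
#'
#' The best of `n_restarts` random restarts (centroids seeded from data
#' rows) is returned; a run converges when the assignment stops changing.
#' A cluster that empties during iteration is re-seeded from the point
#' farthest from its current centroid.
#'
#' @param scores numeric matrix (individuals x items), `NA` = missing; every
#'   row must have at least one observed item.
#' @param K number of clusters (1 <= K <= nrow).
#' @param n_restarts random restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @param seed integer seed; the run is deterministic given it.
#' @return Object of class `subtype_assignment`: list with `K`, `cluster`
#'   (named integer vector, case id -> cluster index), `centroids` (K x p),
#'   `sizes`, `objective`, `objective_trace` (objective after each iteration
#'   of the winning restart), and `names` (`NULL` until [name_clusters()]).
#' @export
kmeans_cluster <- function(scores, K, n_restarts = 10L, max_iter = 100L,
                           seed = 1L) {
  X <- as.matrix(scores)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (K < 1L || K > n) stop("K must be between 1 and the number of cases (", n, ")")
  M <- !is.na(X)
  if (any(rowSums(M) == 0L)) stop("row(s) with no observed items cannot be clustered")
  X0 <- X; X0[!M] <- 0
  col_mean <- colSums(X0) / pmax(colSums(M), 1L)
  x2 <- rowSums(X0^2)

  dist_to <- function(C) {
    # n x K matrix of observed-items squared distances (unscaled)
    sweep(-2 * (X0 %*% t(C)) + M %*% t(C^2), 1L, x2, "+")
  }
  objective <- function(D, assign) sum(D[cbind(seq_len(n), assign)])

  one_run <- function() {
    C <- X[sample.int(n, K), , drop = FALSE]
    C[is.na(C)] <- matrix(col_mean, K, p, byrow = TRUE)[is.na(C)]
    D <- dist_to(C)
    assign <- max.col(-D, ties.method = "first")
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      for (k in seq_len(K)) {
        members <- which(assign == k)
        if (length(members) == 0L) {
          far <- which.max(D[cbind(seq_len(n), assign)])
          C[k, ] <- ifelse(M[far, ], X[far, ], col_mean)
        } else {
          num <- colSums(X0[members, , drop = FALSE])
          den <- colSums(M[members, , drop = FALSE])
          C[k, ] <- ifelse(den > 0L, num / pmax(den, 1L), col_mean)
        }
      }
      D <- dist_to(C)
      new_assign <- max.col(-D, ties.method = "first")
      trace <- c(trace, objective(D, new_assign))
      if (all(new_assign == assign)) { assign <- new_assign; break }
      assign <- new_assign
    }
    list(assign = assign, C = C, obj = objective(D, assign), trace = trace)
  }

  best <- with_seed(seed, {
    runs <- lapply(seq_len(n_restarts), function(r) one_run())
    runs[[which.min(vapply(runs, `[[`, numeric(1L), "obj"))]]
  })

  cluster <- best$assign
  names(cluster) <- rownames(X)
  structure(list(K = K, cluster = cluster, centroids = best$C,
                 sizes = tabulate(cluster, K), objective = best$obj,
                 objective_trace = best$trace, names = NULL),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("subtype_assignment: K =", x$K, ", n =", length(x$cluster),
      ", objective =", format(x$objective, digits = 6), "\n")
  sz <- x$sizes
  names(sz) <- if (!is.null(x$names)) x$names else paste0("cluster", seq_len(x$K))
  print(sz)
  invisible(x)
}

#' Figure-of-merit curve for choosing the cluster number
#'
#' Leave-one-item-out figure of merit (FOM): for each left-out item column
#' `e`, the remaining columns are clustered into K groups and
#' `FOM(e) = sqrt(mean over scored cases of (x[case, e] - cluster mean of
#' e)^2)` measures how well the clustering predicts the held-out item.
#' `FOM(K) = sum over e of FOM(e)`, divided by the adjustment factor
#' `sqrt((n - K) / n)` which compensates for the mechanical decrease of FOM
#' with K. Lower is better; the elbow of the adjusted curve indicates the
#' number of phenotypic subtypes the data support.
#'
#' @param scores severity matrix as in [kmeans_cluster()].
#' @param k_range integer vector of K values (each < nrow).
#' @param seed integer seed.
#' @param n_restarts,max_iter passed to [kmeans_cluster()] (smaller defaults:
#'   the curve needs `length(k_range) * ncol(scores)` clustering runs).
#' @return data.frame with columns `K` and `fom` (adjusted figure of merit).
#' @export
fom_curve <- function(scores, k_range, seed = 1L, n_restarts = 3L,
                      max_iter = 50L) {
  if (length(k_range) == 0L) stop("k_range is empty")
  X <- as.matrix(scores)
  n <- nrow(X); p <- ncol(X)
  if (any(k_range >= n)) stop("every K must be < number of cases (", n, ")")
  fom <- vapply(seq_along(k_range), function(ki) {
    K <- k_range[ki]
    per_item <- vapply(seq_len(p), function(e) {
      asg <- kmeans_cluster(X[, -e, drop = FALSE], K, n_restarts = n_restarts,
                            max_iter = max_iter,
                            seed = seed + 1000L * ki + e)$cluster
      x_e <- X[, e]
      ok <- !is.na(x_e)
      if (!any(ok)) return(0)
      cl_mean <- tapply(x_e[ok], asg[ok], mean)
      pred <- cl_mean[as.character(asg[ok])]
      sqrt(mean((x_e[ok] - pred)^2))
    }, numeric(1L))
    sum(per_item) / sqrt((n - K) / n)
  }, numeric(1L))
  data.frame(K = as.integer(k_range), fom = fom)
}

#' Elbow of a figure-of-merit curve
#'
#' Picks the cluster number at the knee of an adjusted FOM curve computed
#' over consecutive K values: the interior K maximising the second
#' difference, i.e. the drop achieved by going to K minus the drop achieved
#' by going past it. The raw argmin is not useful here because the adjusted
#' FOM keeps creeping down slowly past the true cluster number.
#'
#' @param curve data.frame from [fom_curve()] over consecutive K values
#'   (at least 3).
#' @return The elbow K (integer).
#' @export
fom_elbow <- function(curve) {
  curve <- curve[order(curve$K), ]
  if (nrow(curve) < 3L || any(diff(curve$K) != 1L))
    stop("fom_elbow needs >= 3 consecutive K values")
  f <- curve$fom
  knee <- (f[-c(nrow(curve) - 1L, nrow(curve))] - f[-c(1L, nrow(curve))]) -
          (f[-c(1L, nrow(curve))] - f[-(1:2)])
  curve$K[which.max(knee) + 1L]
}

#' Principal-components projection of the severity matrix
#'
#' Missing entries are imputed by the item (column) mean, the matrix is
#' centered, and the leading principal components are returned; used to
#' verify visually and numerically that K-means subtypes are separable in an
#' unsupervised low-dimensional view.
#'
#' @param scores severity matrix (individuals x items), `NA` allowed.
#' @param n_components number of components to keep (default 2).
#' @return List with `scores` (individuals x components), `explained`
#'   (variance fractions, decreasing, summing to <= 1 over the kept
#'   components), `rotation`, and `center`.
#' @export
pca_project <- function(scores, n_components = 2L) {
  X <- as.matrix(scores)
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[!miss, j])
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nc)],
       rotation = pc$rotation[, seq_len(nc), drop = FALSE],
       center = pc$center)
}

#' Name clusters by severity rank
#'
#' Ranks clusters by their mean severity over all observed entries of their
#' member rows, descending, and attaches rank-based labels. For K = 4 the
#' conventional subtype labels are used, most to least severe:
#' `"Language-impaired"`, `"Intermediate"`, `"Moderate"`, `"Mild"` (the most
#' severe cluster is dominated by spoken-language deficits in the data this
#' convention comes from). For other K the labels are `"rank1"` (most
#' severe) ... `"rankK"`. Ties in mean severity are broken by cluster index.
#'
#' @param assignment a `subtype_assignment` from [kmeans_cluster()].
#' @param scores the severity matrix that was clustered.
#' @return The assignment with `names` filled (cluster index -> label) and a
#'   `case_names` element (case id -> label).
#' @export
name_clusters <- function(assignment, scores) {
  X <- as.matrix(scores)
  K <- assignment$K
  sev <- vapply(seq_len(K), function(k) {
    rows <- X[assignment$cluster == k, , drop = FALSE]
    mean(rows, na.rm = TRUE)
  }, numeric(1L))
  rank_order <- order(-sev, seq_len(K))  # severe first, ties by index
  labels <- if (K == 4L) {
    c("Language-impaired", "Intermediate", "Moderate", "Mild")
  } else {
    paste0("rank", seq_len(K))
  }
  nm <- character(K)
  nm[rank_order] <- labels
  assignment$names <- nm
  assignment$case_names <- stats::setNames(nm[assignment$cluster],
                                           names(assignment$cluster))
  assignment
}
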