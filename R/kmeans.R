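#' Lloyd k-means in normalized feature space
#'
#' Alternates nearest-centroid assignment (squared Euclidean distance,
#' ties to the lowest centroid index) and centroid-mean updates until the
#' assignment stabilizes, the largest centroid movement falls below `tol`,
#' or `max_iter` is reached. Empty clusters are re-seeded at the data
#' point farthest from the empty centroid. The within-cluster sum of
#' squares (WSS) is non-increasing across iterations.
#'
#' @param X numeric matrix or data.frame of normalized features (rows =
#'   patients).
#' @param k number of clusters, `1 <= k <=` number of distinct rows.
#' @param init optional `k x ncol(X)` matrix of initial centroids; when
#'   absent, centroids are drawn from the data rows using `seed`.
#' @param seed integer seed for random initialization (ignored when `init`
#'   is supplied).
#' @param max_iter maximum number of Lloyd iterations.
#' @param tol convergence tolerance on centroid movement, in normalized
#'   units.
#' @param init_method `"forgy"` (k distinct data rows sampled uniformly)
#'   or `"kmeans++"` (distance-squared weighted seeding).
#' @return object of class `kmeans_fit`: list with `k`, `centroids`,
#'   `assignment` (1-based), `wss`, `iterations`, `converged`,
#'   `wss_trace`, `seed`.
#' @examples
#' X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' fit <- lloyd_kmeans(X, k = 2, seed = 1)
#' fit$wss  # 1.0 at the global optimum
#' @export
lloyd_kmeans <- function(X, k, init = NULL, seed = 1L, max_iter = 100L,
                         tol = 1e-6, init_method = c("forgy", "kmeans++")) {
  init_method <- match.arg(init_method)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) pd_stop("lloyd_kmeans: non-finite values in X")
  n_distinct <- nrow(unique(X))
  if (k < 1L) pd_stop("lloyd_kmeans: k must be >= 1")
  if (k > n_distinct)
    pd_stop("lloyd_kmeans: k (", k, ") exceeds the number of distinct rows (",
            n_distinct, ")")
  if (is.null(init)) {
    init <- with_seed(seed, init_centroids(X, k, init_method))
  } else {
    init <- as.matrix(init)
    if (nrow(init) != k || ncol(init) != ncol(X))
      pd_stop("lloyd_kmeans: init must be a ", k, " x ", ncol(X), " matrix")
  }
  res <- .lloyd_cpp(X, init, as.integer(max_iter), tol)
  structure(list(k = k, centroids = res$centroids,
                 assignment = res$assignment + 1L, wss = res$wss,
                 iterations = res$iterations, converged = res$converged,
                 wss_trace = res$wss_trace, seed = seed),
            class = "kmeans_fit")
}

# internal: seeded centroid initialization on distinct rows
init_centroids <- function(X, k, method, distinct = FALSE) {
  U <- if (distinct) X else unique(X)
  if (method == "forgy") return(U[sample.int(nrow(U), k), , drop = FALSE])
  # kmeans++: first centre uniform, then D^2-weighted
  idx <- sample.int(nrow(U), 1L)
  for (j in seq_len(k - 1L)) {
    C <- U[idx, , drop = FALSE]
    d2 <- apply(U, 1L, function(r) min(colSums((t(C) - r)^2)))
    d2[idx] <- 0
    idx <- c(idx, sample.int(nrow(U), 1L, prob = d2 / sum(d2)))
  }
  U[idx, , drop = FALSE]
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat("Lloyd k-means fit: k =", x$k, "| WSS =", format(x$wss, digits = 6),
      "|", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("cluster sizes:", tabulate(x$assignment, x$k), "\n")
  invisible(x)
}

#' Restart-controlled k-means
#'
#' Runs `n_restarts` independent Lloyd fits from seeded random
#' initializations and returns the fit with the minimum within-cluster sum
#' of squares, guarding against local optima. Sub-seeds are spawned
#' deterministically from `seed`, so the result is reproducible.
#'
#' @inheritParams lloyd_kmeans
#' @param n_restarts number of random restarts.
#' @return the best [lloyd_kmeans()] fit, with an extra element
#'   `restart_wss` holding every restart's WSS.
#' @export
kmeans_restarts <- function(X, k, n_restarts = 100L, max_iter = 100L,
                            seed = 1L, tol = 1e-6,
                            init_method = c("forgy", "kmeans++")) {
  init_method <- match.arg(init_method)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) pd_stop("kmeans_restarts: non-finite values in X")
  U <- unique(X)
  if (k < 1L || k > nrow(U))
    pd_stop("kmeans_restarts: k must lie in [1, number of distinct rows]")
  seeds <- spawn_seeds(seed, n_restarts)
  best <- NULL
  best_seed <- NA_integer_
  all_wss <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- with_seed(seeds[r], init_centroids(U, k, init_method,
                                               distinct = TRUE))
    res <- .lloyd_cpp(X, init, as.integer(max_iter), tol)
    all_wss[r] <- res$wss
    if (is.null(best) || res$wss < best$wss) {
      best <- res
      best_seed <- seeds[r]
    }
  }
  structure(list(k = k, centroids = best$centroids,
                 assignment = best$assignment + 1L, wss = best$wss,
                 iterations = best$iterations, converged = best$converged,
                 wss_trace = best$wss_trace, seed = best_seed,
                 restart_wss = all_wss),
            class = "kmeans_fit")
}

#' Calinski-Harabasz pseudo-F index
#'
#' `CH = [B / (k - 1)] / [W / (n - k)]` where `B` is the between-cluster
#' dispersion `sum_j n_j ||c_j - c_bar||^2` and `W` the pooled
#' within-cluster sum of squared distances to centroids. Larger is better;
#' `+Inf` when `W = 0` with `B > 0` (perfectly tight, separated clusters).
#'
#' @param X numeric matrix of features.
#' @param assignment integer cluster index per row; every cluster in
#'   `1..k` must be non-empty, with `2 <= k < n`.
#' @return the pseudo-F value.
#' @export
calinski_harabasz <- function(X, assignment) {
  X <- as.matrix(X)
  n <- nrow(X)
  cl <- sort(unique(assignment))
  k <- length(cl)
  if (k < 2L) pd_stop("calinski_harabasz: need at least 2 clusters")
  if (n <= k) pd_stop("calinski_harabasz: need n > k")
  grand <- colMeans(X)
  W <- 0
  B <- 0
  for (j in cl) {
    rows <- X[assignment == j, , drop = FALSE]
    cj <- colMeans(rows)
    W <- W + sum(sweep(rows, 2L, cj)^2)
    B <- B + nrow(rows) * sum((cj - grand)^2)
  }
  if (W == 0) return(if (B > 0) Inf else NaN)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of subtypes by the Calinski-Harabasz criterion
#'
#' Fits restart-controlled k-means for every `k` in `k_range` and keeps
#' the per-k best fit; the selected `k` maximizes the pseudo-F value, with
#' ties broken toward smaller `k` (parsimony).
#'
#' @inheritParams kmeans_restarts
#' @param k_range integer vector of candidate cluster numbers (default
#'   `2:10`).
#' @return object of class `selection_trace`: list with `trace`
#'   (data.frame `k`, `wss`, `ch`), `selected`, and `fits` (per-k best
#'   [lloyd_kmeans()] fits, named by `k`).
#' @export
select_k <- function(X, k_range = 2:10, n_restarts = 100L, max_iter = 100L,
                     seed = 1L, tol = 1e-6,
                     init_method = c("forgy", "kmeans++")) {
  init_method <- match.arg(init_method)
  X <- as.matrix(X)
  if (max(k_range) >= nrow(X)) pd_stop("select_k: max(k_range) must be < n")
  seeds <- spawn_seeds(seed, length(k_range))
  fits <- vector("list", length(k_range))
  ch <- wss <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- kmeans_restarts(X, k_range[i], n_restarts = n_restarts,
                                 max_iter = max_iter, seed = seeds[i],
                                 tol = tol, init_method = init_method)
    wss[i] <- fits[[i]]$wss
    ch[i] <- calinski_harabasz(X, fits[[i]]$assignment)
  }
  names(fits) <- k_range
  sel <- k_range[which.max(ch)] # which.max: first maximum -> smallest k on ties
  structure(list(trace = data.frame(k = k_range, wss = wss, ch = ch),
                 selected = sel, fits = fits),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Cluster-number selection (Calinski-Harabasz)\n")
  print(x$trace, row.names = FALSE)
  cat("selected k =", x$selected, "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same rows;
#' 1 means identical partitions, 0 is the expectation under independent
#' random partitions.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) pd_stop("length mismatch")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
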