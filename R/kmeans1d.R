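#' Optimal univariate k-means by dynamic programming
#'
#' Globally optimal partition of real values into `k` contiguous groups (in
#' sorted order) minimizing the within-cluster sum of squares, computed by
#' the exact O(k n^2) dynamic program. Deterministic; clusters are returned
#' ordered by center.
#'
#' @param values numeric vector, `length(values) >= k`.
#' @param k number of clusters (>= 1). If `k` exceeds the number of distinct
#'   values it is reduced with a warning.
#' @return list with `cluster` (assignment per input value, 1 = lowest
#'   center), `centers` (ascending), `withinss` (per cluster), `k`.
#' @export
kmeans_1d <- function(values, k) {
  n <- length(values)
  if (k < 1) stop("k must be >= 1")
  if (n < k) stop("need at least k values")
  n_distinct <- length(unique(values))
  if (k > n_distinct) {
    warning("k reduced to the number of distinct values (", n_distinct, ")")
    k <- n_distinct
  }
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # SSE of x[i..j]
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(0, s2 - s^2 / (j - i + 1))
  }
  # D[m, j]: optimal cost of first j points in m clusters; B[m, j]: split start
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        for (i in m:j) {
          cand <- D[m - 1, i - 1] + sse(i, j)
          if (cand < D[m, j]) {
            D[m, j] <- cand
            B[m, j] <- i
          }
        }
      }
    }
  }
  # backtrack cluster boundaries
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else B[m, j]
    bounds[m] <- i
    j <- i - 1
  }
  cl_sorted <- rep(seq_len(k), times = diff(c(bounds[1:k], n + 1)))
  # map back to input order
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  centers <- vapply(seq_len(k), function(m) mean(x[cl_sorted == m]), numeric(1))
  withinss <- vapply(seq_len(k), function(m) {
    xi <- x[cl_sorted == m]
    sum((xi - mean(xi))^2)
  }, numeric(1))
  list(cluster = cluster, centers = centers, withinss = withinss, k = k)
}
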