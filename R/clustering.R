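#' K-means intensity clustering parameters
#'
#' @param n_clusters number of color groups.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param n_init number of k-means++ restarts; the run with the lowest
#'   within-cluster sum of squares wins.
#' @param seed integer seed making the whole procedure deterministic.
#' @return a `kmeans_params` object.
#' @export
kmeans_params <- function(n_clusters = 5L, max_iter = 50L, n_init = 3L,
                          seed = 0L) {
  stopifnot(is.numeric(n_clusters), length(n_clusters) == 1L, n_clusters >= 1,
            is.numeric(max_iter), length(max_iter) == 1L, max_iter >= 1,
            is.numeric(n_init), length(n_init) == 1L, n_init >= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_clusters = as.integer(n_clusters),
                 max_iter = as.integer(max_iter),
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = c("kmeans_params", "segment_params"))
}

#' K-means image segmentation
#'
#' Groups pixels by raw RGB intensity: Lloyd's algorithm with k-means++
#' initialization, restarted `n_init` times, keeping the assignment with
#' the lowest within-cluster sum of squares.  Each pixel joins the nearest
#' centroid by Euclidean distance.  Unlike the superpixel generators,
#' clusters need not be spatially connected; [propose()] splits them into
#' connected components so segments stay spatially selectable.
#'
#' Empty clusters (possible when `n_clusters` exceeds the number of
#' distinct colors) are re-seeded at the pixel farthest from its current
#' centroid.  Cluster ids are renumbered in row-major order of first pixel
#' occurrence, so a fixed seed gives a bit-identical map.
#'
#' @param img a `raster_image`.
#' @param params a [kmeans_params()].
#' @return a `superpixel_map` whose "segments" are color clusters;
#'   `attr(, "sse_trace")` holds the per-iteration sum of squares of the
#'   winning restart (non-increasing) and `attr(, "centers")` the final
#'   `n_clusters x 3` centroid matrix.
#' @export
kmeans_segment <- function(img, params = kmeans_params()) {
  assert_image(img)
  stopifnot(inherits(params, "kmeans_params"))
  d <- image_dim(img)
  N <- prod(d)
  if (params$n_clusters > N)
    stop("`n_clusters` exceeds the pixel count", call. = FALSE)
  # row-major pixel matrix so that first-occurrence relabeling follows
  # reading order
  X <- cbind(as.vector(t(unclass(img)[, , 1])),
             as.vector(t(unclass(img)[, , 2])),
             as.vector(t(unclass(img)[, , 3])))
  best <- NULL
  withr::with_seed(params$seed, {
    for (run in seq_len(params$n_init)) {
      fit <- lloyd_kmeans(X, params$n_clusters, params$max_iter)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  })
  # relabel by first occurrence (row-major)
  remap <- integer(params$n_clusters)
  seen <- logical(params$n_clusters)
  nxt <- 0L
  for (a in best$assign) {
    if (!seen[a]) {
      seen[a] <- TRUE
      remap[a] <- nxt
      nxt <- nxt + 1L
    }
  }
  labels <- matrix(remap[best$assign], nrow = d[1], ncol = d[2], byrow = TRUE)
  out <- new_superpixel_map(labels)
  centers <- best$centers
  present <- which(seen)
  centers[remap[present] + 1L, ] <- best$centers[present, ]
  attr(out, "centers") <- centers
  attr(out, "sse_trace") <- best$trace
  out
}

# Lloyd's algorithm with k-means++ seeding; returns 1-based assignments,
# centers, final SSE and the per-iteration SSE trace.
lloyd_kmeans <- function(X, k, max_iter) {
  N <- nrow(X)
  centers <- X[kmeanspp_init(X, k), , drop = FALSE]
  trace <- numeric(0)
  assign <- integer(N)
  for (iter in seq_len(max_iter)) {
    D2 <- point_center_dist2(X, centers)
    new_assign <- max.col(-D2, ties.method = "first")
    sse <- sum(D2[cbind(seq_len(N), new_assign)])
    # re-seed empty clusters at the point farthest from its centroid
    counts <- tabulate(new_assign, nbins = k)
    if (any(counts == 0L)) {
      for (j in which(counts == 0L)) {
        far <- which.max(D2[cbind(seq_len(N), new_assign)])
        centers[j, ] <- X[far, ]
        D2 <- point_center_dist2(X, centers)
        new_assign <- max.col(-D2, ties.method = "first")
      }
      sse <- sum(D2[cbind(seq_len(N), new_assign)])
    }
    trace <- c(trace, sse)
    converged <- iter > 1L && all(new_assign == assign)
    assign <- new_assign
    for (j in seq_len(k)) {
      m <- assign == j
      if (any(m)) centers[j, ] <- colMeans(X[m, , drop = FALSE])
    }
    if (converged) break
  }
  list(assign = assign, centers = centers, sse = trace[length(trace)],
       trace = trace)
}

kmeanspp_init <- function(X, k) {
  N <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(N, 1L)
  if (k > 1L) {
    d2 <- rowSums((X - matrix(X[idx[1], ], N, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        idx[j] <- sample.int(N, 1L)
      } else {
        idx[j] <- sample.int(N, 1L, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums((X - matrix(X[idx[j], ], N, ncol(X),
                                         byrow = TRUE))^2))
    }
  }
  idx
}

point_center_dist2 <- function(X, centers) {
  # N x k squared Euclidean distances
  cross <- X %*% t(centers)
  sweep(-2 * cross, 2, rowSums(centers^2), "+") + rowSums(X^2)
}
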