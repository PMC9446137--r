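# Independent brute-force reference implementations used as oracles.
# They are written naively (explicit component sets, O(N^2) scans) and
# share no code with the package's segmenters.  Scalar arithmetic is kept
# sequential so floating-point results match the compiled path exactly.

rand_image <- function(h, w, grid8 = TRUE) {
  v <- if (grid8) sample(0:255, h * w * 3, replace = TRUE) / 255
       else stats::runif(h * w * 3)
  raster_image(array(v, dim = c(h, w, 3)))
}

# squared/rooted RGB distance with sequential accumulation
px_dist <- function(arr, r1, c1, r2, c2) {
  s <- (arr[r1, c1, 1] - arr[r2, c2, 1])^2
  s <- s + (arr[r1, c1, 2] - arr[r2, c2, 2])^2
  s <- s + (arr[r1, c1, 3] - arr[r2, c2, 3])^2
  sqrt(s)
}

# ---- Felzenszwalb oracle: explicit component lists ----------------------
felz_oracle <- function(img, scale_k, min_size = 1L) {
  arr <- unclass(img)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  N <- H * W
  # edges with row-major endpoint indices (0-based), 4-connectivity
  edges <- list()
  for (r in 0:(H - 1)) for (c in 0:(W - 1)) {
    p <- r * W + c
    if (c + 1 < W)
      edges[[length(edges) + 1]] <-
        list(w = px_dist(arr, r + 1, c + 1, r + 1, c + 2), a = p, b = p + 1)
    if (r + 1 < H)
      edges[[length(edges) + 1]] <-
        list(w = px_dist(arr, r + 1, c + 1, r + 2, c + 1), a = p, b = p + W)
  }
  ord <- order(vapply(edges, `[[`, 0, "w"), vapply(edges, `[[`, 0, "a"),
               vapply(edges, `[[`, 0, "b"))
  edges <- edges[ord]

  comp_of <- seq_len(N)             # component id per pixel (1-based)
  members <- as.list(seq_len(N))    # pixel sets
  int_of <- rep(0, N)               # Int(C) per component id

  merge_comps <- function(ca, cb, w) {
    members[[ca]] <<- c(members[[ca]], members[[cb]])
    comp_of[members[[cb]]] <<- ca
    int_of[ca] <<- max(int_of[ca], int_of[cb], w)
    members[[cb]] <<- integer(0)
  }

  for (e in edges) {
    ca <- comp_of[e$a + 1L]; cb <- comp_of[e$b + 1L]
    if (ca == cb) next
    ta <- int_of[ca] + scale_k / length(members[[ca]])
    tb <- int_of[cb] + scale_k / length(members[[cb]])
    if (e$w <= min(ta, tb)) merge_comps(ca, cb, e$w)
  }

  if (min_size > 1L && N >= min_size) {
    repeat {
      sizes <- vapply(members, length, 0L)
      minpix <- vapply(members, function(m) if (length(m)) min(m) else N + 1L, 0L)
      small <- which(sizes > 0 & sizes < min_size)
      if (length(small) == 0) break
      target <- small[order(sizes[small], minpix[small])][1]
      done <- FALSE
      for (e in edges) {
        ca <- comp_of[e$a + 1L]; cb <- comp_of[e$b + 1L]
        if (ca == cb) next
        if (ca == target || cb == target) {
          merge_comps(ca, cb, e$w)
          done <- TRUE
          break
        }
      }
      if (!done) break
    }
  }

  # contiguous relabel in row-major first occurrence (pixel p row-major)
  out <- matrix(0L, H, W)
  seen <- integer(0)
  nxt <- 0L
  for (p in 0:(N - 1)) {
    cid <- comp_of[p + 1L]
    pos <- match(cid, seen)
    if (is.na(pos)) {
      seen <- c(seen, cid)
      pos <- length(seen)
    }
    out[p %/% W + 1L, p %% W + 1L] <- pos - 1L
  }
  out
}

# ---- Quickshift oracle: O(N^2) densities and links ----------------------
quickshift_oracle <- function(img, kernel_size, max_dist, ratio = 1) {
  lab <- unclass(to_lab(img))
  H <- dim(lab)[1]; W <- dim(lab)[2]
  feat <- function(r, c) c(ratio * lab[r, c, 1], ratio * lab[r, c, 2],
                           ratio * lab[r, c, 3], c - 1, r - 1)
  fd2 <- function(f1, f2) {
    s <- (f1[1] - f2[1])^2
    for (i in 2:5) s <- s + (f1[i] - f2[i])^2
    s
  }
  wd <- ceiling(3 * kernel_size)
  inv <- 1 / (2 * kernel_size^2)
  dens <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    f <- feat(r, c)
    s <- 0
    for (rr in max(1, r - wd):min(H, r + wd))
      for (cc in max(1, c - wd):min(W, c + wd))
        s <- s + exp(-fd2(f, feat(rr, cc)) * inv)
    dens[r, c] <- s
  }
  parent <- matrix(0L, H, W)  # 0-based row-major linear index
  for (r in 1:H) for (c in 1:W) {
    p <- (r - 1) * W + (c - 1)
    bestq <- p; bestd <- Inf
    for (rr in 1:H) for (cc in 1:W) {
      if (dens[rr, cc] <= dens[r, c]) next
      sd2 <- (rr - r)^2 + (cc - c)^2
      if (sd2 > max_dist^2) next
      q <- (rr - 1) * W + (cc - 1)
      if (sd2 < bestd || (sd2 == bestd && q < bestq)) {
        bestd <- sd2; bestq <- q
      }
    }
    parent[r, c] <- as.integer(bestq)
  }
  # root resolution + contiguous relabel (row-major first occurrence)
  proot <- function(p) {
    repeat {
      q <- parent[p %/% W + 1L, p %% W + 1L]
      if (q == p) return(p)
      p <- q
    }
  }
  out <- matrix(0L, H, W)
  seen <- integer(0)
  for (p in 0:(H * W - 1)) {
    rt <- proot(p)
    pos <- match(rt, seen)
    if (is.na(pos)) { seen <- c(seen, rt); pos <- length(seen) }
    out[p %/% W + 1L, p %% W + 1L] <- pos - 1L
  }
  list(labels = out, parent = parent, density = dens)
}

# ---- magic-wand oracle: plain breadth-first search ----------------------
wand_oracle <- function(img, seed, tolerance) {
  arr <- unclass(img)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  sr <- seed[1] + 1L; sc <- seed[2] + 1L
  sel <- matrix(FALSE, H, W)
  sel[sr, sc] <- TRUE
  queue <- list(c(sr, sc))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- p[1] + d[1]; c <- p[2] + d[2]
      if (r < 1 || r > H || c < 1 || c > W || sel[r, c]) next
      if (px_dist(arr, r, c, sr, sc) <= tolerance) {
        sel[r, c] <- TRUE
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  sel
}

# ---- shared fixtures ----------------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture_scenes <- function() {
  if (is.null(.fixture_cache$scenes))
    .fixture_cache$scenes <- fixture_scenes()
  .fixture_cache$scenes
}
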