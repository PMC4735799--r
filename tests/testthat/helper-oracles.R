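# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: morphology is done by explicit pixel
# shifts, component merging by pairwise Chebyshev distances and union-find,
# onset detection by a literal scan of its definition.

shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rsrc <- rs - dr; csrc <- cs - dc
  rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
  out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
  out
}

brute_dilate1 <- function(m) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out | shift_mask(m, dr, dc)
  out
}

brute_erode1 <- function(m) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out & shift_mask(m, dr, dc)
  out
}

brute_dilate <- function(m, iters) {
  for (i in seq_len(iters)) m <- brute_dilate1(m)
  m
}

brute_open <- function(m) brute_dilate1(brute_erode1(m))

# raster of a Euclidean disk as a logical matrix
disk_mask <- function(center, r, height, width) {
  m <- matrix(FALSE, height, width)
  for (dr in -floor(r):floor(r)) for (dc in -floor(r):floor(r)) {
    if (dr^2 + dc^2 <= r^2) {
      rr <- center[1L] + dr; cc <- center[2L] + dc
      if (rr >= 1 && rr <= height && cc >= 1 && cc <= width) {
        m[rr, cc] <- TRUE
      }
    }
  }
  m
}

# minimal Chebyshev distance between the TRUE pixels of two masks
mask_cheb_dist <- function(a, b) {
  pa <- which(a, arr.ind = TRUE); pb <- which(b, arr.ind = TRUE)
  dr <- outer(pa[, 1L], pb[, 1L], "-")
  dc <- outer(pa[, 2L], pb[, 2L], "-")
  min(pmax(abs(dr), abs(dc)))
}

# distance-based merging oracle for the nucleus-nucleus distance index:
# nuclei merge at the N0 stage iff their opened rasters are 8-adjacent
# (distance <= 1) and at the N5 stage iff the distance is <= 2*dpx + 1
oracle_cluster_counts <- function(centers, r, dpx, height, width) {
  n <- nrow(centers)
  opened <- lapply(seq_len(n), function(i) {
    brute_open(disk_mask(centers[i, ], r, height, width))
  })
  d <- matrix(Inf, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- mask_cheb_dist(opened[[i]], opened[[j]])
    }
  }
  count_merged <- function(threshold) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (d[i, j] <= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    length(unique(vapply(seq_len(n), find, integer(1L))))
  }
  n0 <- count_merged(1)
  n5 <- count_merged(2 * dpx + 1)
  list(n0 = n0, n5 = n5, index = n5 / n0)
}

# literal scan of the re-activation onset definition on a mean curve
brute_onset_scan <- function(t, y, rise_fraction) {
  i_peak <- which.max(y)
  if (i_peak >= length(y)) return(NA_real_)
  after <- seq(i_peak + 1L, length(y))
  i_trough <- after[which.min(y[after])]
  if (i_trough >= length(y)) return(NA_real_)
  thr <- y[i_trough] + rise_fraction * (y[i_peak] - y[i_trough])
  for (k in seq(i_trough + 1L, length(y))) {
    above <- y[k] > thr
    persists <- k == length(y) || y[k + 1L] >= thr
    if (above && persists) return(t[k])
  }
  NA_real_
}

# midpoint Riemann sum of an analytic function
riemann_auc <- function(f, window, n = 2e5) {
  h <- diff(window) / n
  mid <- window[1L] + (seq_len(n) - 0.5) * h
  sum(f(mid)) * h
}

# flat timecourse_data construction from vectors
make_tc <- function(condition, target, times, intensity_by_rep) {
  rows <- lapply(seq_along(intensity_by_rep), function(r) {
    data.frame(condition = condition, target = target, replicate = r,
               time_min = times, intensity = intensity_by_rep[[r]])
  })
  timecourse_data(do.call(rbind, rows))
}

# pre-normalized single-replicate table (bypasses reference lookup)
make_norm_tc <- function(times, values, condition = "X", target = "pERK",
                         n_rep = 1L) {
  tc <- make_tc(condition, target, times,
                rep(list(values), n_rep))
  attr(tc, "normalized") <- TRUE
  tc
}
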