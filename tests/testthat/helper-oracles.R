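# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# all-pairs Euclidean distance to the nearest TRUE cell, in meters
bf_distance <- function(mask, cell_size) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask)))
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2)) * cell_size
  out
}

# BFS flood fill, 8-connectivity; returns a label matrix (0 = background)
bf_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      r <- ((v - 1L) %% nr) + 1L; c <- ((v - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          w <- (c2 - 1L) * nr + r2
          if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
        }
      }
    }
  }
  lab
}

# canonical form of a labeling: each labeled cell mapped to the smallest
# linear index of its component, so partitions compare up to renaming
bf_partition_signature <- function(lab) {
  sig <- matrix(0L, nrow(lab), ncol(lab))
  for (k in setdiff(unique(as.vector(lab)), 0L)) {
    cells <- which(lab == k)
    sig[cells] <- min(cells)
  }
  sig
}

# O(V^2) Dijkstra on the 8-connected move graph with mean-of-endpoints edge
# costs; cost matrix in minutes/meter, NA = impassable
bf_cost_distance <- function(cost, cell_size, src_idx) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- nr * nc
  dist <- rep(Inf, n)
  dist[src_idx] <- 0
  done <- is.na(cost)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    done[v] <- TRUE
    r <- ((v - 1L) %% nr) + 1L; c <- ((v - 1L) %/% nr) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- (c2 - 1L) * nr + r2
      if (is.na(cost[w])) next
      step <- cell_size * sqrt(dr^2 + dc^2) * (cost[v] + cost[w]) / 2
      if (dist[v] + step < dist[w]) dist[w] <- dist[v] + step
    }
  }
  matrix(dist, nr, nc)
}

# all-pairs AUC
bf_auc <- function(pres, bg) {
  cmp <- outer(pres, bg, ">") + 0.5 * outer(pres, bg, "==")
  mean(cmp)
}

# two-sided permutation p-value for the Mann-Whitney contrast
bf_mw_permutation_p <- function(a, b, n_perm = 10000, seed = 42) {
  set.seed(seed)
  na <- length(a)
  pooled <- c(a, b)
  u_of <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  mu <- na * length(b) / 2
  obs <- abs(u_of(a, b) - mu)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (abs(u_of(pooled[idx], pooled[-idx]) - mu) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# small aligned test stack with a categorical land cover
toy_stack <- function(nr = 10, nc = 10, cell = 100) {
  lc <- grid_raster(matrix(1L, nr, nc), cell, categories = c("forest", "cleared"))
  roads <- matrix(0L, nr, nc); roads[ceiling(nr / 2), ] <- 1L
  towns <- matrix(0L, nr, nc); towns[ceiling(nr / 2), 1] <- 1L
  landscape_stack(land_cover = lc,
                  slope = grid_raster(matrix(0, nr, nc), cell),
                  roads = grid_raster(roads, cell),
                  rivers = grid_raster(matrix(0L, nr, nc), cell),
                  towns = grid_raster(towns, cell))
}
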