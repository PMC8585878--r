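# small configurations used across tests
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 5, video_duration_s = 128, seed = 42)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# Lance-Williams recursion for Ward linkage on squared Euclidean distances;
# returns merge heights (sqrt scale) and the partition at k clusters.
# Written directly from the update formula, independent of hclust().
lw_ward <- function(X, k_cut = NULL) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  size <- rep(1, n)
  active <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partition <- NULL
  for (m in seq_len(n - 1)) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(n - 1)) {
      if (!active[i]) next
      for (j in (i + 1):n) {
        if (active[j] && D2[i, j] < best) {
          best <- D2[i, j]; bi <- i; bj <- j
        }
      }
    }
    if (!is.null(k_cut) && (n - m + 1) == k_cut) {
      partition <- integer(n)
      lab <- 0L
      for (i in seq_len(n)) {
        if (active[i]) {
          lab <- lab + 1L
          partition[members[[i]]] <- lab
        }
      }
    }
    heights[m] <- sqrt(best)
    ni <- size[bi]; nj <- size[bj]
    for (kk in seq_len(n)) {
      if (active[kk] && kk != bi && kk != bj) {
        nk <- size[kk]
        D2[bi, kk] <- D2[kk, bi] <-
          ((ni + nk) * D2[bi, kk] + (nj + nk) * D2[bj, kk] - nk * best) /
          (ni + nj + nk)
      }
    }
    size[bi] <- ni + nj
    members[[bi]] <- c(members[[bi]], members[[bj]])
    active[bj] <- FALSE
  }
  if (!is.null(k_cut) && is.null(partition)) {
    partition <- rep(1L, n)
  }
  list(heights = heights, partition = partition)
}

# Harrell-Davis quantile via numerical integration of the beta density over
# each order-statistic interval (independent of pbeta differences)
hd_oracle <- function(x, q) {
  n <- length(x)
  xs <- sort(x)
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  w <- vapply(seq_len(n), function(i) {
    integrate(function(u) dbeta(u, a, b), (i - 1) / n, i / n,
              rel.tol = 1e-13)$value
  }, numeric(1))
  sum(w * xs)
}

# canonical correlations via the generalized eigenvalue route
cca_eigen_oracle <- function(Xa, Xb) {
  Za <- scale(Xa)
  Zb <- scale(Xb)
  Saa <- cov(Za); Sbb <- cov(Zb); Sab <- cov(Za, Zb)
  M <- solve(Saa) %*% Sab %*% solve(Sbb) %*% t(Sab)
  sqrt(pmax(sort(Re(eigen(M)$values), decreasing = TRUE), 0))
}

# TRUE when two labelings describe the same partition
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# deterministic phase layout with `n_ev` isolated salient segments
salient_layout <- function(n_ev, on_s = 8, off_s = 17, pad_phase = "grinding",
                           duration = NULL) {
  lay <- data.frame(
    phase = rep(c("core_move", "percussion"), n_ev),
    len_s = rep(c(on_s, off_s), n_ev)
  )
  if (!is.null(duration)) {
    pad <- duration - sum(lay$len_s)
    stopifnot(pad >= 0)
    if (pad > 0) lay <- rbind(lay, data.frame(phase = pad_phase, len_s = pad))
  }
  lay
}
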