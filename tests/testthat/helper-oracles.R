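# Independent brute-force reference implementations used as oracles.
# These deliberately re-derive each quantity from its definition (exhaustive
# scans and per-pixel loops) and share no code with the package internals.

# Otsu: minimize the pooled within-class variance over the 255 interior edges
# of a 256-bin histogram; pixels are represented by their bin midpoint.
oracle_otsu <- function(values) {
  v <- as.numeric(values)
  rng <- range(v)
  nb <- 256L
  width <- (rng[2] - rng[1]) / nb
  bin <- pmin(floor((v - rng[1]) / width) + 1L, nb)
  mid <- rng[1] + (bin - 0.5) * width
  best_wcv <- Inf
  best_t <- NA_integer_
  for (t in 1:(nb - 1L)) {
    lo <- mid[bin <= t]
    hi <- mid[bin > t]
    if (!length(lo) || !length(hi)) next
    wcv <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.infinite(best_wcv) ||
        wcv < best_wcv - 1e-12 * max(1, abs(best_wcv))) {
      best_wcv <- wcv
      best_t <- t
    }
  }
  rng[1] + best_t * width
}

# Exact distance of every pixel to the nearest true pixel, by direct
# minimization over all true pixels.
oracle_distmap <- function(mask, pixel_size_um = 1) {
  idx <- which(mask, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(NA_real_, h, w)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (p in seq_len(h * w)) {
    out[p] <- sqrt(min((idx[, 1] - rr[p])^2 + (idx[, 2] - cc[p])^2))
  }
  out * pixel_size_um
}

# 8-connected labeling by flood fill, components numbered by the smallest
# column-major index they contain.
oracle_label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% h) + 1L
      c <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1L || r2 > h || c2 < 1L || c2 > w) next
        q <- (c2 - 1L) * h + r2
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Nearest-seed assignment: label of the closest component (brute-force
# distance to every component pixel), ties to the lowest label. Also returns
# the margin between the two closest seeds to identify tie pixels.
oracle_nearest_seed <- function(comps) {
  k <- max(comps)
  h <- nrow(comps); w <- ncol(comps)
  lab <- matrix(0L, h, w)
  margin <- matrix(Inf, h, w)
  dists <- array(NA_real_, c(h, w, k))
  for (j in seq_len(k)) {
    dists[, , j] <- oracle_distmap(comps == j)
  }
  for (p in seq_len(h * w)) {
    r <- ((p - 1L) %% h) + 1L
    c <- ((p - 1L) %/% h) + 1L
    d <- dists[r, c, ]
    j <- which(d == min(d))[1]
    lab[p] <- j
    margin[p] <- if (k > 1L) sort(d)[2] - d[j] else Inf
  }
  list(labels = lab, margin = margin)
}

# DeltaAb by definition: for each band edge re-filter the zone per pixel.
oracle_delta_ab <- function(vessel_id, labels, inside_mask, dist_um, red,
                            noise_mask, band_width_um) {
  zone <- labels == vessel_id
  w <- red * noise_mask
  i_in <- sum(w[zone & inside_mask])
  out <- zone & !inside_mask
  dmax <- if (any(out)) max(dist_um[out]) else 0
  n_bands <- ceiling(dmax / band_width_um)
  edges <- band_width_um * (0:n_bands)
  delta <- vapply(edges, function(d) {
    sum(w[out & dist_um <= d]) - i_in
  }, numeric(1))
  m <- max(delta)
  list(distances_um = edges, delta_ab = delta, delta_ab_max = m,
       extravasation_range_um = edges[which(delta == m)[1]],
       extravasated = m > 0)
}

# Two-sided Fisher p by exhaustive enumeration over the margin-compatible
# tables: sum of hypergeometric probabilities <= that of the observed table.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(xs, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Balanced two-way ANOVA from the textbook cell-mean decomposition.
oracle_anova_balanced <- function(d, response, fa, fb) {
  y <- d[[response]]
  A <- factor(d[[fa]]); B <- factor(d[[fb]])
  n <- length(y) / (nlevels(A) * nlevels(B))
  grand <- mean(y)
  mu_a <- tapply(y, A, mean)
  mu_b <- tapply(y, B, mean)
  mu_ab <- tapply(y, list(A, B), mean)
  ss_a <- n * nlevels(B) * sum((mu_a - grand)^2)
  ss_b <- n * nlevels(A) * sum((mu_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(mu_ab, 1, mu_a), 2, mu_b) + grand)^2)
  ss_e <- sum((y - mu_ab[cbind(A, B)])^2)
  df_a <- nlevels(A) - 1
  df_b <- nlevels(B) - 1
  df_ab <- df_a * df_b
  df_e <- length(y) - nlevels(A) * nlevels(B)
  mse <- ss_e / df_e
  list(F_a = (ss_a / df_a) / mse, F_b = (ss_b / df_b) / mse,
       F_ab = (ss_ab / df_ab) / mse, mse = mse, df_error = df_e)
}
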