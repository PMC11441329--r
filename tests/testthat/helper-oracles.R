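# Independent brute-force oracles used across tests.

# queue-based flood fill; labels in column-major first-pixel order
flood_fill_label <- function(mask, connectivity = 8) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      subset(!(dr == 0 & dc == 0)) |> as.matrix()
  }
  next_label <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    next_label <- next_label + 1L
    queue <- list(c(i, j))
    lab[i, j] <- next_label
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- next_label
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
  }
  lab
}

# exhaustive Otsu over the same 256 bin-edge candidates, objective computed
# naively from raw pixel subsets
otsu_exhaustive <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  cand <- edges[2:n_bins]
  best <- -Inf; best_t <- NA_real_
  n <- length(v)
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# one synapse rendered noiselessly on a small field, with truth attached
render_single_synapse <- function(offset_nm = -50, angle = 0.6,
                                  field_px = c(512L, 512L),
                                  noise = "none", seed = 1L, ...) {
  op <- optics_spec(field_px = field_px)
  center <- field_nm_test(op) / 2
  syn <- synapse_truth(center_nm = center, axis_angle_rad = angle,
                       channel_offset_nm = offset_nm, ...)
  scene <- build_scene(op, 0, seed = seed)
  scene$synapses <- list(syn)
  list(scene = scene, truth = syn,
       stack = render_stack(scene, noise = noise, seed = seed))
}

field_nm_test <- function(op) rev(op$field_px) * op$pixel_size_nm # (x, y)

# measure FWHM of a 1-D profile by linear interpolation at half maximum
measure_fwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  left <- max(which(y[1:i] <= half))
  right <- i - 1 + min(which(y[i:length(y)] <= half))
  xl <- x[left] + (half - y[left]) / (y[left + 1] - y[left]) *
    (x[left + 1] - x[left])
  xr <- x[right - 1] + (half - y[right - 1]) / (y[right] - y[right - 1]) *
    (x[right] - x[right - 1])
  xr - xl
}
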