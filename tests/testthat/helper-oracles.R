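# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# cell-by-cell pressure summary: explicit loops, no matrix tricks
oracle_pressure_summary <- function(values, pitch_mm, threshold, force_N) {
  fcorr <- force_N / (sum(values) * pitch_mm^2 * 1e-3)
  n_active <- 0; peak <- 0; load <- 0
  for (i in seq_len(nrow(values))) for (j in seq_len(ncol(values))) {
    p <- values[i, j] * fcorr
    if (p > peak) peak <- p
    if (p > threshold) {
      n_active <- n_active + 1
      load <- load + p * pitch_mm^2 * 1e-3
    }
  }
  ca <- n_active * pitch_mm^2
  list(ca = ca, pp = peak, mp = if (ca > 0) load / ca * 1e3 else NA_real_,
       fcorr = fcorr)
}

# region proportions by explicit row enumeration given the five indices
oracle_region_props <- function(soc, x_beg, x_max, x_mid1, x_mid2, x_end) {
  tot <- sum(soc[x_beg:x_end])
  seg <- function(a, b) if (b < a) 0 else sum(soc[a:b])
  100 * c(seg(x_beg, x_max - 1), seg(x_max, x_mid1 - 1),
          seg(x_mid1, x_mid2 - 1), seg(x_mid2, x_end)) / tot
}

# trapezoid integral of y over x
oracle_trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# plain interval-halving root finder
oracle_bisect <- function(f, lo, hi, tol = 1e-10, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# quick slab mesh for ROI tests: lx x ly footprint, thickness t, coarse hexes
slab_mesh <- function(t_mm, lx = 120, ly = 120, h = 10) {
  hex_block_mesh(lx, ly, t_mm, h = h)
}
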