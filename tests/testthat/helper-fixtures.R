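# shared fixtures: everything is generated in code, nothing is stored

ref_materials <- bovine_eye_materials()

# noiseless multi-rate sclera curves at the default amplitude
make_sclera_curves <- function(rates = c(0.3, 3, 30, 300),
                               max_displacement = 0.75) {
  lapply(rates, function(r)
    simulate_tension(ref_materials$sclera, sclera_strip(),
                     loading_protocol(r, max_displacement)))
}

make_cornea_curves <- function(rates = c(0.3, 30),
                               max_displacement = 1.5) {
  lapply(rates, function(r)
    simulate_tension(ref_materials$cornea, cornea_strip(),
                     loading_protocol(r, max_displacement)))
}

# independent O(n^2) oracle for the hereditary integral: direct sum of
# each strain increment propagated through the midpoint-evaluated kernel
visco_direct_oracle <- function(g, b, time, eps) {
  n <- length(time)
  out <- numeric(n)
  for (k in 2:n) {
    s <- 0
    for (j in 2:k) {
      tmid <- (time[j] + time[j - 1]) / 2
      s <- s + g * (eps[j] - eps[j - 1]) * exp(-b * (time[k] - tmid))
    }
    out[k] <- s
  }
  out
}

# brute-force domination count: number of rows strictly dominated by
# another row (0 for a valid Pareto set)
count_dominated <- function(obj) {
  n <- nrow(obj)
  bad <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ]))
      bad <- bad + 1L
  }
  bad
}

# centered L2 discrepancy (Hickernell), used as the uniformity measure
centered_l2_discrepancy <- function(x) {
  n <- nrow(x); d <- ncol(x)
  xc <- abs(x - 0.5)
  term2 <- sum(apply(1 + 0.5 * xc - 0.5 * xc^2, 1, prod))
  P <- matrix(1, n, n)
  for (k in seq_len(d)) {
    P <- P * (1 + 0.5 * outer(xc[, k], xc[, k], `+`) -
                0.5 * abs(outer(x[, k], x[, k], `-`)))
  }
  sqrt((13 / 12)^d - (2 / n) * term2 + sum(P) / n^2)
}
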