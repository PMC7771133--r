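# Shared fixtures for the test suite. Everything is generated in code; no
# files are read besides temp files the tests themselves write.

grid1 <- wavelength_grid(300, 700, 1)
grid5 <- wavelength_grid(300, 700, 5)

flat_radiance <- function(grid = grid1, level = 1) {
  spectrum(grid$wl, rep(level, length(grid$wl)), "radiance")
}

# random smooth reflectance spectra: mixture of a sigmoid and a bell with
# random parameters, plus a random pedestal; strictly positive
random_reflectance <- function(grid = grid5) {
  ctr <- runif(2, 330, 670)
  w <- runif(2, 10, 80)
  a <- runif(3, 0.02, 0.45)
  v <- a[1] +
    a[2] / (1 + exp(-(grid$wl - ctr[1]) / w[1])) +
    a[3] * exp(-(grid$wl - ctr[2])^2 / (2 * w[2]^2))
  suppressWarnings(spectrum(grid$wl, pmin(v, 1), "reflectance"))
}

# independent oracle: a per-sample loop assigns every grid sample to its
# segment (half-open, last closed at lambda2); per-segment totals are then
# summed with sum() so accumulation order and precision match any correct
# implementation bit for bit
tally_relative_brightness <- function(l, p) {
  k <- p$n + 1L
  members <- vector("list", k)
  for (j in seq_along(l$wl)) {
    wl <- l$wl[j]
    if (wl < p$lambda1 - 1e-9 || wl > p$lambda2 + 1e-9) next
    for (i in seq_len(k)) {
      lo <- p$boundaries[i]; hi <- p$boundaries[i + 1L]
      inside <- if (i == k) (wl >= lo - 1e-9 && wl <= hi + 1e-9)
                else (wl >= lo - 1e-9 && wl < hi - 1e-9)
      if (inside) { members[[i]] <- c(members[[i]], l$values[j]); break }
    }
  }
  seg <- vapply(members, sum, numeric(1))
  seg / sum(seg)
}

# a segment_brightness object with prescribed S (for locus arithmetic tests)
fake_sb <- function(S, beta = 1, beta_m = NA_real_, n = length(S) - 1L) {
  structure(list(S = S, beta = beta, beta_m = beta_m,
                 partition = segment_partition(300, 700, n)),
            class = "segment_brightness")
}
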