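# Independent oracles and small fixture helpers shared across tests.

# Brute-force nematic order: explicit per-pixel loop over the complex sum,
# kept deliberately naive and separate from the package's vectorized path.
brute_force_nematic <- function(phi_deg, intensity) {
  re <- 0; im <- 0; tot <- 0
  for (p in seq_along(phi_deg)) {
    a <- 2 * phi_deg[p] * pi / 180
    re <- re + intensity[p] * cos(a)
    im <- im + intensity[p] * sin(a)
    tot <- tot + intensity[p]
  }
  z <- complex(real = re, imaginary = im) / tot
  list(magnitude = Mod(z), axis_deg = (Arg(z) * 90 / pi) %% 180)
}

# Exhaustive two-sample KS statistic: evaluate |ECDF_a - ECDF_b| at every
# observed value from either sample.
brute_force_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

# Match follicle segmentations/calls to simulator truth by nearest center.
match_truth <- function(segs, truth) {
  ok <- segs[segs$qc_flag == "ok", ]
  idx <- vapply(seq_len(nrow(ok)), function(i) {
    which.min((truth$cx - ok$cx[i])^2 + (truth$cy - ok$cy[i])^2)
  }, integer(1))
  ok$truth_id <- truth$follicle_id[idx]
  ok
}

# Closed-form normalized FRAP recovery used by the generator.
frap_model <- function(t, bleach_depth, mobile, k) {
  (1 - bleach_depth) + bleach_depth * mobile * (1 - exp(-k * t))
}
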