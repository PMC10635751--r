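# Printed 4-decimal reference grid for the true measures (reference
# values are truncated, not rounded, to 4 dp, hence the 1e-4 comparison
# tolerance used by the tests that consume this table).
reference_measure_grid <- function() {
  ref <- rbind(
    c(0.5, 0.5, NA, 0.5,    2.8889),
    c(0.5, 1.5, NA, 0.825,  3.0909),
    c(2.0, 0.5, NA, 0.1253, 0.6241),
    c(0.5, 0.5,  1, 0.3827, 3.5268),
    c(0.5, 0.5,  5, 0.4729, 3.0432),
    c(0.5, 0.5, 10, 0.4862, 2.9676),
    c(0.5, 0.5, 20, 0.4930, 2.9286),
    c(0.5, 1.5,  1, 0.65,   3.6923),
    c(0.5, 1.5,  5, 0.7871, 3.2297),
    c(0.5, 1.5, 10, 0.8061, 3.1609),
    c(0.5, 1.5, 20, 0.8155, 3.1260),
    c(2.0, 0.5,  1, 0.0486, 0.9871),
    c(2.0, 0.5,  5, 0.0958, 0.7682),
    c(2.0, 0.5, 10, 0.1087, 0.7058),
    c(2.0, 0.5, 20, 0.1165, 0.6678))
  data.frame(theta1 = ref[, 1], theta2 = ref[, 2], k = ref[, 3],
             prob = ref[, 4], strength = ref[, 5])
}

# brute-force 1-D maximiser: coarse grid then a refined grid around the
# argmax (independent of stats::optimize)
grid_maximise <- function(f, lower, upper, n_coarse = 2000L, n_fine = 2000L) {
  g <- seq(lower, upper, length.out = n_coarse)
  v <- vapply(g, f, numeric(1))
  i <- which.max(v)
  lo <- g[max(1L, i - 2L)]; hi <- g[min(n_coarse, i + 2L)]
  g2 <- seq(lo, hi, length.out = n_fine)
  v2 <- vapply(g2, f, numeric(1))
  g2[which.max(v2)]
}
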