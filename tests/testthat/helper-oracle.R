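# Brute-force recomputation of the exposure index from first principles:
# an explicit reading-by-reading scan, independent of the package's
# excursion/band machinery. Used as the oracle in equivalence tests.
oracle_index <- function(ppm, interval_s = 15, mode = "cumulative") {
  n <- length(ppm)
  h01 <- h1 <- h5 <- h10 <- 0
  i <- 1
  while (i <= n) {
    if (ppm[i] >= 0.095) {
      j <- i
      while (j < n && ppm[j + 1] >= 0.095) j <- j + 1
      pk <- max(ppm[i:j])
      if (mode == "cumulative") {
        h01 <- h01 + 1
        if (pk >= 1.05) h1 <- h1 + 1
        if (pk >= 5.05) h5 <- h5 + 1
        if (pk >= 10.05) h10 <- h10 + 1
      } else {
        if (pk >= 10.05) h10 <- h10 + 1
        else if (pk >= 5.05) h5 <- h5 + 1
        else if (pk >= 1.05) h1 <- h1 + 1
        else h01 <- h01 + 1
      }
      i <- j + 1
    } else i <- i + 1
  }
  d01 <- sum(ppm >= 0.095 & ppm < 5.05) * interval_s / 60
  d5 <- sum(ppm >= 5.05) * interval_s / 60
  mx <- max(c(ppm, 0))
  if (mx < 0.095) return(0)
  0.1 * h01 + 0.1 * d01 + h1 + 5 * h5 + 5 * d5 + 10 * h10 + mx
}

# random concentration series on the 0.1-ppm grid with plenty of zeros
random_ppm <- function(n, p_zero = 0.6, max_ppm = 30) {
  v <- ifelse(runif(n) < p_zero, 0, round(runif(n, 0.1, max_ppm), 1))
  pmin(v, 100)
}
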