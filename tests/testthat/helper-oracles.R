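# Independent oracles used by the tests: deliberately naive
# implementations that share no code with the package internals.

# Direct O(n^4) convolution on one (H, W, C) image with 'same'-style
# padding semantics matching a (k, k, Cin, Cout) weight array.
naive_conv <- function(x, W, b, stride, pad) {
  d <- dim(x)
  k <- dim(W)[1]
  cout <- dim(W)[4]
  hout <- (d[1] + 2 * pad - k) %/% stride + 1
  wout <- (d[2] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(hout, wout, cout))
  for (oc in seq_len(cout)) {
    for (ho in seq_len(hout)) {
      for (wo in seq_len(wout)) {
        acc <- b[oc]
        for (kh in seq_len(k)) {
          hi <- (ho - 1) * stride - pad + kh
          if (hi < 1 || hi > d[1]) next
          for (kw in seq_len(k)) {
            wi <- (wo - 1) * stride - pad + kw
            if (wi < 1 || wi > d[2]) next
            acc <- acc + sum(x[hi, wi, ] * W[kh, kw, , oc])
          }
        }
        y[ho, wo, oc] <- acc
      }
    }
  }
  y
}

# Brute-force counting metrics via explicit loops.
naive_metrics <- function(predicted, truth) {
  n <- length(predicted)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- predicted[i] - truth[i]
  m <- sum(d) / n
  sdp <- sqrt(sum((d - m)^2) / n)
  ma <- sum(abs(d)) / n
  sda <- sqrt(sum((abs(d) - ma)^2) / n)
  agree <- 0; within1 <- 0; sq <- 0
  for (i in seq_len(n)) {
    if (d[i] == 0) agree <- agree + 1
    if (abs(d[i]) <= 1) within1 <- within1 + 1
    sq <- sq + d[i]^2
  }
  tm <- sum(truth) / n
  sst <- sum((truth - tm)^2)
  r2 <- if (all(d == 0)) 1 else if (sst == 0) 0 else 1 - sq / sst
  list(dic_mean = m, dic_sd = sdp, abs_dic_mean = ma, abs_dic_sd = sda,
       mse = sq / n, agreement_pct = 100 * agree / n,
       within_one_pct = 100 * within1 / n, r_squared = r2, n = n)
}
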