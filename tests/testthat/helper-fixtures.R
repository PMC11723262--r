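# Small shared fixtures, built once per test run.

tiny_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_benchmark(n_train = 60, n_val = 30, n_test = 60,
                               T = 256, master_seed = 7)
    }
    cache
  }
})

# A quickly trained small model on the tiny benchmark (hw preset, T = 256).
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_denoiser(tiny_benchmark(), denoiser_config("hw", T = 256),
                               epochs = 12, seed = 3)
    }
    cache
  }
})

# Independent moving-average oracle: explicit centered means over a
# symmetrically padded copy (edge samples repeated).
ma_oracle <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  ext <- function(i) x[ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))]
  vapply(seq_len(n), function(i) mean(ext((i - h):(i + h))), numeric(1))
}

# Independent complex-impedance oracle: parallel-combination formulation,
# distinct from the package's three-term sum.
impedance_oracle <- function(Rs, Cs, Rp, Cp, f) {
  w <- 2i * pi * f
  zc <- function(C) 1 / (w * C)
  par <- function(a, b) a * b / (a + b)
  Rs + zc(Cs) + par(Rp, zc(Cp))
}
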