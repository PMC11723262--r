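test_that("shape algebra matches the stated preset arithmetic", {
  cfg <- denoiser_config("balanced", T = 1024)
  expect_equal(unname(c(cfg$L1, cfg$P1, cfg$L2, cfg$P2)), c(1020, 510, 508, 254))
  expect_equal(cfg$flatten, 254 * 64)
  cfg <- denoiser_config("hw", T = 16)
  expect_equal(unname(c(cfg$L1, cfg$P1, cfg$L2, cfg$P2)), c(14, 7, 5, 2))
  expect_equal(cfg$flatten, 2 * 16)
  expect_error(denoiser_config("balanced", T = 4), "conv1")
})

test_that("shape algebra holds for every preset over random window lengths", {
  set.seed(33)
  presets <- c("balanced", "balanced_32_32", "low", "high", "hw")
  for (i in 1:20) {
    T <- sample(40:600, 1)
    p <- sample(presets, 1)
    cfg <- denoiser_config(p, T = T)
    k1 <- cfg$conv1[["kernel"]]; k2 <- cfg$conv2[["kernel"]]
    expect_equal(cfg$L1, T - k1 + 1)
    expect_equal(cfg$P1, (T - k1 + 1) %/% 2)
    expect_equal(cfg$L2, cfg$P1 - k2 + 1)
    expect_equal(cfg$P2, cfg$L2 %/% 2)
    expect_equal(cfg$flatten, cfg$P2 * cfg$conv2[["filters"]])
  }
})

test_that("parameter counts are monotone in filter counts: hw < low < balanced < high", {
  n <- vapply(c("hw", "low", "balanced", "high"),
              function(p) denoiser_config(p, T = 1024)$n_params, numeric(1))
  expect_true(all(diff(n) > 0))
})

test_that("ReLU and max-pool semantics are exact through the real datapath", {
  # unit-weight single-channel network exposing pooled ReLU values at the output
  cfg <- denoiser_config("custom", T = 8, conv1 = c(1, 1), conv2 = c(1, 1),
                         dense_units = 2)
  expect_equal(cfg$flatten, 2)
  w <- list(W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0,
            W3 = diag(2), b3 = c(0, 0),
            W4 = rbind(c(1, 0, 0, 0, 0, 0, 0, 0),
                       c(0, 1, 0, 0, 0, 0, 0, 0)), b4 = numeric(8))
  x <- matrix(c(-1, 2, 0, 5, 1, 3, 2, 4), nrow = 1)
  y <- sinwfet:::cnn_predict_cpp(w, sinwfet:::cfg_for_cpp(cfg), x)
  # relu: 0 2 0 5 1 3 2 4 -> pool pairs: 2 5 3 4 -> conv/relu unchanged ->
  # pool pairs: 5 4
  expect_equal(y[1, 1:2], c(5, 4))
  expect_equal(y[1, 3:8], rep(0, 6))
})

test_that("gradients match central finite differences in double precision", {
  set.seed(17)
  cfg <- denoiser_config("custom", T = 14, conv1 = c(3, 3), conv2 = c(4, 3),
                         dense_units = 5)
  cc <- sinwfet:::cfg_for_cpp(cfg)
  rw <- function(r, co) matrix(rnorm(r * co, sd = 0.4), r, co)
  w <- list(W1 = rw(3, 3), b1 = rnorm(3, sd = .1), W2 = rw(9, 4),
            b2 = rnorm(4, sd = .1), W3 = rw(cfg$flatten, 5),
            b3 = rnorm(5, sd = .1), W4 = rw(5, 14), b4 = rnorm(14, sd = .1))
  X <- matrix(rnorm(4 * 14), 4); Y <- matrix(rnorm(4 * 14), 4)
  an <- sinwfet:::cnn_loss_grad_cpp(w, cc, X, Y)$grad
  eps <- 1e-6
  for (nm in names(w)) {
    ks <- sample(length(w[[nm]]), min(10, length(w[[nm]])))
    for (k in ks) {
      wp <- w; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- w; wm[[nm]][k] <- wm[[nm]][k] - eps
      fd <- (sinwfet:::cnn_loss_grad_cpp(wp, cc, X, Y)$loss -
             sinwfet:::cnn_loss_grad_cpp(wm, cc, X, Y)$loss) / (2 * eps)
      expect_equal(unname(as.numeric(an[[nm]])[k]), fd, tolerance = 1e-4)
    }
  }
})

test_that("denoising is deterministic and enforces the window length", {
  m <- tiny_model()
  x <- tiny_benchmark()$noisy[[1]]
  expect_identical(denoise(m, x), denoise(m, x))
  expect_length(denoise(m, x), 256)
  expect_error(denoise(m, x[1:100]), "does not match")
})

test_that("a trained denoiser violates superposition (it is not a linear filter)", {
  m <- tiny_model()
  set.seed(44)
  b <- tiny_benchmark()
  x1 <- b$noisy[[1]]; x2 <- b$noisy[[2]]
  f <- function(v) denoise(m, v)
  viol <- max(abs(f(x1 + x2) - (f(x1) + f(x2))))
  scale <- max(abs(f(x1 + x2)))
  expect_gt(viol / scale, 1e-3)
})

test_that("training converges on a noise-disabled dataset (identity is learnable)", {
  # benchmark windows with every noise source at zero: noisy == clean
  zero_noise_windows <- function(n, T, seed0) {
    grid <- default_freq_grid()
    cls <- analyte_classes()$name
    amp0 <- amplifier_model(gain = 1, input_referred_noise_sigma = 0)
    do.call(rbind, lapply(seq_len(n), function(i) {
      synthesize_window(cls = cls[(i - 1) %% 5 + 1],
                        noise = noise_model(), amp = amp0,
                        carrier_freq = grid[(i - 1) %% 20 + 1],
                        T = T, seed = seed0 + i)$noisy[[1]]
    }))
  }
  x <- zero_noise_windows(200, 256, 100)
  xv <- zero_noise_windows(40, 256, 900)
  d <- list(x_train = x, y_train = x, x_val = xv, y_val = xv)
  fit <- train_denoiser(d, denoiser_config("hw", T = 256), epochs = 30, seed = 2)
  expect_lt(fit$best_val_mse, 1e-4)
})

test_that("shuffled targets leave no learnable signal", {
  set.seed(9)
  b <- tiny_benchmark()
  tr <- b[b$split == "train", ]
  va <- b[b$split == "val", ]
  xt <- do.call(rbind, tr$noisy)
  yt <- do.call(rbind, tr$clean)[sample(nrow(tr)), ]   # permuted across windows
  d <- list(x_train = xt, y_train = yt,
            x_val = do.call(rbind, va$noisy),
            y_val = do.call(rbind, va$clean)[sample(nrow(va)), ])
  fit <- train_denoiser(d, denoiser_config("hw", T = 256), epochs = 8, seed = 1)
  # best validation MSE stays near the variance of the standardized target
  tvar <- mean(((yt - mean(xt)) / sd(xt))^2)
  expect_gt(fit$best_val_mse, 0.5 * tvar)
})

test_that("training reports divergence with the offending epoch", {
  set.seed(10)
  x <- matrix(rnorm(64 * 32, sd = 1e3), 64)
  d <- list(x_train = x, y_train = x, x_val = x, y_val = x)
  expect_error(
    train_denoiser(d, denoiser_config("hw", T = 32), epochs = 5, lr = 1e18),
    "diverged"
  )
})

test_that("quantization is idempotent and reduces weights to the grid", {
  m <- tiny_model()
  q1 <- quantize_denoiser(m, quant_spec(16, 8))
  q2 <- quantize_denoiser(q1, quant_spec(16, 8))
  expect_identical(q1$weights, q2$weights)
  expect_true(all(abs(q1$weights$W1 * 2^8 -
                      round(q1$weights$W1 * 2^8)) < 1e-12))
  # coarse grid: weights are multiples of 2^-2
  q3 <- quantize_denoiser(m, quant_spec(16, 2))
  expect_true(all(q3$weights$W4 * 4 == round(q3$weights$W4 * 4)))
})

test_that("non-saturating quantization reports overflow with the layer name", {
  m <- tiny_model()
  m$weights$W4 <- m$weights$W4 * 1e6
  expect_error(quantize_denoiser(m, quant_spec(8, 4, saturating = FALSE)),
               "overflow.*dense2", ignore.case = TRUE)
})

test_that("quant_spec validates the word format", {
  expect_error(quant_spec(33, 24), "total_bits")
  expect_error(quant_spec(16, 0), "total_bits")
  expect_error(quant_spec(16, 16), "total_bits")
})

test_that("quantized inference stays close to float inference at Q8.24", {
  m <- tiny_model()
  q <- quantize_denoiser(m, quant_spec(32, 24))
  b <- tiny_benchmark()
  x <- do.call(rbind, b$noisy[b$split == "test"][1:20])
  yf <- denoise_standardized(m, x)
  yq <- denoise_standardized(q, x)
  expect_lt(max(abs(yf - yq)), 1e-3)
})

test_that("repeated inference is bitwise stable", {
  m <- tiny_model()
  x <- tiny_benchmark()$noisy[[3]]
  expect_identical(repeat_inference_identical(m, x, times = 500), 500L)
})
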