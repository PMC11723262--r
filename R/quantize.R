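#' Fixed-point quantization specification
#'
#' Q-format description of the emulated FPGA datapath:
#' `Q(total_bits - frac_bits - 1).frac_bits` signed fixed point. Weights,
#' inputs and every layer's outputs are held on this grid; multiply-accumulate
#' operations use a wide accumulator (as DSP blocks do) and are re-quantized
#' at each layer boundary.
#'
#' @param total_bits Total word length (bits), `0 < frac_bits < total_bits <= 32`.
#' @param frac_bits Fractional bits.
#' @param rounding `"nearest"` (round to nearest, ties to even) or
#'   `"truncate"` (toward zero).
#' @param saturating Clamp out-of-range values to the representable extremes;
#'   if `FALSE`, an overflow raises an error naming the offending layer.
#' @return An object of class `quant_spec`.
#' @export
quant_spec <- function(total_bits = 32, frac_bits = 24,
                       rounding = c("nearest", "truncate"), saturating = TRUE) {
  rounding <- match.arg(rounding)
  if (!(frac_bits > 0 && frac_bits < total_bits && total_bits <= 32)) {
    abort("need 0 < frac_bits < total_bits <= 32")
  }
  structure(list(total_bits = as.integer(total_bits),
                 frac_bits = as.integer(frac_bits),
                 rounding = rounding, saturating = saturating),
            class = "quant_spec")
}

#' Quantize a trained denoiser to fixed point
#'
#' Rounds all weights and biases onto the fixed-point grid and returns a model
#' whose inference runs through the bit-stable fixed-point emulation path.
#' Quantizing an already-quantized model is a no-op (idempotent).
#'
#' @param model A `trained_denoiser` or `quantized_denoiser`.
#' @param spec A [quant_spec()].
#' @return An object of class `quantized_denoiser`.
#' @export
quantize_denoiser <- function(model, spec = quant_spec()) {
  stopifnot(inherits(spec, "quant_spec"))
  base <- if (inherits(model, "quantized_denoiser")) {
    # re-quantizing: start from the already-gridded weights (idempotence)
    list(config = model$config, weights = model$weights, norm = model$norm)
  } else {
    model
  }
  q <- quantize_weights_cpp(base$weights, spec$total_bits, spec$frac_bits,
                            spec$rounding == "nearest", spec$saturating)
  if (q$overflow) {
    abort(sprintf("fixed-point overflow while quantizing weights (layer %s); use a wider format or saturating = TRUE",
                  q$overflow_layer))
  }
  structure(
    list(config = base$config, weights = q$weights, norm = base$norm,
         spec = spec, float = base),
    class = "quantized_denoiser"
  )
}

#' @export
print.quantized_denoiser <- function(x, ...) {
  cat(sprintf("<quantized_denoiser> %s preset, Q%d.%d (%s, %s)\n",
              x$config$name, x$spec$total_bits - x$spec$frac_bits - 1L,
              x$spec$frac_bits, x$spec$rounding,
              if (x$spec$saturating) "saturating" else "non-saturating"))
  invisible(x)
}

#' @export
denoise.quantized_denoiser <- function(model, noisy) {
  inp <- check_T(model, noisy)
  xs <- (inp$x - model$norm[["center"]]) / model$norm[["scale"]]
  res <- cnn_predict_fixed_cpp(model$weights, cfg_for_cpp(model$config), xs,
                               model$spec$total_bits, model$spec$frac_bits,
                               model$spec$rounding == "nearest",
                               model$spec$saturating)
  if (!model$spec$saturating && res$overflow) {
    abort(sprintf("fixed-point overflow during inference at layer %s",
                  res$overflow_layer))
  }
  y <- res$Y * model$norm[["scale"]] + model$norm[["center"]]
  if (inp$vec) drop(y) else y
}

#' @export
predict.quantized_denoiser <- function(object, newdata, ...) denoise(object, newdata)

#' Standardized-scale output of a model (diagnostics)
#'
#' Network output on the standardized scale (before mapping back to current
#' units), used to compare float and fixed-point inference directly.
#' @param model A `trained_denoiser` or `quantized_denoiser`.
#' @param noisy Window matrix (rows = windows).
#' @return Matrix of standardized outputs.
#' @export
denoise_standardized <- function(model, noisy) {
  y <- denoise(model, noisy)
  (y - model$norm[["center"]]) / model$norm[["scale"]]
}
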