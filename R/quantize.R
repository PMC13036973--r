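#' Symmetric per-tensor 8-bit quantization
#'
#' Maps a real tensor onto signed 8-bit integers in `[-127, 127]` with a
#' single scale (`max |x| / 127`) and zero point 0. The round-trip error of
#' `dequantize_tensor(quantize_tensor(x))` is bounded elementwise by
#' `scale / 2`. An all-zero tensor quantizes to zeros with scale 1.
#'
#' @param x Numeric vector, matrix or array with finite values.
#' @return A `quantized_tensor`: list with integer `q` (same shape as `x`),
#'   `scale` and `zero_point`.
#' @export
quantize_tensor <- function(x) {
  if (any(!is.finite(x))) abort("cannot quantize non-finite values")
  m <- max(abs(x))
  scale <- if (m == 0) 1 else m / 127
  q <- round(x / scale)
  q[q > 127] <- 127
  q[q < -127] <- -127
  storage.mode(q) <- "integer"
  structure(list(q = q, scale = scale, zero_point = 0L),
            class = "quantized_tensor")
}

#' @rdname quantize_tensor
#' @param qt A `quantized_tensor`.
#' @export
dequantize_tensor <- function(qt) {
  (unclass(qt$q) - qt$zero_point) * qt$scale
}

# Fake-quantize: round-trip through int8, keeping the float shape. Used to
# simulate the int8 inference path.
fake_quantize <- function(x) dequantize_tensor(quantize_tensor(x))

# Fake-quantize with a fixed activation scale from calibration.
fake_quantize_scaled <- function(x, scale) {
  q <- round(x / scale)
  q[q > 127] <- 127
  q[q < -127] <- -127
  q * scale
}
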