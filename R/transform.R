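#' Transform two-channel allele signals to contrast/size space
#'
#' Axiom-style transform of raw A/B channel intensities. With
#' `A' = a * 100 + 100` and `B' = b * 100 + 100`,
#' `contrast = log2(A'/B')` and `size = (log2 A' + log2 B') / 2`.
#' The +100 offset keeps both quantities finite for any non-negative
#' finite signal.
#'
#' @param signal_a,signal_b Non-negative numeric vectors of raw channel
#'   intensities (recycled to a common length). `NA` propagates.
#' @return A data.frame with columns `contrast` and `size`.
#' @examples
#' to_contrast_size(100, 100)  # contrast 0, size = log2(10100)
#' @export
to_contrast_size <- function(signal_a, signal_b) {
  n <- max(length(signal_a), length(signal_b))
  a <- rep_len(as.numeric(signal_a), n)
  b <- rep_len(as.numeric(signal_b), n)
  bad <- (!is.na(a) & (a < 0 | is.infinite(a))) |
    (!is.na(b) & (b < 0 | is.infinite(b)))
  if (any(bad)) {
    stop("signals must be non-negative and finite (offending index ",
         which(bad)[1], ")")
  }
  la <- log2(a * 100 + 100)
  lb <- log2(b * 100 + 100)
  data.frame(contrast = la - lb, size = (la + lb) / 2)
}

#' Invert the contrast/size transform back to channel signals
#'
#' Solves `to_contrast_size()` for the raw channel intensities. Used by the
#' synthetic-data generator so that sampled (contrast, size) coordinates are
#' reproduced exactly by the forward transform.
#'
#' @param contrast,size Numeric vectors (recycled).
#' @return A data.frame with columns `signal_a` and `signal_b`.
#' @details Requires `size - |contrast|/2 >= log2(100)` so that both solved
#'   signals are non-negative; an error is raised otherwise.
#' @export
contrast_size_to_signals <- function(contrast, size) {
  n <- max(length(contrast), length(size))
  cc <- rep_len(as.numeric(contrast), n)
  ss <- rep_len(as.numeric(size), n)
  la <- ss + cc / 2
  lb <- ss - cc / 2
  a <- (2^la - 100) / 100
  b <- (2^lb - 100) / 100
  bad <- !is.na(a) & !is.na(b) & (a < 0 | b < 0)
  if (any(bad)) {
    stop("(contrast, size) outside the invertible region: size - |contrast|/2 ",
         "must be >= log2(100)")
  }
  data.frame(signal_a = a, signal_b = b)
}
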