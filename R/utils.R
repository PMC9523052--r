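`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

warn2 <- function(...) warning(..., call. = FALSE)

#' Canonical paleoclimate time axis
#'
#' Slice ages follow the spacing of the reconstruction series the package
#' emulates: every 1000 years up to 22 kya and every 2000 years for older
#' slices. Only slices falling inside `[young, old]` are returned.
#'
#' @param young,old Window bounds in calibrated years BP (`young < old`).
#' @return Numeric vector of slice ages in years BP, strictly increasing.
#' @examples
#' paleo_time_axis(7500, 47000)
#' @export
paleo_time_axis <- function(young = 7500, old = 47000) {
  if (!is.numeric(young) || !is.numeric(old) || young >= old)
    stop2("'young' must be smaller than 'old'")
  cand <- c(seq(1000, 22000, by = 1000),
            seq(24000, max(24000, ceiling(old / 2000) * 2000), by = 2000))
  sort(cand[cand >= young & cand <= old])
}

## half-spacing below/above each slice (edge slices reuse the adjacent gap)
slice_gaps <- function(times) {
  n <- length(times)
  if (n == 1) return(list(lo = 1000, hi = 1000))
  d <- diff(times)
  list(lo = c(d[1], d), hi = c(d, d[n - 1]))
}

## normalize longitudes to [-180, 180)
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == 180] <- -180
  out
}
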