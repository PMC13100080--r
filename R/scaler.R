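#' Standardising scaler
#'
#' Fits the affine map `S(x) = sigma * (x - center) / spread` with `center`
#' the training-window mean.  Two readings of the spread are supported:
#' `"range"` (the default, used by the reservoir input layer) takes
#' `spread = max |x - center|`, so the re-centred oscillation range maps
#' exactly into the `[-sigma, sigma]` interval and a spiky voltage trace
#' never saturates the tanh nodes; `"rms"` takes the root-mean-square
#' deviation, so the scaled series has standard deviation `sigma`.
#'
#' @param x numeric series to fit on.
#' @param sigma target amplitude, in (0, 1) for tanh-friendly inputs.
#' @param method `"range"` or `"rms"` spread (see above).
#' @return an object of class `rc_scaler` with fields `center`, `spread`,
#'   `sigma`, `method`.
#' @export
fit_scaler <- function(x, sigma, method = c("range", "rms")) {
  stopifnot(is.numeric(x), length(x) >= 2, sigma > 0)
  method <- match.arg(method)
  center <- mean(x)
  spread <- if (method == "range") max(abs(x - center))
            else sqrt(mean((x - center)^2))
  if (spread < 1e-300 || !is.finite(spread))
    stop("cannot fit scaler on a constant series (zero spread)")
  structure(list(center = center, spread = spread, sigma = sigma,
                 method = method),
            class = "rc_scaler")
}

#' @rdname fit_scaler
#' @param scaler an `rc_scaler` object.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "rc_scaler"))
  scaler$sigma * (x - scaler$center) / scaler$spread
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "rc_scaler"))
  scaler$center + x * scaler$spread / scaler$sigma
}
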