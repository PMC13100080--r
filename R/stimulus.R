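#' Uniformly sampled current protocol
#'
#' @param current numeric vector of injected current samples (uA/cm^2).
#' @param dt_ms sampling interval (ms).
#' @param start_ms time stamp of the first sample.
#' @return an object of class `current_protocol` with elements `I`,
#'   `dt_ms`, `start_ms`.
#' @export
current_protocol <- function(current, dt_ms, start_ms = 0) {
  stopifnot(is.numeric(current), length(current) >= 1, dt_ms > 0)
  if (!all(is.finite(current))) stop("current samples must be finite")
  structure(list(I = as.numeric(current), dt_ms = dt_ms, start_ms = start_ms),
            class = "current_protocol")
}

#' @export
print.current_protocol <- function(x, ...) {
  cat(sprintf("current protocol: %d samples, dt = %g ms (%.6g ms total), range [%.4g, %.4g]\n",
              length(x$I), x$dt_ms, (length(x$I) - 1) * x$dt_ms,
              min(x$I), max(x$I)))
  invisible(x)
}

#' Lorenz system parameters
#'
#' Standard Lorenz-63 coefficients together with a time-scale mapping from
#' Lorenz time units to milliseconds, used to place the chaotic power in a
#' band comparable to the neuron's gate relaxation rates.
#'
#' @param alpha,rho,beta Lorenz coefficients (sigma-rate, Rayleigh, aspect).
#' @param ic 3-vector initial condition.
#' @param time_scale milliseconds per Lorenz time unit, > 0.
#' @return an object of class `lorenz_params`.
#' @export
lorenz_params <- function(alpha = 10, rho = 28, beta = 8 / 3,
                          ic = c(1, 1, 1), time_scale = 25) {
  stopifnot(time_scale > 0, length(ic) == 3)
  structure(list(alpha = alpha, rho = rho, beta = beta,
                 ic = as.numeric(ic), time_scale = time_scale),
            class = "lorenz_params")
}

#' Lorenz x-component sampled as a scalar drive
#'
#' Integrates the Lorenz equations from the stored initial condition and
#' returns the x component sampled every `dt_ms` after the time-scale
#' mapping; the 3D-to-1D mapping is (x, y, z) -> x.  Deterministic for
#' fixed inputs.
#'
#' @param lp a [lorenz_params()] object.
#' @param duration_ms trace duration (ms), > 0.
#' @param dt_ms sampling interval (ms).
#' @return numeric vector of `duration_ms / dt_ms + 1` samples.
#' @export
lorenz_series <- function(lp, duration_ms, dt_ms) {
  stopifnot(inherits(lp, "lorenz_params"), duration_ms > 0, dt_ms > 0)
  n <- round(duration_ms / dt_ms)
  times <- (0:n) * (dt_ms / lp$time_scale)
  if (all(lp$ic == 0)) return(rep(0, n + 1))  # fixed point at the origin
  f <- function(t, y, parms) {
    list(c(parms$alpha * (y[2] - y[1]),
           y[1] * (parms$rho - y[3]) - y[2],
           y[1] * y[2] - parms$beta * y[3]))
  }
  sol <- deSolve::ode(y = lp$ic, times = times, func = f, parms = lp,
                      method = "ode45", rtol = 1e-9, atol = 1e-9)
  x <- sol[, 2]
  if (!all(is.finite(x))) stop("Lorenz integration produced non-finite state")
  unname(x)
}

#' Random current-step parameters
#'
#' @param amp_range length-2 numeric, amplitude bounds (low <= high).
#' @param dur_range length-2 numeric, step duration bounds in ms
#'   (0 < low <= high).
#' @param seed integer seed for reproducible draws.
#' @return an object of class `step_params`.
#' @export
step_params <- function(amp_range = c(-20, 20), dur_range = c(5, 50),
                        seed = 1L) {
  stopifnot(length(amp_range) == 2, length(dur_range) == 2)
  if (amp_range[1] > amp_range[2]) stop("amp_range: low must be <= high")
  if (dur_range[1] <= 0 || dur_range[1] > dur_range[2])
    stop("dur_range: need 0 < low <= high")
  structure(list(amp_range = amp_range, dur_range = dur_range,
                 seed = as.integer(seed)),
            class = "step_params")
}

#' Piecewise-constant random step series
#'
#' Each segment draws its amplitude uniformly from `amp_range` and its
#' duration uniformly from `dur_range`; segments are concatenated until the
#' requested duration is covered.  Fully reproducible from the stored seed.
#'
#' @param sp a [step_params()] object.
#' @param duration_ms trace duration (ms), > 0.
#' @param dt_ms sampling interval (ms).
#' @return numeric vector of `duration_ms / dt_ms + 1` samples.
#' @export
random_steps <- function(sp, duration_ms, dt_ms) {
  stopifnot(inherits(sp, "step_params"), duration_ms > 0, dt_ms > 0)
  n <- round(duration_ms / dt_ms)
  withr::with_seed(sp$seed, {
    durs <- numeric(0); amps <- numeric(0); total <- 0
    while (total < duration_ms) {
      durs <- c(durs, runif(1, sp$dur_range[1], sp$dur_range[2]))
      amps <- c(amps, runif(1, sp$amp_range[1], sp$amp_range[2]))
      total <- sum(durs)
    }
    t <- (0:n) * dt_ms
    idx <- findInterval(t, cumsum(c(0, durs)), rightmost.closed = TRUE)
    idx[idx > length(amps)] <- length(amps)
    amps[idx]
  })
}

#' Protocol generation plan
#'
#' Describes how a mixed identifiability-oriented protocol is assembled:
#' total duration, sampling grid, the random alternation between Lorenz and
#' step regimes (exponentially distributed switch intervals), and the
#' target current range the concatenated series is affinely rescaled into.
#'
#' @param total_ms total duration (ms); must be a multiple of `dt_ms`.
#' @param dt_ms sampling interval (ms).
#' @param target_range length-2 numeric, current range after rescaling.
#' @param mean_segment_ms mean of the exponential switch intervals (ms).
#' @param seed integer seed governing switch times and step draws.
#' @return an object of class `protocol_plan`.
#' @export
protocol_plan <- function(total_ms, dt_ms = 0.25,
                          target_range = c(-2, 22),
                          mean_segment_ms = 50, seed = 1L) {
  stopifnot(total_ms > 0, dt_ms > 0, length(target_range) == 2,
            mean_segment_ms > 0)
  n <- total_ms / dt_ms
  if (abs(n - round(n)) > 1e-8)
    stop("total_ms must be a multiple of dt_ms")
  if (target_range[1] >= target_range[2])
    stop("target_range: low must be < high")
  structure(list(total_ms = total_ms, dt_ms = dt_ms,
                 target_range = target_range,
                 mean_segment_ms = mean_segment_ms, seed = as.integer(seed)),
            class = "protocol_plan")
}

#' Mixed Lorenz / random-step current protocol
#'
#' Builds the identifiability-oriented drive: a continuous Lorenz x-trace
#' and a random step train are generated over the full duration, regimes
#' alternate (starting with Lorenz) at seed-driven exponentially
#' distributed switch times, and the concatenated series is affinely
#' rescaled as a whole into the plan's target range, preserving relative
#' amplitudes across regimes.  Output min and max therefore equal the
#' target bounds exactly.
#'
#' @param plan a [protocol_plan()] object.
#' @param lp a [lorenz_params()] object.
#' @param sp a [step_params()] object (its stored seed is replaced by a
#'   sub-seed derived from the plan seed).
#' @return a [current_protocol()] of `total_ms / dt_ms + 1` samples.
#' @export
mixed_protocol <- function(plan, lp = lorenz_params(), sp = step_params()) {
  stopifnot(inherits(plan, "protocol_plan"), inherits(lp, "lorenz_params"),
            inherits(sp, "step_params"))
  n <- round(plan$total_ms / plan$dt_ms)
  lor <- lorenz_series(lp, plan$total_ms, plan$dt_ms)
  sub <- derive_seeds(plan$seed, 2L)
  sp$seed <- sub[1]
  stp <- random_steps(sp, plan$total_ms, plan$dt_ms)
  mask <- withr::with_seed(sub[2], {
    use_lorenz <- logical(n + 1)
    t0 <- 0; regime <- TRUE   # alternation starts in the Lorenz regime
    tgrid <- (0:n) * plan$dt_ms
    while (t0 <= plan$total_ms) {
      len <- rexp(1, rate = 1 / plan$mean_segment_ms)
      use_lorenz[tgrid >= t0 & tgrid < t0 + len] <- regime
      t0 <- t0 + len
      regime <- !regime
    }
    use_lorenz
  })
  x <- ifelse(mask, lor, stp)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate protocol: constant series")
  lo <- plan$target_range[1]; hi <- plan$target_range[2]
  current_protocol(lo + (x - rng[1]) * (hi - lo) / (rng[2] - rng[1]),
                   plan$dt_ms)
}

#' Spectral bandwidth check against gate relaxation rates
#'
#' Computes the power spectrum of a protocol (DC removed), reports the
#' frequency band containing the central 95% of power, and flags whether
#' that band spans (within a factor of two at each edge) the interval of
#' gate relaxation rates `[1 / (2 pi tau_max), 1 / (2 pi tau_min)]` over
#' all gates evaluated at the resting voltage.  A drive failing this check cannot probe all gate
#' kinetics, so reservoir training data built from it risk being
#' non-identifiable.
#'
#' @param protocol a [current_protocol()] with at least 256 samples.
#' @param params a [neuron_params()] object.
#' @return list with `band_khz` (2-vector), `required_khz` (2-vector),
#'   `spans` (logical) and `reason` (character).
#' @export
protocol_bandwidth_check <- function(protocol, params) {
  stopifnot(inherits(protocol, "current_protocol"),
            inherits(params, "neuron_params"))
  x <- protocol$I
  if (length(x) < 256) stop("protocol must have at least 256 samples")
  vr <- resting_state(params)$v
  taus <- vapply(params$gates, function(g) gate_time_constant(vr, g),
                 numeric(1))
  required <- c(1 / (2 * pi * max(taus)), 1 / (2 * pi * min(taus)))
  if (sd(x) == 0) {
    return(list(band_khz = c(NA_real_, NA_real_), required_khz = required,
                spans = FALSE, reason = "no dynamic content"))
  }
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2
  nf <- floor(n / 2)
  p <- sp[2:(nf + 1)]
  freq <- (1:nf) / (n * protocol$dt_ms)    # cycles per ms = kHz
  cum <- cumsum(p) / sum(p)
  f_lo <- freq[which(cum >= 0.025)[1]]
  f_hi <- freq[which(cum >= 0.975)[1]]
  # spectra roll off smoothly, so gate rates within a factor of two of the
  # central 95% band still receive meaningful drive
  spans <- (f_lo <= 2 * required[1]) && (f_hi >= required[2] / 2)
  list(band_khz = c(f_lo, f_hi), required_khz = required, spans = spans,
       reason = if (spans) "band spans gate relaxation rates"
                else "band does not span gate relaxation rates")
}
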