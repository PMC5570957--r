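#' Calcium-transient response kinetics
#'
#' Parameterizes the idealized FRET-ratio response of a stimulated neuron as
#' a saturating-exponential rise during the stimulus pulse followed by an
#' exponential relaxation back to baseline. This is the minimal transient
#' shape with a well-defined peak and rising-phase slope:
#' \deqn{R(t) = R_0, \quad t < t_{on}}
#' \deqn{R(t) = R_0 (1 + A (1 - e^{-(t - t_{on})/\tau_{rise}})), \quad
#'   t_{on} \le t \le t_{off}}
#' \deqn{R(t) = R_0 + (R(t_{off}) - R_0) e^{-(t - t_{off})/\tau_{decay}},
#'   \quad t > t_{off}}
#'
#' @param R0 Baseline acceptor/donor ratio (dimensionless, > 0).
#' @param A Fractional peak amplitude (>= 0); the ratio saturates at
#'   `R0 * (1 + A)` under a sustained stimulus.
#' @param tau_rise,tau_decay Rise / decay time constants in seconds (> 0).
#' @param t_on,t_off Stimulus onset / offset in seconds (`t_off >= t_on`).
#' @return An object of class `"response_kinetics"`.
#' @examples
#' k <- response_kinetics(R0 = 1, A = 0.3, tau_rise = 5, t_on = 40, t_off = 70)
#' ideal_ratio(k, c(0, 40, 70, 120))
#' @export
response_kinetics <- function(R0 = 1.5, A = 0.3, tau_rise = 5, tau_decay = 8,
                              t_on = 40, t_off = 70) {
  if (R0 <= 0) stop("R0 must be > 0")
  if (A < 0) stop("A must be >= 0")
  if (tau_rise <= 0 || tau_decay <= 0) stop("time constants must be > 0")
  if (t_off < t_on) stop("t_off must be >= t_on")
  structure(list(R0 = R0, A = A, tau_rise = tau_rise, tau_decay = tau_decay,
                 t_on = t_on, t_off = t_off),
            class = "response_kinetics")
}

#' Idealized noise-free FRET-ratio series
#'
#' Evaluates the piecewise transient model of [response_kinetics()] on a
#' time base. The series is continuous at both stimulus edges.
#'
#' @param kinetics A [response_kinetics()] object.
#' @param times Strictly increasing numeric vector of sample times (s).
#' @return Numeric vector of ratio values, one per sample time.
#' @export
ideal_ratio <- function(kinetics, times) {
  stopifnot(inherits(kinetics, "response_kinetics"))
  if (any(diff(times) <= 0)) stop("timebase must be strictly increasing")
  k <- kinetics
  r <- rep(k$R0, length(times))
  rise <- times >= k$t_on & times <= k$t_off
  r[rise] <- k$R0 * (1 + k$A * (1 - exp(-(times[rise] - k$t_on) / k$tau_rise)))
  post <- times > k$t_off
  if (any(post)) {
    r_off <- k$R0 * (1 + k$A * (1 - exp(-(k$t_off - k$t_on) / k$tau_rise)))
    r[post] <- k$R0 + (r_off - k$R0) * exp(-(times[post] - k$t_off) / k$tau_decay)
  }
  r
}

#' Closed-form peak of the idealized transient, as percent change
#'
#' For the saturating-exponential rise the maximum percent change from
#' baseline is reached at stimulus offset:
#' `100 * A * (1 - exp(-(t_off - t_on)/tau_rise))`.
#'
#' @param kinetics A [response_kinetics()] object.
#' @return Peak percent change from baseline (%).
#' @export
peak_percent <- function(kinetics) {
  k <- kinetics
  100 * k$A * (1 - exp(-(k$t_off - k$t_on) / k$tau_rise))
}
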