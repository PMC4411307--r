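#' Consolidation (reference-weight) parameters
#'
#' Each plastic excitatory synapse carries, next to its weight `w`, a slow
#' hidden reference weight `wtilde` that descends the gradient of a double
#' well while being dragged towards the current weight:
#' \deqn{\tau_c \, d\tilde w/dt = (w - \tilde w)
#'       - P\,\tilde w\,(w_P/2 - \tilde w)(w_P - \tilde w).}
#' For `w = wtilde` the drift has roots at 0, `w_P/2` and `w_P`; the outer
#' two are stable, the middle one unstable.  `wtilde` is the set point of
#' heterosynaptic plasticity, so induced changes of `w` that are reverted
#' before `wtilde` has followed leave the synapse unchanged ("reversible
#' window"), while sustained changes consolidate on the `tau_cons`
#' timescale (20-60 min).
#'
#' @param P double-well strength (dimensionless).
#' @param w_P upper stable fixed point (paper value 0.5).
#' @param tau_cons convergence time scale in seconds (default 20 min).
#' @param interval update interval in seconds (default 1.2 s).
#' @return object of class `consolidation_params`.
#' @export
consolidation_params <- function(P = 20, w_P = 0.5, tau_cons = 1200,
                                 interval = 1.2) {
  if (P <= 0 || w_P <= 0) stop("'P' and 'w_P' must be positive")
  if (tau_cons < 20 * 60 || tau_cons > 60 * 60)
    warning("'tau_cons' outside the 20-60 min range")
  structure(list(P = P, w_P = w_P, tau_cons = tau_cons, interval = interval),
            class = "consolidation_params")
}

#' Drift of the reference weight
#'
#' Right-hand side of the reference-weight ODE (in weight units per
#' `tau_cons`), i.e. `(w - wtilde) - P*wtilde*(w_P/2 - wtilde)*(w_P - wtilde)`.
#'
#' @param w current synaptic weight(s).
#' @param wtilde reference weight(s).
#' @param params a [consolidation_params()] object.
#' @return drift value(s).
#' @export
reference_weight_drift <- function(w, wtilde, params) {
  (w - wtilde) -
    params$P * wtilde * (params$w_P / 2 - wtilde) * (params$w_P - wtilde)
}

#' Advance the reference weights by one coarse step
#'
#' Forward-Euler step of the reference-weight ODE, called once every
#' `coarse_dt` seconds (default 1.2 s).
#'
#' @param w numeric vector of current weights.
#' @param wtilde numeric vector of reference weights.
#' @param params a [consolidation_params()] object.
#' @param coarse_dt update interval in seconds.
#' @return updated `wtilde`.
#' @export
step_reference_weights <- function(w, wtilde, params, coarse_dt = params$interval) {
  wtilde + (coarse_dt / params$tau_cons) * reference_weight_drift(w, wtilde, params)
}

#' Fixed points of the reference-weight drift
#'
#' Roots of the cubic drift for a fixed clamped weight `w` (or for the
#' self-coupled case `w = wtilde` when `w = NULL`), with a stability label
#' from the sign of the derivative.
#'
#' @param params a [consolidation_params()] object.
#' @param w either `NULL` (the `w = wtilde` case) or a single fixed weight
#'   at which the coupling term `(w - wtilde)` is evaluated.
#' @return data.frame with columns `root` and `stable`.
#' @export
consolidation_fixed_points <- function(params, w = NULL) {
  P <- params$P; wp <- params$w_P
  ## drift as polynomial in wtilde:
  ## coupling + (-P) * wtilde * (wp/2 - wtilde) * (wp - wtilde)
  ## expand: -P * ( wtilde*(wp/2)(wp) - wtilde^2*(wp/2 + wp) + wtilde^3 )
  c0 <- if (is.null(w)) 0 else w
  c1 <- (if (is.null(w)) 0 else -1) - P * wp^2 / 2
  c2 <- P * 3 * wp / 2
  c3 <- -P
  roots <- polyroot(c(c0, c1, c2, c3))
  re <- Re(roots)[abs(Im(roots)) < 1e-8]
  re <- sort(re)
  deriv <- c1 + 2 * c2 * re + 3 * c3 * re^2
  data.frame(root = re, stable = deriv < 0)
}
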