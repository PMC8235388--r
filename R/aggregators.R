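# Nested CES / CET aggregator primitives in calibrated share form.
#
# All quantities are measured in benchmark-value units (benchmark prices are
# one), so the share parameter of branch k is its benchmark value share and
# the scale parameter is absorbed into the units.  With shares s_k, elasticity
# of substitution sigma (CES) or of transformation psi (CET):
#
#   CES price index  P = (sum_k s_k p_k^(1-sigma))^(1/(1-sigma))
#   CES demand       q_k = q0_k * (Q/Q0) * (P/p_k)^sigma
#   CET price index  P = (sum_k s_k p_k^(1+psi))^(1/(1+psi))
#   CET supply       q_k = q0_k * (Z/Z0) * (p_k/P)^psi
#
# Both satisfy adding-up exactly: sum_k p_k q_k = P * Q (resp. P * Z).
# The Cobb-Douglas limit is taken when |sigma - 1| < 1e-6.

.CD_EPS <- 1e-6

#' CES price (unit-cost) index in calibrated share form
#'
#' @param p positive branch prices.
#' @param s benchmark value shares (nonnegative, summing to 1 over active
#'   branches; zero-share branches are ignored).
#' @param sigma elasticity of substitution (> 0); values within 1e-6 of 1 use
#'   the Cobb-Douglas limiting form.
#' @return the dual price of one unit of the composite.
#' @export
ces_price <- function(p, s, sigma) {
  keep <- s > 0
  p <- p[keep]; s <- s[keep]
  if (!length(p)) return(NA_real_)
  if (abs(sigma - 1) < .CD_EPS) return(prod(p^s))
  (sum(s * p^(1 - sigma)))^(1 / (1 - sigma))
}

#' CES branch demands in calibrated share form
#'
#' @param q0 benchmark branch quantities (benchmark-value units).
#' @param qrel composite quantity relative to benchmark (Q/Q0).
#' @param p branch prices.
#' @param P composite price from [ces_price()] at the same `p`.
#' @param sigma elasticity of substitution.
#' @return branch demand quantities (zero where `q0` is zero).
#' @export
ces_demand <- function(q0, qrel, p, P, sigma) {
  out <- numeric(length(q0))
  keep <- q0 > 0
  if (abs(sigma - 1) < .CD_EPS) {
    out[keep] <- q0[keep] * qrel * P / p[keep]
  } else {
    out[keep] <- q0[keep] * qrel * (P / p[keep])^sigma
  }
  out
}

#' CET price (unit-revenue) index in calibrated share form
#'
#' @inheritParams ces_price
#' @param psi elasticity of transformation (> 0).
#' @export
cet_price <- function(p, s, psi) {
  keep <- s > 0
  p <- p[keep]; s <- s[keep]
  if (!length(p)) return(NA_real_)
  (sum(s * p^(1 + psi)))^(1 / (1 + psi))
}

#' CET branch supplies in calibrated share form
#'
#' @inheritParams ces_demand
#' @param zrel transformed quantity relative to benchmark (Z/Z0).
#' @param P composite price from [cet_price()] at the same `p`.
#' @param psi elasticity of transformation.
#' @export
cet_supply <- function(q0, zrel, p, P, psi) {
  out <- numeric(length(q0))
  keep <- q0 > 0
  out[keep] <- q0[keep] * zrel * (p[keep] / P)^psi
  out
}
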