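#' Nomadic growth rate
#'
#' Pure exponential decay: \code{g1(n1) = -r1 * n1}. Nomads live free of
#' competition and cooperation; under poor conditions their per-capita growth
#' rate is the negative constant \code{-r1}, making nomadism a losing strategy
#' on its own.
#'
#' @param n1 nomadic population size (>= 0)
#' @param params an [nc_params] object
#' @return The growth rate \code{-r1 * n1} (always <= 0).
#' @examples
#' p <- nc_params(r1 = 1, r2 = 10, A = 1.001)
#' nomadic_growth(2, p)   # -2
#' @export
nomadic_growth <- function(n1, params) {
  stop_unless(is_scalar_num(n1) && n1 >= 0, "`n1` must be >= 0")
  -params$r1 * n1
}

#' Colonial growth rate
#'
#' Logistic growth with an Allee effect:
#' \code{g2(n2) = r2 * n2 * (n2/min(A, K) - 1) * (1 - n2/K)}.
#' Growth is positive only for \code{A < n2 < K}; the \code{min(A, K)} term
#' guarantees the rate is zero or negative whenever the carrying capacity has
#' been destroyed below the Allee threshold (\code{K <= A}).
#'
#' @param n2 colonial population size (>= 0)
#' @param K carrying capacity (> 0)
#' @inheritParams nomadic_growth
#' @return The colonial growth rate.
#' @examples
#' p <- nc_params(r1 = 1, r2 = 10, A = 0.5)
#' colonial_growth(2, 5, p)   # 36
#' @export
colonial_growth <- function(n2, K, params) {
  stop_unless(is_scalar_num(n2) && n2 >= 0, "`n2` must be >= 0")
  stop_unless(is_scalar_num(K) && K > 0, "`K` must be > 0")
  params$r2 * n2 * (n2 / min(params$A, K) - 1) * (1 - n2 / K)
}

#' Carrying-capacity dynamics
#'
#' In the reduced parameterisation habitat regenerates at unit rate and each
#' colonist destroys it at unit rate, so \code{dK/dt = 1 - n2}: capacity is
#' stationary exactly at the long-term carrying capacity \code{n2 = 1}. With a
#' finite \code{Kmax} the regeneration saturates:
#' \code{dK/dt = (1 - n2) * (1 - K/Kmax)}.
#'
#' @inheritParams colonial_growth
#' @param K carrying capacity (only used when \code{Kmax} is finite)
#' @return The rate of change of \code{K}.
#' @examples
#' capacity_rate(0, 5, nc_params(r1 = 1, r2 = 10, A = 1.001))         # 1
#' capacity_rate(0.5, 10, nc_params(r1 = 1, r2 = 10, A = 1.001, Kmax = 20))
#' @export
capacity_rate <- function(n2, K = NA_real_, params) {
  stop_unless(is_scalar_num(n2) && n2 >= 0, "`n2` must be >= 0")
  dK <- 1 - n2
  if (is.finite(params$Kmax)) {
    stop_unless(is_scalar_num(K), "`K` is required when Kmax is finite")
    dK <- dK * (1 - K / params$Kmax)
  }
  dK
}

#' Threshold switching rates
#'
#' The capacity-dependent switching rule: colonists switch to nomadism at rate
#' \code{rs} while the carrying capacity is below the lower level
#' (\code{K < L1}), and nomads switch to colonialism at rate \code{rs} while it
#' is above the upper level (\code{K > L2}). Both inequalities are strict; at
#' \code{K = L1} or \code{K = L2} the "otherwise" branch (rate 0) applies.
#'
#' @param K carrying capacity
#' @param policy a [switch_policy] object; for the \code{none} policy both
#'   rates are 0
#' @inheritParams nomadic_growth
#' @return Named numeric vector \code{c(s12 = , s21 = )}, where \code{s12} is
#'   the colonist-to-nomad rate and \code{s21} the nomad-to-colonist rate.
#' @examples
#' p <- nc_params(r1 = 1, r2 = 10, rs = 1000, A = 1.001)
#' switching_rates(2, switch_policy("fixed", L1 = 3, L2 = 4), p)
#' @export
switching_rates <- function(K, policy, params) {
  stop_unless(is_scalar_num(K), "`K` must be a number")
  if (policy$mode == "none") return(c(s12 = 0, s21 = 0))
  L1 <- policy$L1 %||% -Inf
  L2 <- policy$L2 %||% Inf
  c(s12 = if (K < L1) params$rs else 0,
    s21 = if (K > L2) params$rs else 0)
}

#' Full right-hand side of the coupled system
#'
#' Assembles the balance equations for both sub-populations and the capacity:
#' \deqn{dn1/dt = g1(n1) + s12 n2 - s21 n1,\quad
#'       dn2/dt = g2(n2, K) + s21 n1 - s12 n2,\quad dK/dt = 1 - n2.}
#' Switching only transfers organisms, so the switching terms cancel in
#' \code{dn1 + dn2}.
#'
#' @param state an [sim_state] object
#' @inheritParams switching_rates
#' @return Named numeric vector \code{c(dn1 = , dn2 = , dK = )}.
#' @examples
#' p <- nc_params(r1 = 1, r2 = 10, A = 0.5)
#' model_rhs(sim_state(2, 2, 5), p, switch_policy("none"))
#' @export
model_rhs <- function(state, params, policy) {
  s <- switching_rates(state$K, policy, params)
  g1 <- nomadic_growth(state$n1, params)
  g2 <- colonial_growth(state$n2, state$K, params)
  c(dn1 = g1 + s[["s12"]] * state$n2 - s[["s21"]] * state$n1,
    dn2 = g2 + s[["s21"]] * state$n1 - s[["s12"]] * state$n2,
    dK  = capacity_rate(state$n2, state$K, params))
}

## Engine-internal rhs: switching branch given by frozen flags, populations
## clamped for rate evaluation (solver may probe slightly negative values),
## K floored at eps for the singular 1/K term. Mirrors src/nomad_ode.c.
rhs_flags <- function(y, params, s12_on, s21_on, eps_K = 1e-9) {
  n1 <- max(y[[1]], 0)
  n2 <- max(y[[2]], 0)
  K  <- max(y[[3]], eps_K)
  g1 <- -params$r1 * n1
  g2 <- params$r2 * n2 * (n2 / min(params$A, K) - 1) * (1 - n2 / K)
  s12 <- if (s12_on) params$rs else 0
  s21 <- if (s21_on) params$rs else 0
  dK <- 1 - n2
  if (is.finite(params$Kmax)) dK <- dK * (1 - y[[3]] / params$Kmax)
  c(g1 + s12 * n2 - s21 * n1,
    g2 + s21 * n1 - s12 * n2,
    dK)
}
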