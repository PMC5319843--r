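#' Model parameters for the nomadic-colonial system
#'
#' Bundles the rate constants of the two-strategy population model in its
#' reduced parameterisation, where the habitat regeneration rate and the
#' per-organism destruction rate are both scaled to 1, so that the long-term
#' carrying capacity is \code{n* = 1} and all populations and capacities are
#' ratios to it.
#'
#' @param r1 nomadic decay constant (per unit scaled time). The nomadic
#'   sub-population decays as \code{dn1/dt = -r1 * n1}; the losing-strategy
#'   setting requires \code{r1 > 0} (0 is accepted for diagnostic decoupling).
#' @param r2 colonial growth constant (per unit scaled time, > 0 in the
#'   model proper; 0 accepted for diagnostics).
#' @param rs behavioral switching constant (>= 0); 0 disables switching.
#' @param A  colonial critical (Allee) capacity (> 0). Colonial growth is
#'   negative below \code{A}; with \code{A > 1} colonialism alone is a losing
#'   strategy.
#' @param Kmax maximum carrying capacity (> 0), or \code{Inf} for the
#'   unbounded capacity dynamics \code{dK/dt = 1 - n2}. When finite, capacity
#'   follows \code{dK/dt = (1 - n2) * (1 - K/Kmax)}.
#'
#' @return An object of class \code{nc_params}.
#' @examples
#' nc_params(r1 = 1, r2 = 10, rs = 1000, A = 1.001)
#' @export
nc_params <- function(r1, r2, rs = 0, A, Kmax = Inf) {
  stop_unless(is_scalar_num(r1) && r1 >= 0, "`r1` must be a non-negative number")
  stop_unless(is_scalar_num(r2) && r2 >= 0, "`r2` must be a non-negative number")
  stop_unless(is_scalar_num(rs) && rs >= 0, "`rs` must be a non-negative number")
  stop_unless(is_scalar_num(A) && A > 0, "`A` must be a positive number")
  stop_unless(is_scalar_num(Kmax) && Kmax > 0,
              "`Kmax` must be a positive number or Inf")
  structure(list(r1 = r1, r2 = r2, rs = rs, A = A, Kmax = Kmax),
            class = "nc_params")
}

#' @export
print.nc_params <- function(x, ...) {
  cat("<nc_params>  r1 =", x$r1, " r2 =", x$r2, " rs =", x$rs,
      " A =", x$A,
      if (is.finite(x$Kmax)) paste(" Kmax =", x$Kmax) else " (unbounded K)",
      "\n")
  invisible(x)
}

#' Instantaneous simulation state
#'
#' @param n1 nomadic population size (>= 0)
#' @param n2 colonial population size (>= 0)
#' @param K  carrying capacity
#' @param t  scaled time (>= 0), default 0
#' @return An object of class \code{nc_state} (a named list).
#' @examples
#' sim_state(n1 = 2, n2 = 2, K = 5)
#' @export
sim_state <- function(n1, n2, K, t = 0) {
  stop_unless(is_scalar_num(n1) && n1 >= 0, "`n1` must be >= 0")
  stop_unless(is_scalar_num(n2) && n2 >= 0, "`n2` must be >= 0")
  stop_unless(is_scalar_num(K), "`K` must be a number")
  stop_unless(is_scalar_num(t) && t >= 0, "`t` must be >= 0")
  structure(list(t = t, n1 = n1, n2 = n2, K = K), class = "nc_state")
}

## internal helpers ---------------------------------------------------------

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
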