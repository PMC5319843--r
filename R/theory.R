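#' Principal branch of the Lambert W function
#'
#' Solves \code{w * exp(w) = x} for the branch with \code{w >= -1}, by Halley
#' iteration with a branch-point series start near \code{x = -1/e}. The
#' residual \code{|w e^w - x|} is driven below 1e-12.
#'
#' @param x numeric vector, each element \code{>= -1/e}
#' @return \code{w} with \code{w * exp(w) = x}, \code{w >= -1}.
#' @examples
#' lambert_w0(0)          # 0
#' lambert_w0(exp(1))     # 1
#' @export
lambert_w0 <- function(x) {
  vapply(x, lambert_w0_scalar, numeric(1))
}

lambert_w0_scalar <- function(x) {
  stop_unless(is_scalar_num(x), "`x` must be a number")
  em1 <- exp(-1)
  if (x < -em1 - 1e-14)
    stop("lambert_w0: `x` = ", x, " is below -1/e, outside the real domain",
         call. = FALSE)
  x <- max(x, -em1)
  if (x == 0) return(0)
  if (x == -em1) return(-1)

  # initial guess
  if (x < -0.25) {
    # branch-point series in p = sqrt(2 (e x + 1))
    p <- sqrt(2 * (exp(1) * x + 1))
    w <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  } else if (x < 2.5) {
    w <- x / (1 + x)
  } else {
    lx <- log(x)
    w <- lx - log(lx)
  }

  for (i in 1:100) {
    ew <- exp(w)
    f <- w * ew - x
    if (abs(f) <= 1e-13 * (1 + abs(x))) break
    wp1 <- w + 1
    # so close to the branch point that the Halley denominator degenerates:
    # the series start is already at full attainable precision
    if (abs(wp1) < 1e-7) break
    step <- f / (ew * wp1 - (w + 2) * f / (2 * wp1))
    if (!is.finite(step)) break
    w <- w - step
    if (w < -1) w <- -1 + .Machine$double.eps
  }
  w
}

#' Allee capacity compatible with a given critical nomadic level
#'
#' The forward map of the survival theory: for a population whose switching is
#' much faster than growth, a colony seeded by \code{B} nomads at the end of a
#' nomadic phase can just overcome the Allee effect when the Allee capacity is
#' \deqn{A = B - (1 - B)\, W_0\!\left(\tfrac{B}{1-B} e^{B/(1-B)}\right).}
#'
#' The map is increasing on \code{B > 1}, satisfies \code{A <= B}, tends to 1
#' as \code{B} does, and is bounded above by 2: no finite critical level exists
#' for an Allee capacity of 2 or more.
#'
#' @param B critical nomadic level (> 1); may be a vector
#' @return The Allee capacity \code{A}, with \code{1 < A <= B} and \code{A < 2}.
#' @seealso [critical_from_allee] for the inverse.
#' @examples
#' allee_from_critical(2)   # ~1.5936
#' @export
allee_from_critical <- function(B) {
  vapply(B, function(b) {
    stop_unless(is_scalar_num(b) && b > 1, "`B` must be > 1")
    z <- b / (1 - b)              # < -1 for b > 1
    b - (1 - b) * lambert_w0(z * exp(z))
  }, numeric(1))
}

#' Critical nomadic level for a given Allee capacity
#'
#' Inverts [allee_from_critical] by bracketed root search, using the
#' monotonicity of the forward map. Defined for \code{1 < A < 2} only: the
#' forward map never reaches 2, so above that no nomadic reserve, however
#' large, lets a colony overcome the Allee effect under these dynamics.
#'
#' @param A Allee capacity, \code{1 < A < 2}
#' @param tol absolute tolerance of the root search (default 1e-10)
#' @return The critical level \code{B >= A} with
#'   \code{allee_from_critical(B) = A} to within \code{tol}.
#' @examples
#' critical_from_allee(1.5936243)   # ~2
#' @export
critical_from_allee <- function(A, tol = 1e-10) {
  stop_unless(is_scalar_num(A), "`A` must be a number")
  if (A <= 1)
    stop("`A` must be > 1: the survival analysis applies only above the ",
         "long-term carrying capacity", call. = FALSE)
  if (A >= 2)
    stop("no finite critical level exists for `A` >= 2: the forward map ",
         "allee_from_critical() is bounded above by 2", call. = FALSE)
  f <- function(B) allee_from_critical(B) - A
  lo <- A
  hi <- max(2 * A, 10)
  while (f(hi) < 0) {
    hi <- hi * 10
    if (hi > 1e12)
      stop("bracket expansion failed inverting the critical-level map",
           call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Lower bound on the lower switching level
#'
#' For survival by periodic alternation with critical level \code{B}, the
#' lower switching level must satisfy \code{L1 > B e^B / (e^B - 1)}. The bound
#' always exceeds \code{B} and tends to it as \code{B} grows.
#'
#' @param B critical nomadic level (> 1)
#' @return The strict lower bound on \code{L1}.
#' @examples
#' l1_lower_bound(2)   # ~2.313
#' @export
l1_lower_bound <- function(B) {
  vapply(B, function(b) {
    stop_unless(is_scalar_num(b) && b > 1, "`B` must be > 1")
    b * exp(b) / (exp(b) - 1)
  }, numeric(1))
}

#' Upper bound on the upper switching level
#'
#' Given an admissible lower level \code{L1} and nomadic decay constant
#' \code{r1}, periodic alternation can only sustain the population when
#' \deqn{L2 < L1 + \tfrac{1}{r1} \ln\frac{L1 + W_0(-L1 e^{-L1})}{B}.}
#' Larger gaps make the nomadic phase so long that the nomadic reserve decays
#' below the critical level \code{B} before recolonisation.
#'
#' @param L1 lower switching level (> 0)
#' @param B critical nomadic level (> 1)
#' @param r1 nomadic decay constant (> 0)
#' @return The strict upper bound on \code{L2}, or \code{NA} (with a warning)
#'   when the logarithm's argument is not positive, i.e. when no admissible
#'   \code{L2 >= L1} exists because \code{L1} is at or below [l1_lower_bound].
#' @examples
#' B <- critical_from_allee(1.001)
#' l2_upper_bound(3, B, 1)   # ~4.04: separates the surviving L2 = 4
#'                           # from the extinct L2 = 4.5
#' @export
l2_upper_bound <- function(L1, B, r1) {
  stop_unless(is_scalar_num(L1) && L1 > 0, "`L1` must be > 0")
  stop_unless(is_scalar_num(B) && B > 1, "`B` must be > 1")
  stop_unless(is_scalar_num(r1) && r1 > 0, "`r1` must be > 0")
  ratio <- (L1 + lambert_w0(-L1 * exp(-L1))) / B
  if (!is.finite(ratio) || ratio <= 0) {
    warning("no admissible L2 exists: L1 is at or below its lower bound")
    return(NA_real_)
  }
  L1 + log(ratio) / r1
}

#' Guaranteed outcome of pure colonialism
#'
#' With an Allee capacity above the long-term carrying capacity (\code{A > 1})
#' the only stable state of an isolated colony is extinction; with
#' \code{A < 1} survival is possible (the colony stabilises at
#' \code{n2 = K = 1} when started with \code{A < n2 < K}).
#'
#' @param A Allee capacity (> 0, not equal to 1)
#' @return \code{"extinction_guaranteed"} or \code{"survival_possible"}.
#' @examples
#' colonial_outcome(1.001)  # extinction_guaranteed
#' colonial_outcome(0.5)    # survival_possible
#' @export
colonial_outcome <- function(A) {
  stop_unless(is_scalar_num(A) && A > 0, "`A` must be > 0")
  if (A == 1)
    stop("`A` = 1 is the undetermined boundary case", call. = FALSE)
  if (A > 1) "extinction_guaranteed" else "survival_possible"
}

#' Survival bounds for a parameter set
#'
#' Convenience wrapper collecting the derived quantities of the survival
#' theory: the critical nomadic level \code{B}, the lower bound on \code{L1},
#' and (when \code{L1} and \code{r1} are supplied) the upper bound on
#' \code{L2}.
#'
#' @param A Allee capacity, \code{1 < A < 2}
#' @param L1 optional lower switching level
#' @param r1 optional nomadic decay constant (required with \code{L1})
#' @return An object of class \code{nc_theory_bounds}: a list with elements
#'   \code{A}, \code{B}, \code{L1_min} and (optionally) \code{L1},
#'   \code{L2_max}.
#' @examples
#' theory_bounds(1.001, L1 = 3, r1 = 1)
#' @export
theory_bounds <- function(A, L1 = NULL, r1 = NULL) {
  B <- critical_from_allee(A)
  out <- list(A = A, B = B, L1_min = l1_lower_bound(B))
  if (!is.null(L1)) {
    stop_unless(!is.null(r1), "`r1` is required when `L1` is given")
    out$L1 <- L1
    out$r1 <- r1
    out$L2_max <- l2_upper_bound(L1, B, r1)
  }
  structure(out, class = "nc_theory_bounds")
}

#' @export
print.nc_theory_bounds <- function(x, ...) {
  cat("Survival bounds (fast-switching theory)\n")
  cat(sprintf("  A       %.10g\n", x$A))
  cat(sprintf("  B       %.10g   (critical nomadic level)\n", x$B))
  cat(sprintf("  L1_min  %.10g   (L1 must exceed this)\n", x$L1_min))
  if (!is.null(x$L2_max))
    cat(sprintf("  L2_max  %.10g   (L2 must stay below this, given L1 = %g, r1 = %g)\n",
                x$L2_max, x$L1, x$r1))
  invisible(x)
}
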