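#' Simulate the nomadic-colonial system
#'
#' Integrates the coupled population/capacity equations with event-located
#' switching. The threshold rule makes the right-hand side discontinuous in
#' \code{K}, so the active switching branch is frozen per segment, the solver
#' (an adaptive LSODAR pair with root finding, via \pkg{deSolve}) locates each
#' threshold crossing, and integration restarts there with the re-evaluated
#' branch. Under the adaptive rule the located events additionally reassign
#' the thresholds themselves.
#'
#' Event types recorded: \code{K_crossed_L1_down}, \code{K_crossed_L1_up},
#' \code{K_crossed_L2_up}, \code{K_crossed_L2_down},
#' \code{n2_reached_K_growing} (observational under the fixed rule, threshold
#' reassignment under the adaptive rule) and \code{n1_reached_B_decaying}
#' (adaptive rule only).
#'
#' @param params an [nc_params] object
#' @param policy a [switch_policy] object
#' @param init an [sim_state] object (initial condition, \code{t = 0})
#' @param options an [sim_options] object
#' @return An object of class \code{nc_trajectory}: a list with numeric
#'   vectors \code{times}, \code{n1}, \code{n2}, \code{K}, a data frame
#'   \code{events} (\code{time}, \code{type}, state snapshot), a data frame
#'   \code{phases} (\code{start}, \code{end}, \code{phase} in
#'   \code{nomadic / colonial / switching}), and the inputs echoed back.
#' @examples
#' p <- nc_params(r1 = 1, r2 = 10, rs = 1000, A = 1.001)
#' traj <- nc_simulate(p, switch_policy("fixed", L1 = 3, L2 = 4),
#'                     sim_state(2, 2, 5), sim_options(t_end = 20))
#' head(as.data.frame(traj))
#' @export
nc_simulate <- function(params, policy, init, options) {
  stopifnot(inherits(params, "nc_params"), inherits(policy, "nc_policy"),
            inherits(init, "nc_state"), inherits(options, "nc_options"))
  if (policy$mode == "fixed" && params$rs <= 0)
    warning("fixed switching policy with rs = 0 never switches")
  if (policy$mode == "adaptive" && is.null(policy$B)) {
    if (params$A <= 1)
      stop("the adaptive rule needs a critical level B; supply `B` or use A > 1",
           call. = FALSE)
    policy$B <- critical_from_allee(params$A)
  }

  eps_K <- 1e-9
  t0 <- init$t
  t_end <- options$t_end
  grid <- options$output_times %||% seq(t0, t_end, length.out = options$n_out)
  grid <- sort(unique(c(t0, grid, t_end)))
  hmax <- options$max_step %||% ((t_end - t0) / 200)

  y <- c(init$n1, init$n2, init$K)

  ## engine policy state: active thresholds, watches and frozen branch flags
  es <- list(
    mode = policy$mode,
    L1 = switch(policy$mode, none = -Inf, fixed = policy$L1,
                adaptive = policy$L1 %||% -Inf),
    L2 = switch(policy$mode, none = Inf, fixed = policy$L2,
                adaptive = policy$L2 %||% Inf),
    B = if (policy$mode == "adaptive")
      policy$B * (1 + policy$B_margin) else NA_real_,
    watch_n2K = policy$mode != "none",
    watch_B = policy$mode == "adaptive"
  )
  dK0 <- capacity_rate(max(init$n2, 0), init$K, params)
  es$s12_on <- side_below(init$K, es$L1, dK0)
  es$s21_on <- side_above(init$K, es$L2, dK0)

  times <- y1 <- y2 <- y3 <- numeric(0)
  push <- function(m) {
    keep <- m[, 1] > (if (length(times)) times[length(times)] else -Inf)
    if (any(keep)) {
      m <- unname(m[keep, , drop = FALSE])
      times <<- c(times, m[, 1]); y1 <<- c(y1, m[, 2])
      y2 <<- c(y2, m[, 3]); y3 <<- c(y3, m[, 4])
    }
  }
  push(matrix(c(t0, y), nrow = 1))

  ev_time <- numeric(0); ev_type <- character(0)
  ev_n1 <- ev_n2 <- ev_K <- numeric(0)
  seg_start <- numeric(0); seg_label <- character(0)
  colonial_active <- es$s21_on ||
    (!es$s12_on && init$n2 > options$extinction_floor)

  label_of <- function() {
    if (es$s12_on) "switching" else if (colonial_active) "colonial" else "nomadic"
  }

  t_cur <- t0
  n_ev <- 0L
  stall <- 0L
  repeat {
    seg_start <- c(seg_start, t_cur); seg_label <- c(seg_label, label_of())
    seg_times <- c(t_cur, grid[grid > t_cur + 1e-12])
    if (length(seg_times) < 2) seg_times <- c(t_cur, t_end)

    out <- run_segment(y, seg_times, params, es, options, hmax, eps_K)
    push(unclass(out)[, 1:4, drop = FALSE])

    troot <- attr(out, "troot")
    if (is.null(troot) || !length(troot) || !is.finite(troot[1]) ||
        troot[1] >= t_end - 1e-12) break

    t_ev <- troot[1]
    y <- as.numeric(out[nrow(out), 2:4])
    ind <- which(attr(out, "iroot") == 1L)
    rates <- rhs_flags(y, params, es$s12_on, es$s21_on, eps_K)
    dK <- rates[3]

    ## tie-break for coincident roots: policy reassignment (adaptive events
    ## 3, 4) before threshold-branch re-evaluation (events 1, 2)
    for (k in ind[order(match(ind, c(3L, 4L, 1L, 2L)))]) {
      if (k == 3L) {                      # n2 crossed K
        rising <- (rates[2] - rates[3]) > 0
        if (rising) {
          record_event <- TRUE
          if (es$mode == "adaptive") {
            es$L1 <- y[3]; es$L2 <- Inf
            es$s12_on <- side_below(y[3], es$L1, dK)
            es$s21_on <- FALSE
            colonial_active <- FALSE
          }
          ev_time <- c(ev_time, t_ev); ev_type <- c(ev_type, "n2_reached_K_growing")
          ev_n1 <- c(ev_n1, y[1]); ev_n2 <- c(ev_n2, y[2]); ev_K <- c(ev_K, y[3])
        }
      } else if (k == 4L) {               # n1 decayed to B
        if (rates[1] < 0) {
          es$L2 <- y[3]
          es$s21_on <- side_above(y[3], es$L2, dK)
          if (es$s21_on) colonial_active <- TRUE
          ev_time <- c(ev_time, t_ev); ev_type <- c(ev_type, "n1_reached_B_decaying")
          ev_n1 <- c(ev_n1, y[1]); ev_n2 <- c(ev_n2, y[2]); ev_K <- c(ev_K, y[3])
        }
      } else if (k == 1L) {               # K crossed L1
        es$s12_on <- side_below(y[3], es$L1, dK)
        if (es$s12_on) colonial_active <- FALSE
        ev_time <- c(ev_time, t_ev)
        ev_type <- c(ev_type,
                     if (dK < 0) "K_crossed_L1_down" else "K_crossed_L1_up")
        ev_n1 <- c(ev_n1, y[1]); ev_n2 <- c(ev_n2, y[2]); ev_K <- c(ev_K, y[3])
      } else if (k == 2L) {               # K crossed L2
        es$s21_on <- side_above(y[3], es$L2, dK)
        if (es$s21_on) colonial_active <- TRUE
        ev_time <- c(ev_time, t_ev)
        ev_type <- c(ev_type,
                     if (dK > 0) "K_crossed_L2_up" else "K_crossed_L2_down")
        ev_n1 <- c(ev_n1, y[1]); ev_n2 <- c(ev_n2, y[2]); ev_K <- c(ev_K, y[3])
      }
    }

    n_ev <- n_ev + length(ind)
    if (n_ev > options$max_events)
      stop("event cap exceeded (", options$max_events,
           "): the switching dynamics did not settle; last state t = ", t_ev,
           call. = FALSE)
    stall <- if (t_ev - t_cur < 1e-12) stall + 1L else 0L
    if (stall > 200L)
      stop("integration stalled at t = ", t_ev,
           " (repeated events at one time point)", call. = FALSE)
    t_cur <- t_ev
  }

  phases <- data.frame(start = seg_start,
                       end = c(seg_start[-1], t_end),
                       phase = seg_label, stringsAsFactors = FALSE)
  phases <- merge_phases(phases)

  structure(list(
    times = times, n1 = pmax(y1, 0), n2 = pmax(y2, 0), K = y3,
    events = data.frame(time = ev_time, type = ev_type, n1 = ev_n1,
                        n2 = ev_n2, K = ev_K, stringsAsFactors = FALSE),
    phases = phases,
    params = params, policy = policy, init = init, options = options,
    n_segments = length(seg_start)
  ), class = "nc_trajectory")
}

## one lsodar segment with the frozen switching branch; roots terminate it
run_segment <- function(y, seg_times, params, es, options, hmax, eps_K) {
  parms <- c(params$r1, params$r2, params$rs, params$A,
             if (is.finite(params$Kmax)) params$Kmax else 1,
             as.numeric(is.finite(params$Kmax)),
             as.numeric(es$s12_on), as.numeric(es$s21_on),
             if (is.finite(es$L1)) es$L1 else -1e30,
             if (is.finite(es$L2)) es$L2 else 1e30,
             if (es$watch_B) es$B else -1e30,
             as.numeric(es$watch_n2K), as.numeric(es$watch_B),
             eps_K)
  use_roots <- es$mode != "none"
  out <- deSolve::lsodar(
    y = y, times = seg_times, func = "nc_derivs", parms = parms,
    rtol = options$rtol, atol = options$atol, hmax = hmax,
    rootfunc = if (use_roots) "nc_root" else NULL,
    nroot = if (use_roots) 4L else 0L,
    dllname = "nomadcolony", initfunc = "nc_initmod",
    maxsteps = 500000)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("ODE solver failure (istate = ", istate[1], ") near t = ",
         out[nrow(out), 1], "; state = (",
         paste(signif(out[nrow(out), 2:4], 6), collapse = ", "), ")",
         call. = FALSE)
  out
}

## strict-side tests with the capacity derivative breaking exact ties:
## dK/dt does not depend on the switching branch, so the side K is about to
## occupy is well defined even at a threshold.
side_below <- function(K, L, dK) {
  if (K < L) TRUE else if (K > L) FALSE else dK < 0
}
side_above <- function(K, L, dK) {
  if (K > L) TRUE else if (K < L) FALSE else dK > 0
}

merge_phases <- function(ph) {
  if (nrow(ph) < 2) return(ph)
  keep <- c(TRUE, ph$phase[-1] != ph$phase[-nrow(ph)])
  idx <- cumsum(keep)
  data.frame(start = tapply(ph$start, idx, min),
             end = tapply(ph$end, idx, max),
             phase = ph$phase[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}
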