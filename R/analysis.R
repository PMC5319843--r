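#' Classify the long-run regime of a trajectory
#'
#' Maps a simulated trajectory to one of the qualitative outcome regimes:
#' without switching, extinction of both sub-populations
#' (\code{both_extinct_no_switching}) or colonial survival at the long-term
#' carrying capacity (\code{colonial_survives_no_switching}); with switching,
#' extinction (\code{extinct_with_switching}), persistence by periodic
#' alternation (\code{periodic_survival}), or \code{long_term_growth} when the
#' per-cycle peak carrying capacity is still climbing at the end of the run.
#'
#' Extinction is judged against \code{options$extinction_floor} at the final
#' time (the continuum model never reaches zero in finite time). Growth is
#' declared when, among the last five complete alternation cycles, at least
#' three consecutive cycles raise the peak capacity by more than
#' \code{growth_tol} relative per cycle.
#'
#' @param traj an \code{nc_trajectory}
#' @param growth_tol minimal relative per-cycle increase of peak \code{K}
#'   counted as growth (default 0.01, matching [detect_plateau])
#' @return A single regime label (character); \code{"undetermined"} with a
#'   warning when no pattern fits.
#' @examples
#' p <- nc_params(r1 = 1, r2 = 10, rs = 0, A = 0.5)
#' traj <- nc_simulate(p, switch_policy("none"), sim_state(2, 2, 5),
#'                     sim_options(t_end = 50))
#' classify_regime(traj)   # colonial_survives_no_switching
#' @export
classify_regime <- function(traj, growth_tol = 0.01) {
  fl <- traj$options$extinction_floor
  fin <- final_state(traj)
  switching <- traj$policy$mode != "none" && traj$params$rs > 0

  if (!switching) {
    if (fin[["n1"]] < fl && fin[["n2"]] < fl)
      return("both_extinct_no_switching")
    if (abs(fin[["n2"]] - 1) < 0.01)
      return("colonial_survives_no_switching")
    warning("trajectory fits no non-switching regime pattern")
    return("undetermined")
  }

  if (fin[["n1"]] + fin[["n2"]] < fl)
    return("extinct_with_switching")

  peaks <- phase_peaks(traj)
  if (nrow(peaks) >= 3) {
    last <- utils::tail(peaks$peak_K, 5)
    rel <- diff(last) / utils::head(last, -1)
    if (length(rel) >= 2) {
      growing <- rel > growth_tol
      run <- rle(growing)
      if (any(run$lengths[run$values] >= 2))   # 3 cycles = 2 rises
        return("long_term_growth")
    }
  }
  "periodic_survival"
}

#' Per-cycle peak statistics
#'
#' Splits a switching trajectory into alternation cycles anchored at colonial
#' entries (the capacity rising through \code{L2} under the fixed rule, the
#' nomadic reserve decaying to \code{B} under the adaptive rule; a run that
#' starts in a colonial phase contributes its start as the first anchor) and
#' reports the maxima of \code{n1}, \code{n2} and \code{K} within each
#' complete cycle.
#'
#' @param traj an \code{nc_trajectory}
#' @return A data frame with one row per complete cycle: \code{cycle},
#'   \code{cycle_start}, \code{cycle_end}, \code{peak_n1}, \code{peak_n2},
#'   \code{peak_K}. Empty when fewer than one complete cycle exists.
#' @export
phase_peaks <- function(traj) {
  anchors <- cycle_anchors(traj)
  empty <- data.frame(cycle = integer(0), cycle_start = numeric(0),
                      cycle_end = numeric(0), peak_n1 = numeric(0),
                      peak_n2 = numeric(0), peak_K = numeric(0))
  if (length(anchors) < 2) return(empty)
  n_cyc <- length(anchors) - 1L
  res <- lapply(seq_len(n_cyc), function(i) {
    sel <- traj$times >= anchors[i] & traj$times < anchors[i + 1]
    if (!any(sel)) return(NULL)
    data.frame(cycle = i, cycle_start = anchors[i], cycle_end = anchors[i + 1],
               peak_n1 = max(traj$n1[sel]), peak_n2 = max(traj$n2[sel]),
               peak_K = max(traj$K[sel]))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty else out
}

cycle_anchors <- function(traj) {
  entry_type <- if (traj$policy$mode == "adaptive")
    "n1_reached_B_decaying" else "K_crossed_L2_up"
  anchors <- traj$events$time[traj$events$type == entry_type]
  ph1 <- traj$phases$phase[1]
  if (identical(ph1, "colonial"))
    anchors <- c(traj$phases$start[1], anchors)
  anchors
}

#' Colonial-phase growth condition
#'
#' Survival by alternation additionally requires that, in each colonial phase,
#' the colony grows fast enough to meet the falling carrying capacity at a
#' level still above the lower switching threshold: there is a time
#' \code{t*} in the phase with \code{n2(t*) = K(t*) >= L1}. The intersection
#' is taken from the recorded \code{n2_reached_K_growing} events.
#'
#' @param traj an \code{nc_trajectory}
#' @param L1 lower switching level; defaults to the policy's
#' @return Logical vector, one element per colonial phase (TRUE when the
#'   condition holds in that phase).
#' @export
check_growth_condition <- function(traj, L1 = NULL) {
  L1 <- L1 %||% traj$policy$L1
  stop_unless(is_scalar_num(L1), "`L1` is required (policy carries none)")
  ph <- traj$phases[traj$phases$phase == "colonial", , drop = FALSE]
  if (nrow(ph) == 0) return(logical(0))
  ev <- traj$events[traj$events$type == "n2_reached_K_growing", , drop = FALSE]
  vapply(seq_len(nrow(ph)), function(i) {
    hit <- ev$time >= ph$start[i] & ev$time <= ph$end[i] & ev$K >= L1 - 1e-9
    any(hit)
  }, logical(1))
}

#' Detect a plateau in per-cycle peak capacity
#'
#' Long-term growth under the adaptive rule eventually saturates: once the
#' colony gets large, conversion back to nomadism takes long enough to drag
#' the capacity down by as much as the next nomadic phase rebuilds. The
#' plateau onset is defined as the start time of the first cycle after which
#' the peak capacity changes by less than \code{rel_change} (relative) per
#' cycle for all remaining cycles.
#'
#' @param peaks a data frame from [phase_peaks] (>= 5 cycles recommended)
#' @param rel_change relative per-cycle change threshold (default 0.01)
#' @return The plateau onset time, or \code{NA_real_} when the peaks never
#'   settle.
#' @export
detect_plateau <- function(peaks, rel_change = 0.01) {
  pk <- peaks$peak_K
  n <- length(pk)
  if (n < 2) return(NA_real_)
  rel <- abs(diff(pk)) / utils::head(pk, -1)
  ok <- rel < rel_change
  if (!any(!ok)) return(peaks$cycle_start[1])
  j <- max(which(!ok)) + 1L
  if (j > n - 1L) return(NA_real_)       # still moving at the last change
  peaks$cycle_start[j]
}
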