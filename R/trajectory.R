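#' @export
print.nc_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("<nc_trajectory> ", n, " samples on [",
      format(x$times[1]), ", ", format(x$times[n]), "], ",
      nrow(x$events), " events, policy ", x$policy$mode, "\n", sep = "")
  cat(sprintf("  final state: n1 = %.6g, n2 = %.6g, K = %.6g\n",
              x$n1[n], x$n2[n], x$K[n]))
  invisible(x)
}

#' Flatten a trajectory to a data frame
#'
#' @param x an \code{nc_trajectory}
#' @param ... unused
#' @return A data frame with columns \code{t}, \code{n1}, \code{n2},
#'   \code{K}, \code{phase}.
#' @export
as.data.frame.nc_trajectory <- function(x, ...) {
  ph <- x$phases
  idx <- findInterval(x$times, ph$start, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  data.frame(t = x$times, n1 = x$n1, n2 = x$n2, K = x$K,
             phase = ph$phase[idx], stringsAsFactors = FALSE)
}

#' Final state of a trajectory
#'
#' @param traj an \code{nc_trajectory}
#' @return Named numeric vector \code{c(t, n1, n2, K)}.
#' @export
final_state <- function(traj) {
  n <- length(traj$times)
  c(t = traj$times[n], n1 = traj$n1[n], n2 = traj$n2[n], K = traj$K[n])
}

#' Quick trajectory plot
#'
#' Minimal base-graphics view of the three state series; intended for
#' interactive inspection, not figure reproduction.
#'
#' @param x an \code{nc_trajectory}
#' @param log plot populations on a log scale ("y") or not ("")
#' @param ... passed to [graphics::matplot]
#' @export
plot.nc_trajectory <- function(x, log = "", ...) {
  graphics::matplot(x$times, cbind(x$n1, x$n2, x$K), type = "l", lty = 1,
                    col = c("#D55E00", "#0072B2", "#009E73"),
                    xlab = "t", ylab = "value", log = log, ...)
  graphics::legend("topleft", legend = c("n1 (nomads)", "n2 (colonists)", "K"),
                   col = c("#D55E00", "#0072B2", "#009E73"), lty = 1, bty = "n")
  invisible(x)
}
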