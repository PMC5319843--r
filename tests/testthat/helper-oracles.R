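# Independent bisection oracle for the principal Lambert W branch:
# deliberately naive so it shares nothing with the package's Halley iteration.
w_bisect <- function(x, lo = -1, hi = 100) {
  f <- function(w) w * exp(w) - x
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# relative difference guarded below the extinction floor, where the absolute
# solver tolerance dominates and relative comparison is meaningless
guarded_rel_diff <- function(a, b, floor = 1e-6) {
  abs(a - b) / pmax(abs(a), abs(b), floor)
}

fig2_params <- function(rs = 1000) nc_params(r1 = 1, r2 = 10, rs = rs, A = 1.001)

std_init <- function() sim_state(n1 = 2, n2 = 2, K = 5)
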