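# Independent oracles used to pin expected values, kept deliberately free of
# the package's closed-form code paths.

# Fixed-point iteration on the mass-balance relation
#   B <- r*T*(ag0 - B) / ((ag0 - B) + kd)
# converges to the physical bound amount; returns B/T.
oracle_bound_fraction <- function(ag0, r, kd, t_total,
                                  tol = 1e-14, max_iter = 100000L) {
  if (ag0 == 0) return(0)
  b <- 0
  for (i in seq_len(max_iter)) {
    b_new <- r * t_total * (ag0 - b) / ((ag0 - b) + kd)
    if (abs(b_new - b) < tol * max(1, abs(b_new))) return(b_new / t_total)
    b <- b_new
  }
  stop("fixed-point oracle did not converge")
}

default_kd_axis <- function() c(0.01, 0.0316, 0.1, 0.316, 1, 3.16, 10,
                                31.62, 100)
default_ag <- function() c(1.25, 2.5, 5, 10, 20, 40, 80)

default_params <- function() binding_parameters(r = 0.7, kd = 1,
                                                t_total = 0.1)

# Noise-free kinetics-distorted saturation points at one KD, the Table 2
# generating conditions.
table2_points <- function(kd, t = 1200, kon = 0.0001444) {
  p <- default_params()
  ag <- default_ag()
  bf <- bound_fraction_exact(ag, p, kd = kd) * (1 - exp(-kon * ag * t))
  data.frame(ag0 = ag, bound_fraction = bf)
}
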