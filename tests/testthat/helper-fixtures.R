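# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures.

demo_subject <- function(weight_kg = 2.5, activity_MBq = 7.2,
                         group = "healthy") {
  subject_info("test-rabbit", "rabbit", group, weight_kg, activity_MBq)
}

# A near-step arterial input: one very short leading frame so the
# piecewise-linear interpolant rises from zero almost instantaneously,
# then constant amplitude. Closed forms for the 1TCM response to a unit
# step then apply to within the ramp width.
step_input <- function(amplitude = 1, t_end_s = 360) {
  starts <- c(0, seq(0.01, t_end_s - 0.99, by = 1))
  durs <- c(0.01, rep(1, length(starts) - 1))
  sched <- frame_schedule(starts, durs)
  tac("step", sched, rep(amplitude, nrow(sched)),
      decay_corrected = TRUE, nuclide = o15())
}

# Independent ODE oracle for the 1TCM: integrates
# dCt/dt = K1*Ca(t) - k2*Ct with lsoda on the same piecewise-linear
# input interpretation the model uses (zero prepended at t = 0, constant
# extension beyond the last node).
ode_1tcm_oracle <- function(K1, k2, input, t_out_min) {
  ip <- tac_resample_midpoints(input)
  xs <- ip$time_min; ys <- ip$conc_kBq_per_mL
  if (xs[1] > 0) { xs <- c(0, xs); ys <- c(0, ys) }
  ca <- approxfun(xs, ys, rule = 2)
  rhs <- function(t, y, parms) list(K1 * ca(t) - k2 * y)
  out <- deSolve::lsoda(c(Ct = 0), times = c(0, t_out_min), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  out[-1, "Ct"]
}

# Paper-era blood sampling schedule (hours).
plasma_times_h <- function() c(1/60, 5/60, 10/60, 0.5, 1, 2, 3, 4, 24, 48, 72, 168)

small_masses <- function() {
  list(rabbit = phantom_masses("rabbit",
                               c(liver = 0.09, spleen = 0.003, kidneys = 0.016),
                               2.5),
       human = phantom_masses("human",
                              c(liver = 1.8, spleen = 0.15, kidneys = 0.31),
                              70))
}
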