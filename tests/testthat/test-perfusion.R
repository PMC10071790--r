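test_that("model_curve limiting cases: K1 = 0 and k2 = 0", {
  inp <- sim_input_function(sim_config())
  sched <- inp$schedule
  expect_true(all(model_curve(0, 3, inp, sched) == 0))
  # k2 = 0: running integral of the input, monotone non-decreasing
  m <- model_curve(2, 0, inp, sched)
  expect_true(all(diff(m) >= -1e-12))
  expect_error(model_curve(-1, 1, inp, sched), ">= 0")
})

test_that("step-input response matches the closed form (K1/k2)(1 - exp(-k2 t))", {
  step <- step_input(1)
  sched <- step$schedule
  mids_min <- sched$mid_s / 60
  m <- model_curve(2, 4, step, sched, frame_value = "midpoint")
  expected <- 0.5 * (1 - exp(-4 * mids_min))
  keep <- sched$mid_s >= 30  # clear of the sub-frame onset ramp
  expect_lt(max(abs(m[keep] / expected[keep] - 1)), 1e-3)
})

test_that("model_curve agrees with independent ODE integration across the perfusion regime", {
  inp <- sim_input_function(sim_config())
  sched <- inp$schedule
  for (K1 in c(0.5, 2, 5.25, 6)) {
    for (k2 in c(0.5, 2.13, 5.6)) {
      m <- model_curve(K1, k2, inp, sched, frame_value = "midpoint")
      oracle <- ode_1tcm_oracle(K1, k2, inp, sched$mid_s / 60)
      keep <- oracle > 1e-3 * max(oracle)
      expect_lt(max(abs(m[keep] / oracle[keep] - 1)), 1e-3)
    }
  }
})

test_that("frame-averaged values equal the mean of the model over each frame", {
  inp <- sim_input_function(sim_config())
  sched <- inp$schedule
  avg <- model_curve(2, 2.13, inp, sched, frame_value = "average")
  # brute-force frame means on a dense midpoint-evaluated grid
  for (i in c(3, 10, 20, 26)) {
    tt <- seq(sched$start_s[i], sched$start_s[i] + sched$duration_s[i],
              length.out = 201)
    dense_sched <- frame_schedule(tt[-length(tt)], diff(tt))
    dense <- model_curve(2, 2.13, inp, dense_sched, frame_value = "midpoint")
    expect_equal(avg[i], mean(dense), tolerance = 2e-3)
  }
})

test_that("noise-free fits recover the generating parameters to 0.1%", {
  cfg <- sim_config()
  inp <- sim_input_function(cfg)
  for (r in c("uuo_cortex", "healthy_cortex")) {
    tt <- sim_tissue_tac(cfg, r, inp)
    f <- fit_1tcm(tt, inp, frame_value = "midpoint")
    expect_true(f$converged)
    expect_lt(abs(f$K1 / cfg$tissue_params[[r]]$K1 - 1), 1e-3)
    expect_lt(abs(f$k2 / cfg$tissue_params[[r]]$k2 - 1), 1e-3)
  }
})

test_that("fit handles degenerate and repeated inputs deterministically", {
  cfg <- sim_config(seed = 5)
  inp <- sim_input_function(cfg)
  zero <- tac("empty", inp$schedule, rep(0, nrow(inp$schedule)), TRUE, o15())
  f0 <- fit_1tcm(zero, inp)
  expect_identical(f0$K1, 0)
  expect_true(f0$degenerate)
  noisy <- sim_tissue_tac(cfg, "uuo_cortex", inp, noisy = TRUE)
  f1 <- fit_1tcm(noisy, inp, frame_value = "midpoint")
  f2 <- fit_1tcm(noisy, inp, frame_value = "midpoint")
  expect_identical(f1$K1, f2$K1)
  expect_identical(f1$k2, f2$k2)
  expect_error(fit_1tcm(tac("x", frame_schedule(0, 4), 1, TRUE, o15()), inp),
               "4 frames")
})

test_that("scaling the tissue curve scales fitted K1 proportionally", {
  cfg <- sim_config()
  inp <- sim_input_function(cfg)
  tt <- sim_tissue_tac(cfg, "uuo_cortex", inp)
  for (c_scale in c(0.5, 3)) {
    scaled <- tac(tt$region, tt$schedule, tt$conc_kBq_per_mL * c_scale,
                  TRUE, o15())
    f <- fit_1tcm(scaled, inp, frame_value = "midpoint")
    expect_equal(f$K1, c_scale * 2.00, tolerance = 1e-3)
  }
})

test_that("perfusion_report summarizes groups and recovers generating means", {
  one <- structure(list(region = "cortex", K1 = 2, k2 = 2, delay_s = 0,
                        wrss = 0, converged = TRUE, degenerate = FALSE,
                        n_frames = 26, K1_over_k2 = 1),
                   class = "one_tissue_fit")
  rep1 <- perfusion_report(list(one), "UUO", pairwise_tests = FALSE)
  expect_equal(rep1$summary$mean_K1, 2)
  expect_true(is.na(rep1$summary$sd_K1))
  rep3 <- perfusion_report(list(one, one, one), rep("UUO", 3),
                           pairwise_tests = FALSE)
  expect_equal(rep3$summary$sd_K1, 0)

  # cohort of 6 per group with truths drawn at the reported group levels
  set.seed(314)
  truths <- list(UUO = pmax(rnorm(6, 2.00, 0.95), 0.2),
                 healthy = pmax(rnorm(6, 5.25, 0.55), 0.2))
  inp <- sim_input_function(sim_config())
  fits <- list(); groups <- character()
  for (g in names(truths)) for (k1 in truths[[g]]) {
    cfg <- sim_config()
    cfg$tissue_params$cortex <- list(K1 = k1, k2 = k1 / 0.94)
    tt <- sim_tissue_tac(cfg, "cortex", inp)
    fits[[length(fits) + 1]] <- fit_1tcm(tt, inp, frame_value = "midpoint")
    groups <- c(groups, g)
  }
  rep6 <- perfusion_report(fits, groups)
  for (g in names(truths)) {
    mu <- c(UUO = 2.00, healthy = 5.25)[[g]]
    sem <- c(UUO = 0.95, healthy = 0.55)[[g]] / sqrt(6)
    got <- rep6$summary$mean_K1[rep6$summary$group == g]
    expect_lt(abs(got - mu), 2 * sem)
  }
  expect_true(nrow(rep6$tests) >= 1)
})
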