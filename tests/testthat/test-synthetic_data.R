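test_that("arterial input is zero before the bolus, peaks where configured", {
  cfg <- sim_config()
  inp <- sim_input_function(cfg)
  mids <- inp$schedule$mid_s
  expect_true(all(inp$conc_kBq_per_mL[mids < cfg$input_function_params$bolus_arrival_s] == 0))
  # argmax in the frame containing the configured 20-s peak
  peak_frame <- which.max(inp$conc_kBq_per_mL)
  expect_true(inp$schedule$start_s[peak_frame] <= 20 &&
                20 <= inp$schedule$start_s[peak_frame] +
                      inp$schedule$duration_s[peak_frame])
  # zero amplitude -> all-zero curve
  cfg0 <- sim_config()
  cfg0$input_function_params$peak_amp_kBq_per_mL <- 0
  expect_true(all(sim_input_function(cfg0)$conc_kBq_per_mL == 0))
})

test_that("input-function area matches the closed-form integral", {
  p <- sim_config()$input_function_params
  # fine-grid numerical integral; slowest washout rate 0.002/s makes the
  # contribution beyond 20000 s < 1e-17 of the total
  t <- seq(0, 20000, by = 0.05)
  v <- input_function_value(p, t)
  num <- sum((v[-1] + v[-length(v)]) / 2) * 0.05
  expect_equal(num, input_function_auc(p), tolerance = 0.005)
})

test_that("tissue generator obeys 1TCM limiting cases", {
  cfg <- sim_config()
  cfg$tissue_params$null_region <- list(K1 = 0, k2 = 1)
  inp <- sim_input_function(cfg)
  expect_true(all(sim_tissue_tac(cfg, "null_region", inp)$conc_kBq_per_mL == 0))
  expect_error(sim_tissue_tac(cfg, "no_such_region", inp), "no tissue parameters")
  # constant input, K1 = 2, k2 = 4 per min: plateau at K1/k2 = 0.5
  cfg$tissue_params$plateau <- list(K1 = 2, k2 = 4)
  step <- step_input(1)
  tt <- sim_tissue_tac(cfg, "plateau", step)
  n <- nrow(step$schedule)
  expect_equal(tt$conc_kBq_per_mL[n], 0.5, tolerance = 1e-3)
})

test_that("noise-free tissue TAC matches an independent ODE oracle within 0.1%", {
  cfg <- sim_config()
  inp <- sim_input_function(cfg)
  for (r in names(cfg$tissue_params)) {
    tt <- sim_tissue_tac(cfg, r, inp)
    pars <- cfg$tissue_params[[r]]
    oracle <- ode_1tcm_oracle(pars$K1, pars$k2, inp, inp$schedule$mid_s / 60)
    keep <- oracle > 1e-3 * max(oracle)
    expect_lt(max(abs(tt$conc_kBq_per_mL[keep] / oracle[keep] - 1)), 1e-3)
  }
})

test_that("noisy generation is a pure function of config and seed", {
  cfg <- sim_config(seed = 42)
  inp <- sim_input_function(cfg)
  a <- sim_tissue_tac(cfg, "uuo_cortex", inp, noisy = TRUE)
  b <- sim_tissue_tac(cfg, "uuo_cortex", inp, noisy = TRUE)
  expect_identical(a$conc_kBq_per_mL, b$conc_kBq_per_mL)
  other <- sim_tissue_tac(sim_config(seed = 43), "uuo_cortex", inp, noisy = TRUE)
  expect_false(identical(a$conc_kBq_per_mL, other$conc_kBq_per_mL))
  # noise does not disturb the global RNG stream
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(sim_tissue_tac(cfg, "uuo_cortex", inp, noisy = TRUE))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("organ biokinetics follow uptake-washout-decay form and stay bounded", {
  cfg <- sim_config()
  bio <- sim_organ_biokinetics(cfg)
  tot <- tapply(bio$fraction_of_injected, bio$time_h, sum)
  expect_true(all(tot <= 1 + 1e-12))
  # liver dominates at all positive times
  liv <- bio$fraction_of_injected[bio$organ == "liver"]
  for (o in setdiff(unique(bio$organ), "liver"))
    expect_true(all(liv[-1] > bio$fraction_of_injected[bio$organ == o][-1]))
  # instant uptake, no biological washout -> pure physical decay
  cfg2 <- sim_config()
  cfg2$organ_biokinetics_params$uptake_rate_per_h <- Inf
  cfg2$organ_biokinetics_params$biological_half_life_h <- Inf
  b2 <- sim_organ_biokinetics(cfg2, times_h = c(0, 24, 79.2, 158.4))
  liv2 <- b2[b2$organ == "liver", ]
  u <- cfg2$organ_biokinetics_params$uptake_fractions[["liver"]]
  expect_equal(liv2$fraction_of_injected,
               u * 2^(-liv2$time_h / 79.2), tolerance = 1e-12)
  # all-zero uptake -> all-zero curves
  cfg3 <- sim_config()
  cfg3$organ_biokinetics_params$uptake_fractions[] <- 0
  expect_true(all(sim_organ_biokinetics(cfg3)$fraction_of_injected == 0))
  # fractions summing above 1 are rejected at config time
  expect_error(sim_config(organ_biokinetics_params = list(
    uptake_fractions = c(liver = 0.6, spleen = 0.5),
    uptake_rate_per_h = 1, biological_half_life_h = 100)), "sum")
})

test_that("plasma series starts at dose over central volume and intact at f0", {
  cfg <- sim_config(plasma_params = list(V_central_mL = 100,
                                         fractions = c(0.5, 0.5),
                                         rates_per_h = c(0.1, 0.1),
                                         blood_to_plasma_ratio = 0.6))
  p <- sim_plasma_series(cfg, times_h = c(0, 1, 2))
  expect_equal(p$plasma_kBq_per_mL[1], 7200 / 100)   # 0.072 MBq/mL
  expect_equal(p$intact_pct[1], cfg$intact_fraction_params$initial_pct)
  expect_equal(p$blood_kBq_per_mL / p$plasma_kBq_per_mL, rep(0.6, 3))
})

test_that("intact-fraction fit recovers the generating rate on noise-free data", {
  cfg <- sim_config()
  p <- sim_plasma_series(cfg, times_h = c(4, 24, 48, 72))
  fit <- fit_intact_fraction(c(4, 24, 48, 72), p$intact_pct)
  expect_equal(fit$rate_per_d, cfg$intact_fraction_params$rate_per_d,
               tolerance = 0.005)
  expect_equal(fit$f0_pct, cfg$intact_fraction_params$initial_pct,
               tolerance = 0.005)
})
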