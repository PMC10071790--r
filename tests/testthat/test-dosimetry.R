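test_that("residence time integrates pure physical decay to T1/2 / ln 2", {
  t <- c(0, 4, 24, 48, 72, 168)
  tau <- residence_time(t, exp(-log(2) / 79.2 * t))
  expect_equal(tau, 79.2 / log(2), tolerance = 1e-9)
  expect_equal(residence_time(t, rep(0, 6)), 0)
  # linearity: halving fractions halves tau
  f <- 0.4 * exp(-0.02 * t)
  expect_equal(residence_time(t, f / 2), residence_time(t, f) / 2,
               tolerance = 1e-12)
  expect_error(residence_time(t, exp(-0.01 * t), decay_corrected = TRUE),
               "NOT decay-corrected")
  expect_error(residence_time(t, c(-0.1, 0, 0, 0, 0, 0)), ">= 0")
})

test_that("organ_biokinetics validates fractions and time ordering", {
  ok <- data.frame(organ = "liver", time_h = c(0, 24),
                   fraction_of_injected = c(0.3, 0.2))
  expect_s3_class(organ_biokinetics(ok), "organ_biokinetics")
  bad <- ok; bad$fraction_of_injected <- c(0.3, 1.2)
  expect_error(organ_biokinetics(bad), "\\[0, 1\\]")
  two <- data.frame(organ = rep(c("a", "b"), each = 2),
                    time_h = c(0, 24, 0, 24),
                    fraction_of_injected = c(0.6, 0.5, 0.6, 0.5))
  expect_error(organ_biokinetics(two), "exceeds 1")
})

test_that("rabbit-to-human scaling multiplies by the relative organ-mass ratio", {
  mm <- small_masses()
  d <- data.frame(organ = rep(c("liver", "spleen"), each = 2),
                  time_h = c(0, 24, 0, 24),
                  fraction_of_injected = c(0.30, 0.25, 0.01, 0.008))
  bio <- organ_biokinetics(d)
  # identical relative masses -> unchanged
  same <- phantom_masses("human", mm$rabbit$organ_masses_kg * 28, 70)
  out_same <- scale_rabbit_to_human(bio, mm$rabbit, same)
  expect_equal(out_same$fraction_of_injected, bio$fraction_of_injected)
  # doubling one organ's relative mass doubles its fractions
  dbl <- mm$rabbit$organ_masses_kg * 28
  dbl[["liver"]] <- dbl[["liver"]] * 2
  out_dbl <- scale_rabbit_to_human(bio, mm$rabbit,
                                   phantom_masses("human", dbl, 70))
  expect_equal(out_dbl$fraction_of_injected[out_dbl$organ == "liver"],
               2 * d$fraction_of_injected[d$organ == "liver"])
  expect_error(scale_rabbit_to_human(bio, mm$rabbit,
    phantom_masses("human", c(liver = 1.8), 70)), "missing organ masses")
})

test_that("scaling that overshoots unity renormalizes proportionally", {
  mm <- small_masses()
  d <- data.frame(organ = rep(c("liver", "spleen"), each = 1),
                  time_h = c(0, 0), fraction_of_injected = c(0.4, 0.2))
  # masses making every relative-mass ratio 2: scaling pushes the sum to 1.2
  r <- phantom_masses("rabbit", c(liver = 0.09, spleen = 0.003), 2.5)
  h <- phantom_masses("human", c(liver = 0.09 * 56, spleen = 0.003 * 56), 70)
  bio <- organ_biokinetics(d)
  expect_message(out <- scale_rabbit_to_human(bio, r, h), "renormalizing")
  expect_equal(sum(out$fraction_of_injected), 1)
  expect_equal(out$fraction_of_injected[out$organ == "liver"] /
                 out$fraction_of_injected[out$organ == "spleen"], 2)
})

test_that("remainder completes organ residence times to the physical bound", {
  total <- 79.2 / log(2)
  rt0 <- remainder_and_total(numeric(0))
  expect_equal(rt0$remainder_h, total)
  expect_equal(rt0$total_h, total)
  rt <- remainder_and_total(c(liver = 30, spleen = 40))
  expect_equal(rt$remainder_h, total - 70)
  expect_equal(sum(rt$organ_tau_h) + rt$remainder_h, rt$total_h)
  full <- remainder_and_total(c(body = total))
  expect_equal(full$remainder_h, 0, tolerance = 1e-9)
  expect_error(remainder_and_total(c(a = 80, b = 60)), "above the total")
  # conservation for random organ splits
  set.seed(21)
  for (i in 1:10) {
    taus <- runif(4, 0, total / 4)
    names(taus) <- paste0("o", 1:4)
    r <- remainder_and_total(taus)
    expect_equal(sum(r$organ_tau_h) + r$remainder_h, total, tolerance = 1e-12)
  }
})

test_that("organ doses are the S-weighted sum over sources incl. remainder", {
  one <- s_matrix(data.frame(source = c("liver", "remainder"),
                             target = c("liver", "liver"),
                             mGy_per_MBq_h = c(0.5, 0)))
  rt <- remainder_and_total(c(liver = 10), total_h = 50)
  expect_equal(organ_doses(rt, one)[["liver"]], 5)
  rt0 <- remainder_and_total(c(liver = 0), total_h = 50)
  expect_equal(unname(organ_doses(rt0, one)), 0 + 40 * 0)
  # 3-organ fixture vs explicit matrix-vector product
  set.seed(5)
  orgs <- c("liver", "spleen", "kidneys")
  grid <- expand.grid(source = c(orgs, "remainder"), target = orgs,
                      stringsAsFactors = FALSE)
  grid$mGy_per_MBq_h <- runif(nrow(grid), 0, 0.01)
  for (o in orgs)  # keep self-dose dominant
    grid$mGy_per_MBq_h[grid$source == o & grid$target == o] <- runif(1, 0.5, 1)
  sm <- s_matrix(grid)
  taus <- c(liver = 20, spleen = 5, kidneys = 3)
  rt3 <- remainder_and_total(taus)
  got <- organ_doses(rt3, sm)
  tau_full <- c(taus, remainder = rt3$remainder_h)
  manual <- sm$S[, names(tau_full)] %*% tau_full
  expect_equal(got, drop(manual))
  expect_error(organ_doses(remainder_and_total(c(lungs = 1)), sm),
               "lacks source")
})

test_that("doses are linear in residence times and S entries", {
  set.seed(6)
  orgs <- c("a", "b")
  grid <- expand.grid(source = c(orgs, "remainder"), target = orgs,
                      stringsAsFactors = FALSE)
  grid$mGy_per_MBq_h <- runif(nrow(grid), 0.01, 0.2)
  grid$mGy_per_MBq_h[grid$source == grid$target] <- 1
  sm <- s_matrix(grid)
  taus <- c(a = 8, b = 3)
  base <- organ_doses(remainder_and_total(taus, total_h = 30), sm)
  half <- organ_doses(remainder_and_total(taus / 2, total_h = 15), sm)
  expect_equal(half, base / 2, tolerance = 1e-12)
  grid2 <- grid; grid2$mGy_per_MBq_h <- grid$mGy_per_MBq_h * 3
  tripled <- organ_doses(remainder_and_total(taus, total_h = 30),
                         s_matrix(grid2))
  expect_equal(tripled, base * 3, tolerance = 1e-12)
})

test_that("raising an organ's uptake never lowers its self-dose", {
  mm <- small_masses()
  sm <- s_matrix(expand.grid(source = c("liver", "remainder"),
                             target = "liver",
                             stringsAsFactors = FALSE) |>
                   transform(mGy_per_MBq_h = c(0.3, 0.001)))
  t <- c(0, 24, 72)
  doses <- sapply(c(0.1, 0.2, 0.3), function(u) {
    bio <- organ_biokinetics(data.frame(
      organ = "liver", time_h = t,
      fraction_of_injected = u * exp(-log(2) / 79.2 * t)))
    taus <- residence_times(scale_rabbit_to_human(bio, mm$rabbit, mm$human))
    organ_doses(remainder_and_total(taus), sm)[["liver"]]
  })
  expect_true(all(diff(doses) > 0))
})

test_that("ICRP-103 weighted effective dose is normalized and linear", {
  w <- icrp103_weights()
  expect_equal(sum(w), 1)
  d <- rep(1, length(w)); names(d) <- names(w)
  expect_equal(effective_dose(d), 1)
  set.seed(12)
  d2 <- runif(length(w), 0.1, 5); names(d2) <- names(w)
  expect_equal(effective_dose(2 * d2), 2 * effective_dose(d2),
               tolerance = 1e-12)
  expect_error(effective_dose(unname(d2)), "named")
})

test_that("unmatched organs enter through the remainder mean", {
  doses <- c(liver = 2, lung = 1, muscle = 0.4, skin = 0.1)
  w <- icrp103_weights()
  remainder <- 0.4  # only muscle is outside the named tissue list
  named <- setdiff(names(w), "remainder")
  expected <- sum(sapply(named, function(tn)
    w[[tn]] * if (tn %in% names(doses)) doses[[tn]] else remainder)) +
    w[["remainder"]] * remainder
  expect_equal(effective_dose(doses), expected, tolerance = 1e-12)
})

test_that("administered effective dose follows the coefficient linearly", {
  expect_equal(administered_dose(0.702, 37), 26)
  expect_equal(administered_dose(1, 1), 1)
  expect_equal(administered_dose(0.702, 74), 52)
  expect_equal(administered_dose(0.702, 37, signif_digits = NULL), 25.974)
  expect_error(administered_dose(0, 37), "> 0")
})

test_that("liver-only instant uptake propagates in closed form end to end", {
  mm <- small_masses()
  u <- 0.2
  t <- c(0, 4, 24, 48, 72, 168)
  bio <- organ_biokinetics(data.frame(
    organ = "liver", time_h = t,
    fraction_of_injected = u * exp(-log(2) / 79.2 * t)))
  human <- scale_rabbit_to_human(bio, mm$rabbit, mm$human)
  tau <- residence_times(human)[["liver"]]
  m_ratio <- (1.8 / 70) / (0.09 / 2.5)
  expect_equal(tau, u * m_ratio * 79.2 / log(2), tolerance = 1e-9)
})
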