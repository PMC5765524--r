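# Published fundamental matrices for the three fulmar heterogeneity groups
# (inputs printed to 2 decimals, so entries match within 0.05).
published_N <- list(
  "UH-1" = matrix(c(10.00, 9.03, 2.75, 1.69,
                    0, 9.30, 2.54, 1.63,
                    0, 7.90, 3.61, 1.92,
                    0, 6.66, 2.20, 3.35), 4, 4),
  "UH-2" = matrix(c(11.21, 1.28, 0.37, 0.54,
                    0, 13.08, 3.32, 5.31,
                    0, 11.03, 4.26, 4.93,
                    0, 9.92, 2.91, 5.81), 4, 4),
  "UH-3" = matrix(c(6.25, 8.49, 0.19, 0.43,
                    0, 8.49, 0.19, 0.43,
                    0, 7.19, 1.60, 0.81,
                    0, 6.45, 0.54, 2.11), 4, 4)
)

test_that("single-state geometric chains have closed-form N and V", {
  # self-transition 0.5: expected visits 1/(1-p) = 2, variance p/(1-p)^2 = 2
  expect_equal(fundamental_matrix(matrix(0.5)), matrix(2))
  expect_equal(occupancy_variance(matrix(2)), matrix(2))
  # immediate absorption: one deterministic visit
  expect_equal(fundamental_matrix(matrix(0)), matrix(1))
  expect_equal(occupancy_variance(fundamental_matrix(matrix(0))), matrix(0))
})

test_that("fundamental matrices reproduce the published group matrices", {
  mix <- fulmar_mixture()
  for (g in names(published_N)) {
    N <- fundamental_matrix(mix$chains[[g]])
    expect_lt(max(abs(N - published_N[[g]])), 0.05)
    expect_true(all(N >= 0))
    expect_true(all(diag(N) >= 1))
    expect_equal(unname(N[1, 2:4]), rep(0, 3)) # PB never re-entered
  }
})

test_that("a no-absorption chain fails with an informative error", {
  immortal <- absorbing_chain(flat_rates(sigma = 1, beta = 0.5, gamma = 0.5,
                                         label = "immortal"))
  expect_error(fundamental_matrix(immortal), "immortal")
  expect_error(fundamental_matrix(immortal), "singular")
})

test_that("longevity moments match the published column sums", {
  mix <- fulmar_mixture()
  lon <- longevity(mix$chains[["UH-1"]])
  expect_equal(lon$mean[lon$start == "PB"], sum(published_N[["UH-1"]][, 1]),
               tolerance = 0.005)
  lon2 <- longevity(mix$chains[["UH-2"]])
  expect_equal(lon2$mean[lon2$start == "PB"], sum(published_N[["UH-2"]][, 1]),
               tolerance = 0.005)
  expect_true(all(lon$variance >= 0))
  expect_true(all(lon$prob_event == 1))
})

test_that("deterministic one-step life has longevity 1 with zero variance", {
  dead <- absorbing_chain(flat_rates(sigma = 0))
  lon <- longevity(dead)
  expect_equal(lon$mean, rep(1, 4))
  expect_equal(lon$variance, rep(0, 4))
})

test_that("lifetime reproductive output is occupancy of the S stage", {
  mix <- fulmar_mixture()
  lro2 <- lifetime_output(mix$chains[["UH-2"]])
  expect_equal(lro2$mean[lro2$start == "PB"], 1.28, tolerance = 0.01)
  lro3 <- lifetime_output(mix$chains[["UH-3"]])
  expect_equal(lro3$mean[lro3$start == "PB"], 8.49, tolerance = 0.01)
  # no successful breeding possible -> S never entered, so LRO is 0 from
  # every stage except a (counterfactual) S start, which counts its own
  # current census per the occupancy convention
  sterile <- absorbing_chain(vital_rates(
    c(0.9, 0.9, 0.9, 0.9), c(0.5, 0.5, 0.5, 0.5), rep(0, 4)))
  lro0 <- lifetime_output(sterile)
  expect_equal(lro0$mean[lro0$start %in% c("PB", "F", "NB")], rep(0, 3))
  expect_equal(lro0$mean[lro0$start == "S"], 1)
})

test_that("occupancy variance agrees with a Monte Carlo estimate", {
  mix <- fulmar_mixture()
  V <- occupancy_variance(mix$chains[["UH-1"]])
  one_group <- mixture_model(list(uh1_rates()), 1)
  sim <- simulate_cohort(one_group, n = 3e4, seed = 907)
  mc_var <- var(sim$lro) # years in S from a PB start
  n <- nrow(sim)
  m <- mean(sim$lro)
  se_var <- sqrt((mean((sim$lro - m)^4) - mc_var^2) / n)
  expect_lt(abs(V["S", "PB"] - mc_var), 3 * se_var)
})

test_that("whole-life and adult-life occupancy shares match the published ones", {
  mix <- fulmar_mixture()
  occ2 <- stage_occupancy(mix$chains[["UH-2"]], "PB")
  expect_equal(occ2$proportion[occ2$stage == "PB"], 0.84, tolerance = 0.02)
  occ3 <- stage_occupancy(mix$chains[["UH-3"]], "PB")
  expect_equal(occ3$proportion[occ3$stage == "S"], 0.55, tolerance = 0.02)
  adult3 <- stage_occupancy(mix$chains[["UH-3"]],
                            recruitment_start(mix$chains[["UH-3"]]))
  expect_equal(adult3$proportion[adult3$stage == "S"], 0.93, tolerance = 0.02)
  # proportions always normalize
  for (g in names(mix$chains)) {
    expect_equal(sum(stage_occupancy(mix$chains[[g]], "NB")$proportion), 1)
  }
})
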