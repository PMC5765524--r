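# Published per-group first-passage results (means to one decimal,
# probabilities to two).
published_outcomes <- tibble::tribble(
  ~group, ~outcome,                 ~start, ~prob, ~mean,
  "UH-1", "age_first_reproduction", "PB",   1.00,  10.0,
  "UH-2", "age_first_reproduction", "PB",   0.10,  11.2,
  "UH-3", "age_first_reproduction", "PB",   1.00,   6.2,
  "UH-1", "age_first_success",      "PB",   0.97,  10.3,
  "UH-2", "age_first_success",      "PB",   0.10,  11.7,
  "UH-3", "age_first_success",      "PB",   1.00,   6.25,
  "UH-1", "breeding_interval",      "S",    NA,     1.4,
  "UH-2", "breeding_interval",      "S",    NA,     1.6,
  "UH-3", "breeding_interval",      "S",    NA,     1.1,
  "UH-1", "breeding_interval",      "F",    NA,     1.9,
  "UH-2", "breeding_interval",      "F",    NA,     1.9,
  "UH-3", "breeding_interval",      "F",    NA,     1.8,
  "UH-1", "breeding_interval",      "NB",   NA,     2.6,
  "UH-2", "breeding_interval",      "NB",   NA,     2.2,
  "UH-3", "breeding_interval",      "NB",   NA,     2.2
)

test_that("the outcome table reproduces the published first-passage results", {
  got <- outcome_table(fulmar_mixture())
  merged <- dplyr::inner_join(published_outcomes, got,
                              by = c("group", "outcome", "start"))
  expect_equal(nrow(merged), nrow(published_outcomes))
  expect_true(all(abs(merged$mean.y - merged$mean.x) <= 0.1))
  probs <- merged[!is.na(merged$prob), ]
  expect_true(all(abs(probs$prob_event - probs$prob) <= 0.01))
  expect_false(any(merged$no_path))
  expect_true(all(merged$variance >= 0))
})

test_that("recruitment age has the geometric closed form when juveniles cannot die", {
  # sigma_PB = 1: conditioning is vacuous and age ~ Geometric(beta_PB)
  ch3 <- absorbing_chain(uh3_rates())
  fp <- first_passage(ch3, target = c("S", "F"), start = "PB")
  expect_equal(fp$prob_event, 1)
  expect_equal(fp$mean, 1 / 0.16, tolerance = 1e-12)
  expect_equal(fp$variance, (1 - 0.16) / 0.16^2, tolerance = 1e-10)
})

test_that("a fully absorbing target yields a one-step passage", {
  safe <- absorbing_chain(flat_rates(sigma = 1, beta = 0.3, gamma = 0.5))
  fp <- first_passage(safe, target = c("PB", "S", "F", "NB"), start = "PB")
  expect_equal(fp$prob_event, 1)
  expect_equal(fp$mean, 1)
  expect_equal(fp$variance, 0)
})

test_that("unreachable events are flagged as no-path, never NaN", {
  never_breeds <- absorbing_chain(vital_rates(
    rep(0.9, 4), rep(0, 4), rep(0.5, 4)))
  fp <- first_passage(never_breeds, target = c("S", "F"))
  # no stage can (re-)enter a breeding stage when beta is 0 everywhere
  expect_equal(fp$prob_event, rep(0, 4))
  expect_true(all(fp$no_path))
  expect_false(any(is.nan(fp$mean)))
  expect_true(all(is.na(fp$mean)))
})

test_that("event and death absorption probabilities are complementary", {
  # independent accounting: P(event) + P(death before event) = 1
  set.seed(509)
  for (i in 1:10) {
    r <- random_rates()
    r$sigma <- pmin(r$sigma, 0.98) # keep death reachable
    ch <- absorbing_chain(r)
    U <- ch$U
    tset <- sample(2:4, sample(1:2, 1))
    Umod <- U
    Umod[tset, ] <- 0
    Nmod <- solve(diag(4) - Umod)
    death <- as.vector((1 - colSums(Umod) - colSums(U[tset, , drop = FALSE])) %*% Nmod)
    fp <- first_passage(ch, target = tset)
    expect_equal(fp$prob_event + death, rep(1, 4), tolerance = 1e-10)
  }
})

test_that("conditional moments agree with brute-force enumeration on a tiny chain", {
  # PB survives for sure, breeds w.p. 0.25; enumerate the geometric law
  ch <- absorbing_chain(vital_rates(
    c(1, 0.5, 0.5, 0.5), c(0.25, 1, 1, 1), c(0.6, 0.5, 0.5, 0.5)))
  fp <- first_passage(ch, target = c("S", "F"), start = "PB")
  t_vals <- 1:10000
  p_t <- 0.75^(t_vals - 1) * 0.25
  expect_equal(fp$mean, sum(t_vals * p_t), tolerance = 1e-9)
  expect_equal(fp$variance, sum(t_vals^2 * p_t) - sum(t_vals * p_t)^2,
               tolerance = 1e-6)
})

test_that("breeding intervals distinguish success and attempt targets", {
  ch1 <- absorbing_chain(uh1_rates())
  succ <- breeding_interval(ch1, from = "NB", type = "success")
  att <- breeding_interval(ch1, from = "NB", type = "attempt")
  expect_gt(succ$mean, att$mean) # reaching S takes at least as long as {S,F}
  # certain immediate success: interval exactly one year
  instant <- absorbing_chain(flat_rates(sigma = 1, beta = 1, gamma = 1))
  bi <- breeding_interval(instant)
  expect_equal(bi$mean, rep(1, 3))
  expect_equal(bi$variance, rep(0, 3))
  expect_error(breeding_interval(ch1, from = "PB"), "adult stage")
})
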