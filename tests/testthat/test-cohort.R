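test_that("vec-permutation matrices permute group-major to stage-major", {
  expect_equal(vec_permutation(1, 1), diag(1))
  expect_equal(vec_permutation(1, 3), diag(3))
  expect_equal(vec_permutation(4, 1), diag(4))
  # s = 2, g = 2: only the two middle coordinates swap
  K22 <- vec_permutation(2, 2)
  expect_equal(K22 %*% c(1, 2, 3, 4), matrix(c(1, 3, 2, 4)))
  K <- vec_permutation(4, 3)
  expect_equal(t(K) %*% K, diag(12))
  expect_equal(K %*% t(K), diag(12))
  # index map: group-major (stage i, group k) lands at stage-major slot
  n_gm <- as.vector(outer(1:4, 1:3, function(i, k) 100 * k + i))
  n_sm <- as.vector(K %*% n_gm)
  for (i in 1:4) for (k in 1:3) {
    expect_equal(n_sm[(i - 1) * 3 + k], 100 * k + i)
  }
})

test_that("fixed heterogeneity collapses the projection to the group blocks", {
  mix <- fulmar_mixture()
  bp <- block_projection(mix)
  expect_equal(bp$U_tilde, bp$U_blk)
  blk <- matrix(0, 12, 12)
  for (k in 1:3) {
    blk[(k - 1) * 4 + 1:4, (k - 1) * 4 + 1:4] <- mix$chains[[k]]$U
  }
  expect_equal(bp$U_tilde, blk)
  expect_true(all(colSums(bp$U_tilde) <= 1 + 1e-12))
})

test_that("group-transition blocks act stage-wise through the permutation", {
  mix2 <- mixture_model(list(uh1_rates(), uh2_rates()), c(0.5, 0.5))
  Dmix <- replicate(4, matrix(0.5, 2, 2), simplify = FALSE)
  bp <- block_projection(mix2, D = Dmix)
  # uniform group mixing preserves column sums (survival) but splits each
  # stage's survivors equally between the groups
  expect_equal(colSums(bp$U_tilde), colSums(bp$U_blk))
  U1 <- mix2$chains[[1]]$U
  one_step <- bp$U_tilde %*% c(1, rep(0, 7))
  expect_equal(one_step[1:4] + one_step[5:8], as.vector(U1[, 1]))
  expect_equal(one_step[1:4], one_step[5:8])
  expect_error(block_projection(mix2, D = replicate(4, matrix(0.7, 2, 2),
                                                    simplify = FALSE)),
               "column-stochastic")
})

test_that("projection starts at the mixing distribution and attrits", {
  mix <- fulmar_mixture()
  traj <- project_cohort(mix, horizon = 100)
  comp <- cohort_composition(traj)
  shares0 <- dplyr::filter(comp, t == 0, unit == "group")
  expect_equal(shares0$share[match(names(mix$mixing), shares0$name)],
               unname(mix$mixing))
  surv <- dplyr::distinct(dplyr::filter(comp, unit == "group"),
                          t, survivorship)$survivorship
  expect_true(all(diff(surv) <= 1e-12)) # pure attrition, never increases
  expect_equal(surv[1], 1)
})

test_that("intra-cohort selection first dilutes then fixes the frail-juvenile group", {
  mix <- fulmar_mixture()
  traj <- project_cohort(mix, horizon = 300)
  comp <- cohort_composition(traj)
  uh2 <- dplyr::filter(comp, unit == "group", name == "UH-2")
  expect_lt(min(uh2$share, na.rm = TRUE), 0.67)    # initial dip
  expect_gt(uh2$share[uh2$t == 100], 0.67)         # reversal under way
  expect_gt(uh2$share[uh2$t == 300], 0.99)         # asymptotic fixation
})

test_that("about a tenth of a percent of the cohort reaches age 100", {
  traj <- project_cohort(fulmar_mixture(), horizon = 100)
  comp <- cohort_composition(traj)
  s100 <- dplyr::filter(comp, t == 100, unit == "group")$survivorship[1]
  expect_gt(s100, 0.0005)
  expect_lt(s100, 0.005)
})

test_that("mixed projection equals groupwise projection under fixed heterogeneity", {
  mix <- fulmar_mixture()
  traj <- project_cohort(mix, horizon = 25)
  for (k in seq_along(mix$chains)) {
    lone <- mixture_model(mix$chains[k], 1)
    n0 <- matrix(0, 4, 1)
    n0[1, 1] <- mix$mixing[k]
    sub <- project_cohort(lone, n0 = n0, horizon = 25)
    got <- dplyr::filter(as_tibble(traj), group == names(mix$chains)[k])
    expect_equal(got$abundance, sub$abundance, tolerance = 1e-12)
  }
})

test_that("degenerate projections behave", {
  mix <- fulmar_mixture()
  traj0 <- project_cohort(mix, horizon = 0)
  expect_equal(unique(traj0$t), 0)
  # single-group mixture: shares identically 1 while anyone is alive
  lone <- mixture_model(list(uh3_rates()), 1)
  comp <- cohort_composition(project_cohort(lone, horizon = 10))
  expect_equal(dplyr::filter(comp, unit == "group")$share, rep(1, 11))
  # instant extinction: shares flagged undefined, not NaN
  doomed <- mixture_model(list(flat_rates(sigma = 0)), 1)
  compd <- cohort_composition(project_cohort(doomed, horizon = 3))
  late <- dplyr::filter(compd, t >= 1)
  expect_true(all(!late$alive))
  expect_true(all(is.na(late$share)))
  expect_false(any(is.nan(late$share)))
})
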