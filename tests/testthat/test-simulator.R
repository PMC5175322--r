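test_that("rate containers validate their domain", {
  expect_error(epimutation_rates(-0.1, 0.2), "\\[0, 1\\]")
  expect_error(epimutation_rates(0.6, 0.5), "< 1")
  expect_error(
    stationary_methylated_fraction(epimutation_rates(0, 0)),
    "undefined"
  )
  expect_equal(
    stationary_methylated_fraction(epimutation_rates(1e-4, 3e-4)), 0.25
  )
})

test_that("stationary sampling matches the equilibrium fraction", {
  sym <- stationary_state_sample(epimutation_rates(2e-3, 2e-3), 5e4,
                                 seed = 1)
  expect_lt(abs(mean(sym) - 0.5), 3 * sqrt(0.25 / 5e4))
  all_m <- stationary_state_sample(epimutation_rates(1e-3, 0), 100,
                                   seed = 1)
  expect_true(all(all_m))
  # genome-wide rates: about 29% methylated at equilibrium
  gw <- stationary_state_sample(athaliana_rates("genome"), 1e6, seed = 2)
  pm <- stationary_methylated_fraction(athaliana_rates("genome"))
  expect_lt(abs(mean(gw) - pm), 3 * sqrt(pm * (1 - pm) / 1e6))
})

test_that("pedigrees with zero rates never change, and seeds reproduce", {
  founder <- rep(c(TRUE, FALSE), 50)
  ped <- simulate_ma_pedigree(epimutation_rates(0, 0), n_sites = 100,
                              n_lines = 2, n_generations = 5,
                              founder = founder, seed = 1)
  for (traj in ped$lines) {
    expect_true(all(traj == founder))
  }
  r <- epimutation_rates(0.01, 0.02)
  p1 <- simulate_ma_pedigree(r, 500, 2, 10, seed = 42)
  p2 <- simulate_ma_pedigree(r, 500, 2, 10, seed = 42)
  expect_identical(p1$lines, p2$lines)
  p3 <- simulate_ma_pedigree(r, 500, 2, 10, seed = 43)
  expect_false(identical(p1$lines, p3$lines))
})

test_that("single-generation gains follow the binomial expectation", {
  mu <- 2.56e-4
  ped <- simulate_ma_pedigree(epimutation_rates(mu, 6.3e-4),
                              n_sites = 1e6, n_lines = 1,
                              n_generations = 1, founder = "all-U",
                              seed = 7)
  gains <- sum(ped$lines[[1]][, 2])
  expect_lt(abs(gains - 1e6 * mu), 3 * sqrt(1e6 * mu * (1 - mu)))
})

test_that("endpoint divergence matches the closed-form curve", {
  rates <- athaliana_rates("genome")
  for (t in c(10, 30)) {
    ped <- simulate_ma_pedigree(rates, n_sites = 2e5, n_lines = 2,
                                n_generations = t, seed = 100 + t,
                                keep = "endpoint")
    obs <- mean(ped$lines[[1]] != ped$lines[[2]])
    d <- divergence_curve(rates, t)
    expect_lt(abs(obs - d), 3 * sqrt(d * (1 - d) / 2e5))
  }
})

test_that("methylation converges to equilibrium from any founder", {
  r <- epimutation_rates(0.01, 0.02)
  pm <- stationary_methylated_fraction(r)
  lambda <- 1 - r$mu_UM - r$mu_MU
  for (founder in c("all-M", "all-U")) {
    ped <- simulate_ma_pedigree(r, n_sites = 5e4, n_lines = 1,
                                n_generations = 150,
                                founder = founder, seed = 11)
    traj_mean <- colMeans(ped$lines[[1]])
    p0 <- traj_mean[1]
    # relaxation toward pm at rate lambda^t
    for (t in c(50, 150)) {
      expected <- pm + (p0 - pm) * lambda^t
      expect_lt(abs(traj_mean[t + 1] - expected), 0.01)
    }
  }
})

test_that("transition counting recovers rates with correct arithmetic", {
  # hand-built trajectory over 3 generation intervals (TRUE = M):
  # site 1: U U M M -> 1 gain  / U opportunities 2, M opportunities 1
  # site 2: M U M U -> 1 gain, 2 losses / U opp. 1, M opp. 2
  traj <- rbind(
    c(FALSE, FALSE, TRUE, TRUE),
    c(TRUE, FALSE, TRUE, FALSE)
  )
  ped <- structure(
    list(founder = traj[, 1], lines = list(line_1 = traj),
         rates = NULL, n_generations = 3, seed = NULL,
         keep = "trajectory"),
    class = "ma_pedigree"
  )
  est <- estimate_rates_from_pedigree(ped)
  gains <- est[est$direction == "gain", ]
  losses <- est[est$direction == "loss", ]
  expect_equal(gains$n_transitions, 2)
  expect_equal(gains$n_opportunities, 3)
  expect_equal(gains$rate, 2 / 3)
  expect_equal(losses$n_transitions, 2)
  expect_equal(losses$n_opportunities, 3)
  expect_equal(losses$rate, 2 / 3)
})

test_that("no observed transitions still yields a finite upper bound", {
  traj <- matrix(TRUE, 10, 3) # all M, no transitions
  ped <- structure(
    list(founder = traj[, 1], lines = list(line_1 = traj),
         rates = NULL, n_generations = 2, seed = NULL,
         keep = "trajectory"),
    class = "ma_pedigree"
  )
  expect_warning(est <- estimate_rates_from_pedigree(ped), "undefined")
  losses <- est[est$direction == "loss", ]
  expect_equal(losses$rate, 0)
  expect_true(is.finite(losses$upper95) && losses$upper95 > 0)
  gains <- est[est$direction == "gain", ]
  expect_false(gains$defined)
})

test_that("simulated pedigree rates fall within three standard errors", {
  rates <- athaliana_rates("genome")
  ped <- simulate_ma_pedigree(rates, n_sites = 3e5, n_lines = 2,
                              n_generations = 30, seed = 13)
  est <- estimate_rates_from_pedigree(ped)
  gain <- est[est$direction == "gain", ]
  loss <- est[est$direction == "loss", ]
  expect_lt(abs(gain$rate - rates$mu_UM), 3 * gain$se)
  expect_lt(abs(loss$rate - rates$mu_MU), 3 * loss$se)
})

test_that("the divergence curve is exact against matrix-power enumeration", {
  rates <- epimutation_rates(3e-3, 7e-3)
  P <- matrix(c(1 - rates$mu_UM, rates$mu_UM,
                rates$mu_MU, 1 - rates$mu_MU), 2, 2, byrow = TRUE)
  pi_u <- 1 - stationary_methylated_fraction(rates)
  pi_vec <- c(pi_u, 1 - pi_u)
  for (t in c(0, 1, 5, 25, 200)) {
    Pt <- diag(2)
    for (i in seq_len(t)) Pt <- Pt %*% P
    exact <- sum(pi_vec * 2 * Pt[, 1] * Pt[, 2])
    expect_equal(divergence_curve(rates, t), exact, tolerance = 1e-12)
  }
})

test_that("the divergence curve saturates monotonically", {
  rates <- athaliana_rates("genome")
  t <- c(0, 1, 10, 100, 1000, 1e5)
  d <- divergence_curve(rates, t)
  expect_equal(d[1], 0)
  expect_true(all(diff(d) > 0))
  pm <- stationary_methylated_fraction(rates)
  asymptote <- 2 * pm * (1 - pm)
  expect_true(all(d <= asymptote))
  expect_equal(divergence_curve(rates, 1e7), asymptote, tolerance = 1e-6)
})

test_that("regional predictions mix annotation-specific divergences", {
  profile <- tibble::tibble(
    chrom = "chr1", start = c(0, 1e6, 2e6), end = c(1e6, 2e6, 3e6),
    gene_density = c(1, 0, 0.5), te_density = c(0, 1, 0.5)
  )
  track <- predict_regional_diversity(profile, t = 30)
  expect_gt(track$diversity[1], track$diversity[2]) # genes > TEs
  flat <- predict_regional_diversity(profile[c(3, 3), ], t = 30)
  expect_equal(flat$diversity[1], flat$diversity[2])
  zero <- predict_regional_diversity(profile, t = 0)
  expect_equal(zero$diversity, rep(0, 3))
})

test_that("Wright-Fisher dynamics respect absorbing and selective regimes", {
  none <- epimutation_rates(0, 0)
  wf0 <- simulate_wright_fisher(none, N = 20, s = 0, n_sample = 10,
                                n_sites = 50, burn_in = 50,
                                init_freq_u = 0, seed = 1)
  expect_true(all(wf0$b == 0))
  wf1 <- simulate_wright_fisher(none, N = 20, s = 0, n_sample = 10,
                                n_sites = 50, burn_in = 50,
                                init_freq_u = 1, seed = 1)
  expect_true(all(wf1$b == 10))
  # positive selection on U raises the sampled U frequency
  r <- epimutation_rates(0.02, 0.02)
  neutral <- simulate_wright_fisher(r, N = 100, s = 0, n_sample = 10,
                                    n_sites = 5000, seed = 2)
  selected <- simulate_wright_fisher(r, N = 100, s = 0.2, n_sample = 10,
                                     n_sites = 5000, seed = 2)
  expect_gt(mean(selected$b), mean(neutral$b))
  expect_error(simulate_wright_fisher(r, N = 20, s = -1.5), "positive")
})

test_that("neutral symmetric Wright-Fisher spectra are symmetric", {
  r <- epimutation_rates(0.02, 0.02)
  wf <- simulate_wright_fisher(r, N = 50, s = 0, n_sample = 6,
                               n_sites = 3e4, seed = 3)
  emp <- tabulate(wf$b + 1L, nbins = 7) / nrow(wf)
  expect_lt(max(abs(emp - rev(emp))), 0.02)
})

test_that("direct mSFS draws follow the multinomial law", {
  pars <- pop_params(alpha = 0.5, r = 2)
  # n = 2: everything lands in the single class
  s2 <- simulate_msfs_counts(pars, n = 2, n_sites = 500, seed = 1)
  expect_equal(msfs_counts(s2), 500)
  # determinism
  expect_equal(
    msfs_counts(simulate_msfs_counts(pars, n = 8, n_sites = 1e4, seed = 9)),
    msfs_counts(simulate_msfs_counts(pars, n = 8, n_sites = 1e4, seed = 9))
  )
  # chi-square goodness of fit at the 1% level over 100 replicates:
  # with a correct generator about 1 rejection is expected; allow 5
  q <- conditional_msfs(pars, n = 10)$q[2:10]
  rejections <- 0
  for (i in 1:100) {
    sfs <- simulate_msfs_counts(pars, n = 10, n_sites = 5000,
                                seed = 4000 + i)
    pval <- suppressWarnings(
      stats::chisq.test(msfs_counts(sfs), p = q)$p.value
    )
    if (pval < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 5)
})

test_that("simulated call panels reduce to their true states", {
  pars <- pop_params(alpha = 0.3, r = 3)
  sim <- simulate_call_matrix(pars, n_accessions = 6, n_sites = 800,
                              mean_coverage = 200,
                              coverage_dispersion = 1e6,
                              missing_rate = 0, level_m = 1, level_u = 0,
                              seed = 12)
  calls <- purrr::map(sim$calls, binarize_calls)
  mat <- assemble_call_matrix(calls, policy = "intersection")
  expect_equal(meth_states(mat), meth_states(sim$truth))
  # monomorphic fraction near its model probability
  p <- sampling_probability(pars, 6)
  mono_expected <- p[1] + p[7]
  b <- rowSums(meth_states(sim$truth) == "U")
  mono_obs <- mean(b == 0 | b == 6)
  expect_lt(abs(mono_obs - mono_expected),
            3 * sqrt(mono_expected * (1 - mono_expected) / 800))
})

test_that("an end-to-end simulated panel recovers the bias parameter", {
  pars <- pop_params(alpha = 0.3, r = 3.43)
  sim <- simulate_call_matrix(pars, n_accessions = 24, n_sites = 4e4,
                              missing_rate = 0.03, seed = 20)
  calls <- purrr::map(sim$calls, binarize_calls)
  mat <- assemble_call_matrix(calls, policy = "intersection")
  fit <- fit_msfs(build_msfs(mat))
  # the neutral-constrained estimate is sharp even through coverage noise,
  # binarization and missing-data intersection
  expect_lt(abs(fit$neutral$params$r - pars$r) / pars$r, 0.10)
  # and the sigma-free fit finds no strong selection signal
  expect_lt(fit$delta_loglik, qchisq(0.999, 1) / 2)
})
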