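neutral_folded <- function(n) {
  e <- vapply(1:(n - 1), function(i) 1 / i, numeric(1))
  nb <- floor(n / 2)
  vapply(seq_len(nb), function(i) if (i < n - i) e[i] + e[n - i] else e[i],
         numeric(1))
}

test_that("the neutral equilibrium expectation matches the coalescent closed form", {
  e <- expected_folded_sfs(demography(), s = 0, n = 16)[-1]
  want <- neutral_folded(16)
  rel <- abs(e / sum(e) - want / sum(want)) / (want / sum(want))
  expect_lt(max(rel), 0.01)
  # odd sample size too
  e15 <- expected_folded_sfs(demography(), s = 0, n = 15)[-1]
  want15 <- neutral_folded(15)
  expect_lt(max(abs(e15 / sum(e15) - want15 / sum(want15)) /
                  (want15 / sum(want15))), 0.01)
})

test_that("strong selection suppresses segregating mass", {
  e0 <- expected_folded_sfs(demography(), s = 0, n = 16)[-1]
  es <- expected_folded_sfs(demography(), s = -10, n = 16)[-1]  # Nes = 1000
  expect_lt(sum(es) / sum(e0), 0.01)
})

test_that("a zero-length second epoch is the single-epoch model", {
  for (nu in c(0.5, 2, 5)) {
    expect_equal(expected_folded_sfs(demography(nu, 0), 0, 16),
                 expected_folded_sfs(demography(), 0, 16))
  }
  # very long second epochs converge to the rescaled equilibrium
  e_long <- expected_folded_sfs(demography(2, 5000), 0, 16)[-1]
  e_eq2 <- 2 * expected_folded_sfs(demography(), 0, 16)[-1]
  expect_lt(max(abs(e_long - e_eq2) / e_eq2), 0.05)
})

test_that("the neutral limit of the selected expectation is the neutral SFS", {
  e0 <- expected_folded_sfs(demography(), s = 0, n = 16)[-1]
  e_small <- expected_folded_sfs(demography(), s = -1e-9, n = 16)[-1]
  expect_lt(max(abs(e_small - e0) / e0), 1e-3)
})

test_that("bin 0 absorbs the non-segregating mass", {
  e <- expected_folded_sfs(demography(), 0, 16, mut_scale = 100,
                           total_sites = 1e4)
  expect_equal(sum(e), 1e4)
  expect_equal(unname(e[1]), 1e4 - sum(e[-1]))
  expect_error(expected_folded_sfs(demography(), NaN, 16), "non-finite")
})

test_that("demography recovery: equilibrium data fit as equilibrium-like", {
  tr <- ground_truth(small_config(seed = 1))          # N2_ratio 1, t2 0
  sim <- simulate_fsfs_pair(tr, 1e4, 2e5, 16, seed = 5)
  dm <- fit_neutral(sim$fsfs4)
  e_fit <- expected_folded_sfs(dm, 0, 16, dm$lambda4, sum(sim$fsfs4$bins))
  e_eq <- expected_folded_sfs(demography(), 0, 16,
                              sum(sim$fsfs4$bins[-1]) /
                                sum(neutral_folded(16)),
                              sum(sim$fsfs4$bins))
  # fitted spectrum stays close to the true equilibrium shape
  expect_lt(max(abs(e_fit[-1] - e_eq[-1]) / e_eq[-1]), 0.15)
  expect_true(dm$converged)
})

test_that("an expansion is detected by likelihood against equilibrium", {
  tr <- ground_truth(small_config(seed = 1), N2_ratio = 2, t2 = 100)
  sim <- simulate_fsfs_pair(tr, 1e4, 2e5, 16, seed = 6)
  dm <- fit_neutral(sim$fsfs4)
  expect_gt(dm$nu, 1)
  # equilibrium profile fit for comparison
  obs <- sim$fsfs4$bins
  lam_eq <- sum(obs[-1]) / sum(neutral_folded(16))
  e_eq <- expected_folded_sfs(demography(), 0, 16, lam_eq, sum(obs))
  ll_eq <- sum(dpois(obs, pmax(e_eq, 1e-12), log = TRUE))
  expect_gt(dm$logL, ll_eq)
})

test_that("no segregating sites yields a flagged boundary fit", {
  f <- folded_sfs(16, c(500, rep(0, 8)))
  expect_warning(dm <- fit_neutral(f), "unidentifiable")
  expect_false(dm$converged)
  expect_equal(dm$lambda4, 0)
})

test_that("gamma class proportions match the closed forms", {
  p <- gamma_class_proportions(1, 1)    # exponential with mean 1
  expect_equal(unname(p["0-1"]), 1 - exp(-1), tolerance = 1e-9)
  expect_equal(unname(p[">100"]), exp(-100), tolerance = 1e-9)
  expect_equal(sum(p), 1)
  # proportions always sum to one
  withr::with_seed(11, {
    for (r in 1:50) {
      expect_equal(sum(gamma_class_proportions(runif(1, 0.05, 5),
                                               exp(runif(1, -3, 8)))), 1)
    }
  })
  # mean Nes -> infinity pushes all mass beyond 100
  expect_gt(gamma_class_proportions(1, 1e7)[">100"], 0.999)
  # agreement with direct numerical integration of the gamma density
  beta <- 0.4; mn <- 25
  dens <- function(x) stats::dgamma(x, shape = beta, scale = mn / beta)
  num <- c(stats::integrate(dens, 0, 1)$value,
           stats::integrate(dens, 1, 10)$value,
           stats::integrate(dens, 10, 100)$value)
  num <- c(num, 1 - sum(num))
  expect_equal(unname(gamma_class_proportions(beta, mn)), num,
               tolerance = 1e-6)
})

test_that("likelihood is invariant to a consistent rescaling of the problem", {
  tr <- ground_truth(small_config(seed = 1), beta = 0.5, Es = 0.2)
  sim <- simulate_fsfs_pair(tr, 2e4, 2e4, 16, seed = 8)
  dm <- fit_neutral(sim$fsfs4)
  d1 <- fit_selected(sim$fsfs0, dm)
  # doubling all bins and the site totals doubles the expectations; the fitted
  # shape parameters are unchanged
  f2 <- folded_sfs(16, 2 * sim$fsfs0$bins)
  g2 <- folded_sfs(16, 2 * sim$fsfs4$bins)
  dm2 <- fit_neutral(g2)
  d2 <- fit_selected(f2, dm2)
  expect_equal(d2$beta, d1$beta, tolerance = 0.1)
  expect_equal(d2$lambda0, 2 * d1$lambda0, tolerance = 0.1)
})

test_that("DFE fits recover beta on simulator output", {
  tr <- ground_truth(small_config(seed = 1), beta = 0.5, Es = 0.5)  # Nes 50
  betas <- vapply(1:5, function(r) {
    sim <- simulate_fsfs_pair(tr, 1e5, 1e5, 16, seed = 300 + r)
    fit_selected(sim$fsfs0, fit_neutral(sim$fsfs4))$beta
  }, numeric(1))
  expect_lt(abs(median(betas) - 0.5), 0.15)
})

test_that("neutral 0-fold data land in the nearly-neutral class", {
  tr <- ground_truth(small_config(seed = 1), beta = 0.5, Es = 1e-9)
  sim <- simulate_fsfs_pair(tr, 1e5, 1e5, 16, seed = 77)
  dfe <- fit_selected(sim$fsfs0, fit_neutral(sim$fsfs4))
  expect_gt(nes_class_proportions(dfe)["0-1"], 0.95)
})

test_that("fits are deterministic and identical inputs give identical fits", {
  tr <- ground_truth(small_config(seed = 1), beta = 0.3, Es = 0.3)
  sim <- simulate_fsfs_pair(tr, 2e4, 2e4, 16, seed = 15)
  dm_a <- fit_neutral(sim$fsfs4); dm_b <- fit_neutral(sim$fsfs4)
  expect_identical(dm_a[c("nu", "t2", "lambda4", "logL")],
                   dm_b[c("nu", "t2", "lambda4", "logL")])
  fa <- fit_selected(sim$fsfs0, dm_a); fb <- fit_selected(sim$fsfs0, dm_b)
  expect_identical(fa[c("beta", "Es", "logL")], fb[c("beta", "Es", "logL")])
})

test_that("run_replicates returns one fit per replicate and shrinking SEs", {
  tr <- ground_truth(small_config(seed = 1), beta = 0.5, Es = 0.3)
  mk <- function(reps, L)
    lapply(seq_len(reps), function(r)
      simulate_fsfs_pair(tr, L, L, 16, seed = 1000 + r))
  sims <- mk(8, 2e4)
  rr <- run_replicates(lapply(sims, `[[`, "fsfs0"),
                       lapply(sims, `[[`, "fsfs4"))
  expect_equal(nrow(rr$fits), 8)
  expect_equal(length(rr$beta) + rr$n_failed, 8)
  expect_true(all(rr$class_summary$mean >= 0))
  expect_equal(sum(rr$class_summary$mean), 1, tolerance = 1e-6)
  # identical replicate inputs give identical fits
  rr2 <- run_replicates(lapply(sims, `[[`, "fsfs0"),
                        lapply(sims, `[[`, "fsfs4"))
  expect_identical(rr$fits, rr2$fits)
})
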