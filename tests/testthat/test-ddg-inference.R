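test_that("occupancy follows the logistic closed forms", {
  em <- randomAnchoredEM(4L, 2L)
  canonical <- paste(anchors(em), collapse = "")
  expect_equal(predictOccupancy(em, 0, canonical), 0.5)    # E = mu
  expect_equal(predictOccupancy(em, 30, canonical), 1, tolerance = 1e-9)
  ## E - mu = ln 3 -> occupancy 1/4
  expect_equal(predictOccupancy(em, -log(3), canonical), 0.25)
})

test_that("z-score prediction is the linear scaling of occupancy", {
  em <- randomAnchoredEM(5L, 3L)
  canonical <- paste(anchors(em), collapse = "")
  pars <- BindingModelParams(mu = 50, a = 2, b = 20)
  expect_equal(predictZscores(em, pars, canonical), 20, tolerance = 1e-6)
  pars0 <- BindingModelParams(mu = -50, a = 2, b = 20)
  expect_equal(predictZscores(em, pars0, canonical), 2, tolerance = 1e-6)
  ## monotone decreasing in site energy
  bf <- bruteForceSiteEnergies(em)
  ord <- order(bf$ddg)
  z <- predictZscores(em, BindingModelParams(1, 0, 30),
                      bf$sequence[ord])
  expect_true(all(diff(z) <= 1e-12))
})

test_that("zero-noise simulated z-scores are reproduced exactly", {
  prot <- TALEProtein(c("NI", "HD", "NN", "NG", "NI", "HD"))
  em <- truthEM(prot, truthContextModel(noise_sd = 0))
  ps <- probeEntries(dinucSubstitutionProbes(canonicalTargetSite(prot)))
  pars <- BindingModelParams(1, 0, 30)
  z <- predictZscores(em, pars, ps$site_sequence)
  occ <- vapply(ps$site_sequence, function(s)
    predictOccupancy(em, 1, s), numeric(1L))
  expect_equal(unname(z), unname(0 + 30 * occ), tolerance = 1e-12)
})

test_that("gauge shifts of the matrix are absorbed by the chemical potential", {
  em <- randomAnchoredEM(6L, 4L)
  shift <- runif(6L, -1, 1)
  em2 <- EnergyMatrix(sweep(as.matrix(em), 2L, shift, "+"), anchors(em))
  sites <- bruteForceSiteEnergies(em)$sequence[1:50]
  z1 <- predictZscores(em, BindingModelParams(1, 0, 30), sites)
  z2 <- predictZscores(em2, BindingModelParams(1 + sum(shift), 0, 30),
                       sites)
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("fitScaling recovers exact parameters and flags broken pairings", {
  prot <- TALEProtein(c("NI", "HD", "NN", "NG", "NI", "HD", "NN"))
  em <- truthEM(prot, truthContextModel(noise_sd = 0))
  ps <- probeEntries(dinucSubstitutionProbes(canonicalTargetSite(prot)))
  z <- predictZscores(em, BindingModelParams(0.7, 1.5, 25),
                      ps$site_sequence)
  fit <- fitScaling(em, ps$site_sequence, z)
  expect_equal(fit$params@mu, 0.7, tolerance = 1e-4)
  expect_equal(fit$params@a, 1.5, tolerance = 1e-4)
  expect_equal(fit$params@b, 25, tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_gt(fit$params@b, fit$params@a)
  ## 5% noise on 200 probes spanning the occupancy curve still
  ## explains >= 95% of the variance
  em6 <- randomAnchoredEM(6L, 33L)
  bf <- bruteForceSiteEnergies(em6)
  ## pick sites whose energies spread evenly across the occupancy curve
  targets <- 1 - log(seq(0.5, 29.5, length.out = 200L) / 30 /
                       (1 - seq(0.5, 29.5, length.out = 200L) / 30))
  idx <- vapply(targets, function(t) which.min(abs(bf$ddg - t)), 1L)
  pars <- BindingModelParams(1, 0, 30)
  z200 <- predictZscores(em6, pars, bf$sequence[idx])
  set.seed(31)
  zn <- z200 + rnorm(200L, 0, 0.05 * 30)
  fit2 <- fitScaling(em6, bf$sequence[idx], zn)
  expect_gte(fit2$r_squared, 0.95)
  expect_equal(fit2$params@mu, 1, tolerance = 0.15)
  ## permuted pairing carries no signal
  set.seed(32)
  fit3 <- fitScaling(em6, bf$sequence[idx], sample(z200))
  expect_lt(fit3$r_squared, 0.2)
  expect_error(fitScaling(em, rep(canonicalTargetSite(prot), 5L),
                          rep(1, 5L)), "distinct")
})

test_that("split-Rhat distinguishes converged from shifted chains", {
  set.seed(41)
  iid <- lapply(1:4, function(i) matrix(rnorm(2000L), ncol = 1L))
  expect_lt(checkConvergence(iid)[1L], 1.01)
  shifted <- lapply(1:4, function(i)
    matrix(rnorm(2000L, mean = i * 5), ncol = 1L))
  expect_gt(checkConvergence(shifted)[1L], 1.05)
  constant <- lapply(1:4, function(i) matrix(1, 100L, 1L))
  expect_true(is.na(checkConvergence(constant)[1L]))
  expect_error(checkConvergence(iid[1L]), ">= 2 chains")
})

test_that("a probe set missing coverage for a position is rejected", {
  prot <- TALEProtein(c("NI", "HD", "NN"))
  ps <- probeEntries(dinucSubstitutionProbes(canonicalTargetSite(prot)))
  keep <- !grepl("^2(,|$)|,2$", ps$mutated_positions)  # drop position 2
  probes <- data.frame(site_sequence = ps$site_sequence[keep],
                       zscore = rnorm(sum(keep)))
  expect_error(fitDdgPosterior(prot, probes, method = "map"),
               "position.*2")
})

test_that("MAP fit recovers a known matrix from low-noise data", {
  prot <- TALEProtein(c("NI", "HD", "NN", "NG", "NI", "HD"))
  truth <- truthContextModel(noise_sd = 0)
  em <- truthEM(prot, truth)
  cfg <- simulationConfig(z_noise_sd = 0.1, outlier_rate = 0, seed = 8L)
  probes <- simulatedProbeZ(prot, em, cfg)
  fit <- fitDdgPosterior(prot, probes, method = "map")
  expect_s4_class(fit, "PosteriorEM")
  tm <- as.matrix(em)
  fm <- as.matrix(posteriorMeanEM(fit))
  nz <- tm != 0
  expect_lt(sqrt(mean((fm[nz] - tm[nz])^2)), 0.2)
  expect_true(isAnchored(posteriorMeanEM(fit)))
  expect_identical(fit@method, "map")
  ## Laplace intervals bracket the estimate
  expect_true(all(fit@ci_lower <= fm + 1e-9))
  expect_true(all(fit@ci_upper >= fm - 1e-9))
})

test_that("constant z-scores yield a flagged, wide fit rather than a crash", {
  prot <- TALEProtein(c("NI", "HD", "NN"))
  ps <- probeEntries(dinucSubstitutionProbes(canonicalTargetSite(prot)))
  probes <- data.frame(site_sequence = ps$site_sequence,
                       zscore = rep(5, nrow(ps)))
  fit <- fitDdgPosterior(prot, probes, method = "map")
  nz <- as.matrix(posteriorMeanEM(fit)) != 0 |
    (fit@ci_upper - fit@ci_lower) > 0
  expect_true(mean((fit@ci_upper - fit@ci_lower)[nz]) > 1)
})

test_that("two MCMC seeds agree within Monte-Carlo error on a small protein", {
  prot <- TALEProtein(c("NI", "HD", "NN", "NG", "HD"))
  truth <- truthContextModel(noise_sd = 0)
  em <- truthEM(prot, truth)
  cfg <- simulationConfig(seed = 17L)
  probes <- simulatedProbeZ(prot, em, cfg)
  f1 <- fitDdgPosterior(prot, probes,
                        ddgFitConfig(burn_in = 800L, samples = 800L,
                                     seed = 1L))
  f2 <- fitDdgPosterior(prot, probes,
                        ddgFitConfig(burn_in = 800L, samples = 800L,
                                     seed = 2L))
  expect_true(all(f1@rhat < 1.1, na.rm = TRUE))
  m1 <- as.matrix(posteriorMeanEM(f1))
  m2 <- as.matrix(posteriorMeanEM(f2))
  ## Monte-Carlo error scale: posterior sd over an effective sample
  ## size of ~25 draws per ensemble (walkers are correlated)
  mcse <- (f1@ci_upper - f1@ci_lower) / (2 * 1.96) / sqrt(25)
  nz <- as.matrix(em) != 0
  expect_true(all(abs(m1[nz] - m2[nz]) < 3 * pmax(mcse[nz], 0.03)))
  ## credible intervals bracket the posterior means
  expect_true(all(f1@ci_lower[nz] <= m1[nz] & m1[nz] <= f1@ci_upper[nz]))
})
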