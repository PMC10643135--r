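vGrid <- seq(-2, 2, by = 0.005)

test_that("degenerate doublet collapses to one line at the isomer shift", {
  sp <- simulateMossbauer(mossbauerDoublet(0.3, 0), vGrid)
  expect_equal(sp@axis[which.min(sp@ordinate)], 0.3, tolerance = 0.005)
  # symmetric about delta: y(0.3 - d) = y(0.3 + d), paired by grid index
  k <- round((sp@axis - 0.3) / 0.005)
  d <- 1:300
  expect_equal(sp@ordinate[match(-d, k)], sp@ordinate[match(d, k)],
               tolerance = 1e-9)
})

test_that("doublet minima sit at delta +/- dEQ/2", {
  sp <- simulateMossbauer(mossbauerDoublet(0.3, 0.51), vGrid)
  o <- order(sp@ordinate)
  minima <- sort(sp@axis[o[1:2]])
  expect_equal(minima, c(0.045, 0.555), tolerance = 0.005)
})

test_that("total absorption area equals the amplitude", {
  # Lorentzian tails decay slowly; a +/-10 mm/s window (~80 half-widths)
  # captures > 99% of the area
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  wide <- seq(-10, 10, by = 0.005)
  for (amp in c(1, 3.7)) {
    sp <- simulateMossbauer(mossbauerDoublet(0.3, 0.51, amplitude = amp),
                            wide)
    expect_equal(-trapz(wide, sp@ordinate), amp, tolerance = 0.01)
  }
})

test_that("asymmetry splits the two line areas as requested", {
  # depth ratio at the two line centres equals the area ratio (the other
  # line's tail contributes < 1% at 1.2 mm/s separation)
  d <- mossbauerDoublet(0.3, 1.2, asymmetry = 2)
  sp <- simulateMossbauer(d, seq(-4, 4, by = 0.002))
  depthAt <- function(v) -sp@ordinate[which.min(abs(sp@axis - v))]
  expect_equal(depthAt(0.3 - 0.6) / depthAt(0.3 + 0.6), 2,
               tolerance = 0.02)
  # and a noiseless fit recovers the requested asymmetry exactly
  fit <- fitMossbauer(sp, mossbauerDoublet(0.3, 1.1, asymmetry = 1.5))
  expect_equal(fit$doublet@asymmetry, 2, tolerance = 1e-6)
})

test_that("noiseless self-simulation is recovered exactly", {
  truth <- mossbauerDoublet(0.3, 0.51, linewidth = 0.24, amplitude = 0.8,
                            asymmetry = 1.3)
  fit <- fitMossbauer(simulateMossbauer(truth, vGrid),
                      mossbauerDoublet(0.2, 0.4, amplitude = 1))
  expect_true(fit$converged)
  expect_equal(fit$doublet@isomerShift, 0.3, tolerance = 1e-6)
  expect_equal(fit$doublet@quadrupoleSplitting, 0.51, tolerance = 1e-6)
  expect_equal(fit$doublet@linewidth, 0.24, tolerance = 1e-6)
  expect_equal(fit$doublet@amplitude, 0.8, tolerance = 1e-6)
  expect_equal(fit$doublet@asymmetry, 1.3, tolerance = 1e-5)
})

test_that("seeded 1% noise leaves the splitting within 0.02 mm/s", {
  truth <- mossbauerDoublet(0.3, 0.51)
  clean <- simulateMossbauer(truth, vGrid)
  sigma <- 0.01 * max(abs(clean@ordinate))
  noisy <- makeNoisySpectrum(truth, vGrid, noiseSigma = sigma, seed = 7L)
  fit <- fitMossbauer(noisy, mossbauerDoublet(0.25, 0.40))
  expect_true(fit$converged)
  expect_equal(fit$doublet@quadrupoleSplitting, 0.51, tolerance = 0.02)
})

test_that("the splitting estimate is unbiased over seeded replicates", {
  truth <- mossbauerDoublet(0.3, 0.51)
  grid <- seq(-2, 2, by = 0.01)
  sigma <- 0.01 * max(abs(simulateMossbauer(truth, grid)@ordinate))
  est <- vapply(1:100, function(seed) {
    noisy <- makeNoisySpectrum(truth, grid, noiseSigma = sigma,
                               seed = seed)
    fitMossbauer(noisy,
                 mossbauerDoublet(0.25, 0.4))$doublet@quadrupoleSplitting
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.51), 0.005)
})

test_that("an isotropic g = 2.0023 line crosses zero at its resonance field", {
  # B[mT] = 71.4477 * nu[GHz] / g = 335.4 at 9.40 GHz
  sp <- simulateEprPowder(list(eprComponent("isotropic", gIso = 2.0023,
                                            linewidth = 20)),
                          9.40, seq(300, 370, by = 0.02))
  i <- which(diff(sign(sp@ordinate)) != 0)
  crossing <- sp@axis[i[which.min(abs(sp@axis[i] - 335))]]
  expect_equal(crossing, 71.4477 * 9.40 / 2.0023, tolerance = 0.1)
})

test_that("an axial powder pattern has its edges at g|| and gperp fields", {
  field <- seq(300, 370, by = 0.02)
  sp <- simulateEprPowder(list(eprComponent("axial", gPar = 2.02,
                                            gPerp = 1.94,
                                            linewidth = 50)),
                          9.40, field)
  bPar <- 71.4477 * 9.40 / 2.02
  bPerp <- 71.4477 * 9.40 / 1.94
  # dominant derivative feature at the gperp edge, a weaker one at g||
  expect_equal(field[which.max(abs(sp@ordinate))], bPerp, tolerance = 2)
  nearPar <- abs(field - bPar) < 3
  expect_gt(max(abs(sp@ordinate[nearPar])),
            0.05 * max(abs(sp@ordinate)))
})

test_that("derivative spectra integrate to ~0 and scale with weight", {
  field <- seq(290, 380, by = 0.02)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  sp <- simulateEprPowder(list(eprComponent("axial", gPar = 2.02,
                                            gPerp = 1.94,
                                            linewidth = 50)), 9.4, field)
  expect_lt(abs(trapz(field, sp@ordinate)),
            1e-3 * max(abs(sp@ordinate)))
  # double integral of each recovered absorption is the component weight
  comps <- list(eprComponent("axial", gPar = 2.02, gPerp = 1.94,
                             linewidth = 50, weight = 0.96),
                eprComponent("isotropic", gIso = 2.01, linewidth = 20,
                             weight = 0.04))
  mix <- simulateEprPowder(comps, 9.4, field)
  w <- fitEprWeights(mix, comps, 9.4)
  expect_equal(unname(w), c(0.96, 0.04), tolerance = 0.02 * 0.96)
})

test_that("weights must sum to one", {
  bad <- list(eprComponent("isotropic", gIso = 2.0, weight = 0.4))
  expect_error(simulateEprPowder(bad, 9.4, seq(300, 370, by = 0.1)),
               "sum to 1")
})

test_that("a 4% radical weight is recovered within 1% from noisy data", {
  field <- seq(290, 380, by = 0.05)
  comps <- list(eprComponent("axial", gPar = 2.02, gPerp = 1.94,
                             linewidth = 50, weight = 0.96),
                eprComponent("isotropic", gIso = 2.01, linewidth = 20,
                             weight = 0.04))
  clean <- simulateEprPowder(comps, 9.4, field)
  sigma <- 0.01 * max(abs(clean@ordinate))
  noisy <- makeNoisySpectrum(comps, field, noiseSigma = sigma, seed = 11L,
                             frequencyGHz = 9.4)
  w <- fitEprWeights(noisy, comps, 9.4)
  expect_equal(unname(w[2]), 0.04, tolerance = 0.01 / 0.04)
  # single component -> weight 1; absent component -> ~0
  w1 <- fitEprWeights(clean, comps[1], 9.4)
  expect_equal(unname(w1), 1)
  only1 <- simulateEprPowder(list(eprComponent("axial", gPar = 2.02,
                                               gPerp = 1.94,
                                               linewidth = 50,
                                               weight = 1)), 9.4, field)
  w0 <- fitEprWeights(only1, comps, 9.4)
  expect_lt(unname(w0[2]), 0.005)
})

test_that("identical components are a degenerate design", {
  comps <- list(eprComponent("isotropic", gIso = 2.0, linewidth = 20,
                             weight = 0.5),
                eprComponent("isotropic", gIso = 2.0, linewidth = 20,
                             weight = 0.5))
  sp <- simulateEprPowder(comps, 9.4, seq(300, 370, by = 0.05))
  expect_error(fitEprWeights(sp, comps, 9.4), "degenerate")
})

test_that("spectra round-trip through the two-column text format", {
  sp <- makeNoisySpectrum(mossbauerDoublet(0.3, 0.51), vGrid,
                          noiseSigma = 0.001, seed = 2L)
  f <- tempfile(fileext = ".txt")
  writeSpectrum(sp, f)
  sp2 <- readSpectrum(f)
  expect_equal(sp2@axis, sp@axis, tolerance = 1e-9)
  expect_equal(sp2@ordinate, sp@ordinate, tolerance = 1e-9)
  expect_equal(sp2@metadata$axisUnit, "mm/s")
})

test_that("noise is seeded and reproducible with the requested sd", {
  truth <- mossbauerDoublet(0.3, 0.51)
  grid <- seq(-2, 2, by = 0.01)
  clean <- simulateMossbauer(truth, grid)
  s0 <- makeNoisySpectrum(truth, grid, noiseSigma = 0, seed = 5L)
  expect_equal(s0@ordinate, clean@ordinate)
  sA <- makeNoisySpectrum(truth, grid, noiseSigma = 0.01, seed = 5L)
  sB <- makeNoisySpectrum(truth, grid, noiseSigma = 0.01, seed = 5L)
  expect_identical(sA@ordinate, sB@ordinate)
  # empirical residual sd over many seeds
  resid <- unlist(lapply(1:100, function(seed)
    makeNoisySpectrum(truth, grid, noiseSigma = 0.01,
                      seed = seed)@ordinate - clean@ordinate))
  expect_equal(stats::sd(resid), 0.01, tolerance = 0.05)
})
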