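# Kinetic engine: steady states, clearance profiles, apparent rates,
# occupancy, and agreement with an independent ODE oracle.

test_that("steady state solves the synthesis/removal balance", {
  m <- modelPreset("model_1_2")
  # no writing: single-pool balance k_syn / k_deg
  ss <- steadyState(m, c(k_syn = 1, k_w = 0, k_e = 0.3,
                         k_deg_u = 0.1, k_deg_P = 0.2))
  expect_equal(unname(ss), c(10, 0), tolerance = 1e-12)
  # no synthesis anywhere: empty system
  ss0 <- steadyState(m, c(k_syn = 0, k_w = 0.2, k_e = 0.1,
                          k_deg_u = 0.1, k_deg_P = 0.1))
  expect_equal(unname(ss0), c(0, 0))
  # symmetric interconversion case, checked against an independent linear
  # solve of the 2x2 balance
  p <- c(k_syn = 1, k_w = 0.2, k_e = 0.1, k_deg_u = 0.1, k_deg_P = 0.1)
  M <- rbind(c(-(0.2 + 0.1), 0.1), c(0.2, -(0.1 + 0.1)))
  expect_equal(unname(steadyState(m, p)),
               as.numeric(solve(-M, c(1, 0))), tolerance = 1e-12)
  expect_equal(unname(steadyState(m, p)), c(5, 5), tolerance = 1e-12)
})

test_that("a system without degradation is rejected with its eigenvalue", {
  m <- modelPreset("model_1_2")
  expect_error(
    steadyState(m, c(k_syn = 1, k_w = 0.2, k_e = 0.1,
                     k_deg_u = 0, k_deg_P = 0)),
    "eigenvalue")
  expect_error(validateRates(m, c(k_syn = 1, k_w = 0.2, k_e = 0.1,
                                  k_deg_u = 0.1)),
               "missing rate")
  expect_error(validateRates(m, c(k_syn = 1, k_w = -0.2, k_e = 0.1,
                                  k_deg_u = 0.1, k_deg_P = 0.1)),
               ">= 0")
})

test_that("single-pool clearance is a pure exponential", {
  m <- modelPreset("model_0_1")
  prof <- clearanceProfile(m, c(k_syn = 1, k_deg = 0.1),
                           times = c(0, 2, 5, 10))
  expect_equal(unname(phi(prof)[, "O"]), c(0, -0.2, -0.5, -1),
               tolerance = 1e-10)
})

test_that("profiles start at 0, stay non-positive, and match the ODE oracle", {
  m <- modelPreset("model_1_2")
  p <- c(k_syn = 1, k_w = 0.2, k_e = 0.1, k_deg_u = 0.1, k_deg_P = 0.1)
  times <- c(0, 1, 2, 4, 6)
  prof <- clearanceProfile(m, p, times)
  expect_s4_class(prof, "ClearanceProfile")
  expect_equal(unname(phi(prof)[1, ]), rep(0, 3))
  expect_true(all(phi(prof) <= 1e-9))
  oracle <- odeClearanceOracle(m, p, times)
  expect_lt(max(abs(phi(prof) - oracle)), 1e-8)
})

test_that("eigen solution agrees with the ODE oracle on random instances of all presets", {
  set.seed(101)
  times <- c(0, 0.5, 1, 3, 6, 12)
  for (preset in c("model_0_1", "model_1_2", "model_1_2r", "model_1_3")) {
    m <- modelPreset(preset)
    for (i in 1:25) {
      p <- randomRates(m)
      prof <- clearanceProfile(m, p, times)
      oracle <- odeClearanceOracle(m, p, times)
      expect_lt(max(abs(phi(prof) - oracle)), 1e-8)
    }
  }
})

test_that("defective system matrices fall back to the matrix exponential", {
  # maturation chain with equal removal totals has a repeated eigenvalue and
  # a non-diagonalisable system matrix
  m <- modelPreset("model_1_3")
  p <- c(k_syn = 1, k_w = 0.2, k_e = 0.15, k_deg_0 = 0.1,
         k_deg_P = 0.15, k_deg_u = 0.05)
  A <- systemMatrix(m, p)
  ev <- eigen(A, only.values = TRUE)$values
  expect_equal(sort(Re(ev))[1], sort(Re(ev))[2], tolerance = 1e-12)
  times <- c(0, 1, 4, 10)
  prof <- clearanceProfile(m, p, times)
  oracle <- odeClearanceOracle(m, p, times)
  expect_lt(max(abs(phi(prof) - oracle)), 1e-8)
})

test_that("modified species clears slower in the forward wiring, faster in the reversed", {
  set.seed(202)
  times <- c(0, 0.5, 1, 2, 4, 8, 16, 28)
  for (i in 1:200) {
    p <- randomRates(modelPreset("model_1_2"))
    prof <- clearanceProfile(modelPreset("model_1_2"), p, times)
    expect_true(all(phi(prof)[, "O_P"] >= phi(prof)[, "O"] - 1e-9))
    expect_true(all(phi(prof)[, "O"] >= phi(prof)[, "O_u"] - 1e-9))
    profr <- clearanceProfile(modelPreset("model_1_2r"), p, times)
    expect_true(all(phi(profr)[, "O_P"] <= phi(profr)[, "O"] + 1e-9))
  }
})

test_that("fast interconversion collapses the modified pool onto the total pool", {
  m <- modelPreset("model_1_2")
  kd <- c(k_deg_u = 0.1, k_deg_P = 0.05)
  k <- 100 * max(kd)
  p <- c(k_syn = 1, k_w = k, k_e = k, kd)
  prof <- clearanceProfile(m, p, times = c(0, seq(0.5, 28, by = 0.5)))
  expect_lt(max(abs(phi(prof)[, "O_P"] - phi(prof)[, "O"])), 0.01)
})

test_that("without writing, the unmodified pool decays at its own degradation rate", {
  m <- modelPreset("model_1_2")
  p <- c(k_syn = 1, k_w = 0, k_e = 0.2, k_deg_u = 0.07, k_deg_P = 0.3)
  prof <- clearanceProfile(m, p, times = c(0, 1, 5, 20),
                           observables = list(O_u = c(P_u = 1)))
  expect_equal(unname(phi(prof)[, "O_u"]), -0.07 * c(0, 1, 5, 20),
               tolerance = 1e-10)
  # the modified pool has zero steady-state abundance: undefined observable
  expect_error(
    clearanceProfile(m, p, times = c(0, 1), observables = list(O_P = c(P_P = 1))),
    "zero steady-state abundance")
})

test_that("apparent rate is the through-origin slope on the window", {
  tt <- c(0, 1, 2, 3, 4.5, 6)
  prof <- new("ClearanceProfile", times = tt,
              phi = cbind(O = -0.1 * tt))
  expect_equal(apparentRate(prof, "O", 6), 0.1, tolerance = 1e-12)
  prof0 <- new("ClearanceProfile", times = tt, phi = cbind(O = 0 * tt))
  expect_equal(apparentRate(prof0, "O", 6), 0)
  expect_error(apparentRate(new("ClearanceProfile", times = 0,
                                phi = cbind(O = 0)), "O", 6),
               "at least 2 points")
})

test_that("the old modified pool starts flat in the forward wiring", {
  # at steady state, erasing loss and writing gain of the old modified pool
  # balance at t = 0, so its initial clearance rate is exactly zero
  m <- modelPreset("model_1_2")
  p <- c(k_syn = 1, k_w = 0.2, k_e = 0.1, k_deg_u = 0.1, k_deg_P = 0.1)
  ks <- vapply(c(0.5, 0.1, 0.02), function(w) {
    prof <- clearanceProfile(m, p, times = c(0, w / 2, w))
    apparentRate(prof, "O_P", w)
  }, numeric(1))
  expect_true(all(diff(abs(ks)) < 0))      # shrinking window -> rate -> 0
  expect_lt(abs(ks[3]), 5e-3)
  # finite-difference initial slope is zero to first order
  prof <- clearanceProfile(m, p, times = c(0, 1e-5))
  expect_lt(abs(phi(prof)[2, "O_P"] / 1e-5), 1e-6)
})

test_that("occupancy matches the steady-state modified fraction", {
  expect_equal(occupancyModel12(0, 0.1, 0.1), 0)
  expect_equal(occupancyModel12(0.5, 0, 0), 1)
  expect_equal(occupancyModel12(0.2, 0.1, 0.05), 0.2 / 0.35,
               tolerance = 1e-12)
  expect_error(occupancyModel12(0, 0, 0), "cannot all be zero")
  set.seed(33)
  m <- modelPreset("model_1_2")
  for (i in 1:20) {
    k <- exp(runif(3, log(0.01), log(1)))
    p <- c(k_syn = 1, k_w = k[1], k_e = k[2], k_deg_u = k[3], k_deg_P = k[3])
    ss <- steadyState(m, p)
    expect_equal(occupancyModel12(k[1], k[2], k[3]),
                 unname(ss["P_P"] / sum(ss)), tolerance = 1e-10)
  }
})

test_that("closed-form two-species profiles equal the general engine", {
  set.seed(44)
  times <- c(0, 0.5, 2, 6, 24)
  for (i in 1:20) {
    k <- exp(runif(3, log(0.01), log(1)))
    p <- c(k_syn = 1, k_w = k[1], k_e = k[2], k_deg_u = k[3], k_deg_P = k[3])
    prof <- clearanceProfile(modelPreset("model_1_2"), p, times)
    cf <- phiModel12(times, k_deg = k[3], k_w = k[1], k_e = k[2])
    expect_lt(max(abs(cf - phi(prof))), 1e-10)
    profr <- clearanceProfile(modelPreset("model_1_2r"), p, times)
    cfr <- phiModel12(times, k_deg = k[3], k_w = k[1], k_e = k[2],
                      reversed = TRUE)
    expect_lt(max(abs(cfr - phi(profr))), 1e-10)
  }
})

test_that("wiring validity is enforced", {
  expect_error(kineticModel("P", synthesis = c(P = "k_syn"),
                            conversions = data.frame(from = "P", to = "P",
                                                     rate = "k"),
                            degradation = c(P = "k_deg")),
               "from == to")
  expect_error(kineticModel(c("A", "B"), synthesis = c(C = "k_syn"),
                            degradation = c(A = "kd", B = "kd")),
               "undeclared")
  expect_error(kineticModel(c("A", "B"), synthesis = c(A = "k_syn"),
                            degradation = c(A = "kd")),
               "every species needs")
})

test_that("model config round-trips through YAML and profiles export as TSV", {
  cfg <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(preset = "model_1_2",
                        params = list(k_syn = 1, k_w = 0.2, k_e = 0.1,
                                      k_deg_u = 0.1, k_deg_P = 0.1)), cfg)
  mc <- readModelConfig(cfg)
  expect_equal(modelSpecies(mc$model), c("P_u", "P_P"))
  prof <- clearanceProfile(mc$model, mc$params, times = c(0, 1, 2))
  out <- tempfile(fileext = ".tsv")
  df <- writeProfileTSV(prof, out)
  back <- read.delim(out)
  expect_equal(back$phi, df$phi, tolerance = 1e-12)
  expect_equal(names(back), c("time_h", "observable", "phi"))
})
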