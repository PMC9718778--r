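# Comparative spline F-test: reference construction, the F statistic against
# a normal-equations oracle, the randomization null, calibration, hit
# calling and classification.

mkTrace <- function(pep, phi_fun, times = c(0.5, 1, 2, 3, 4.5, 6, 9, 24),
                    reps = 1:3, prot = "P1", mod = "none", sites = "") {
  g <- expand.grid(replicate = reps, time_h = times, KEEP.OUT.ATTRS = FALSE)
  data.frame(protein_id = prot, peptide_id = pep, mod_type = mod,
             site_positions = sites, replicate = g$replicate,
             time_h = g$time_h, phi = phi_fun(g$time_h, g$replicate),
             stringsAsFactors = FALSE)
}

test_that("the protein reference is the per-(replicate, time) median of the others", {
  tr <- rbind(mkTrace("p1", function(t, r) -0.1 * t),
              mkTrace("p2", function(t, r) -0.2 * t),
              mkTrace("p3", function(t, r) -0.6 * t))
  ref <- proteinReference(tr, "P1", exclude_peptides = "p9")
  expect_equal(ref$phi[ref$time_h == 1], rep(-0.2, 3))
  # excluding the tested peptide: its extreme values cannot shift the median
  trx <- rbind(tr, mkTrace("wild", function(t, r) -5 * t))
  refx <- proteinReference(trx, "P1", exclude_peptides = "wild")
  expect_equal(refx$phi[refx$time_h == 1], rep(-0.2, 3))
  # fewer than 2 remaining unique peptides: no reference
  expect_null(proteinReference(tr[tr$peptide_id %in% c("p1", "p2"), ],
                               "P1", exclude_peptides = "p1"))
  # site-covering unmodified peptides are left out of the median by default
  trs <- rbind(tr, mkTrace("cnt", function(t, r) -3 * t, sites = "42"))
  refs <- proteinReference(trs, "P1")
  expect_equal(refs$phi[refs$time_h == 1], rep(-0.2, 3))
})

test_that("spline F statistic matches a normal-equations least-squares oracle", {
  set.seed(77)
  pep <- data.frame(time_h = c(0.5, 1, 2, 3, 4.5, 6, 9, 24),
                    phi = c(-0.031, -0.066, -0.118, -0.178, -0.271,
                            -0.344, -0.521, -1.302))
  ref <- data.frame(time_h = rep(c(0.5, 1, 2, 3, 4.5, 6, 9, 24), 2),
                    phi = rep(c(-0.025, -0.049, -0.103, -0.151, -0.229,
                                -0.303, -0.453, -1.185), 2) +
                      rnorm(16, 0, 0.01))
  st <- splineFTest(pep, ref)
  # oracle: same natural-spline basis, explicit normal equations
  t_all <- c(pep$time_h, ref$time_h); y <- c(pep$phi, ref$phi)
  X0 <- cbind(1, splines::ns(t_all, df = 3))
  beta0 <- solve(crossprod(X0), crossprod(X0, y))
  rss0 <- sum((y - X0 %*% beta0)^2)
  g <- rep(0:1, c(nrow(pep), nrow(ref)))
  X1 <- cbind(X0 * (g == 0), X0 * (g == 1))
  beta1 <- solve(crossprod(X1), crossprod(X1, y))
  rss1 <- sum((y - X1 %*% beta1)^2)
  expect_equal(st$rss0, rss0, tolerance = 1e-10)
  expect_equal(st$rss1, rss1, tolerance = 1e-10)
  expect_equal(st$F_raw, ((rss0 - rss1) / 4) / (rss1 / (st$n_points - 8)),
               tolerance = 1e-10)
})

test_that("identical traces give F = 0 and a constant offset is detected", {
  pep <- data.frame(time_h = c(0.5, 1, 2, 3, 4.5, 6, 9, 24),
                    phi = -0.1 * c(0.5, 1, 2, 3, 4.5, 6, 9, 24))
  refbase <- pep[rep(1:8, 2), ]
  set.seed(3)
  refbase$phi <- refbase$phi + rnorm(16, 0, 0.005)
  same <- splineFTest(refbase, refbase)
  expect_equal(same$rss0, same$rss1, tolerance = 1e-12)
  expect_equal(same$F_raw, 0)
  off <- pep; off$phi <- off$phi + 1
  st <- splineFTest(off, refbase)
  expect_gt(st$F_raw, 0)
  expect_gte(st$rss0 - st$rss1, nrow(pep) * 0.25)
})

test_that("F never decreases as a planted offset grows", {
  pep0 <- data.frame(time_h = c(0.5, 1, 2, 3, 4.5, 6, 9, 24),
                     phi = -0.08 * c(0.5, 1, 2, 3, 4.5, 6, 9, 24))
  set.seed(9)
  ref <- pep0[rep(1:8, 3), ]
  ref$phi <- ref$phi + rnorm(24, 0, 0.01)
  Fs <- vapply(c(0, 0.05, 0.1, 0.2, 0.5, 1), function(delta) {
    pep <- pep0; pep$phi <- pep$phi - delta
    splineFTest(pep, ref)$F_raw
  }, numeric(1))
  expect_true(all(diff(Fs) >= 0))
})

test_that("RSS1 never exceeds RSS0 (separate fits nest the joint fit)", {
  set.seed(11)
  for (i in 1:50) {
    tt <- c(0.5, 1, 2, 3, 4.5, 6, 9, 24)
    pep <- data.frame(time_h = tt, phi = -0.1 * tt + rnorm(8, 0, 0.05))
    ref <- data.frame(time_h = rep(tt, 2),
                      phi = -0.1 * rep(tt, 2) + rnorm(16, 0, 0.05))
    st <- splineFTest(pep, ref)
    expect_lte(st$rss1, st$rss0 + 1e-12)
  }
})

test_that("the randomization null is reproducible and strictly positive on average", {
  set.seed(21)
  tr <- do.call(rbind, lapply(1:6, function(i)
    mkTrace(sprintf("p%d", i),
            function(t, r) -0.1 * t + rnorm(length(t), 0, 0.02))))
  asm <- pepTurnover:::assembleComparisons(tr, exclude_time = 24)
  n1 <- buildNull(tr[tr$time_h < 24, ], asm$comparisons,
                  n_permutations = 5, seed = 42)
  n2 <- buildNull(tr[tr$time_h < 24, ], asm$comparisons,
                  n_permutations = 5, seed = 42)
  expect_identical(n1, n2)
  expect_gt(mean(n1$F_raw), 0)
  n3 <- buildNull(tr[tr$time_h < 24, ], asm$comparisons,
                  n_permutations = 5, seed = 43)
  expect_false(identical(n1$F_raw, n3$F_raw))
  # point-label scheme is available for diagnostics
  n4 <- buildNull(tr[tr$time_h < 24, ], asm$comparisons,
                  n_permutations = 5, seed = 42, scheme = "points")
  expect_true(all(is.finite(n4$F_raw)))
})

test_that("effective degrees of freedom are recovered from a known F sample", {
  set.seed(31)
  null <- data.frame(F_raw = rf(5000, 3, 10), n_points = 40L)
  cal <- calibrateNull(null, n_bins = 1)
  expect_gt(cal$d1, 2.5); expect_lt(cal$d1, 3.5)
  expect_gt(cal$d2, 8); expect_lt(cal$d2, 12)
  expect_lt(abs(cal$scale - 1), 0.15)
  # a degenerate all-equal null cannot be calibrated
  expect_error(calibrateNull(data.frame(F_raw = rep(1, 500), n_points = 40L)),
               "degenerate")
  expect_error(calibrateNull(data.frame(F_raw = numeric(), n_points = integer())),
               "empty null")
})

test_that("calibrated p of the null sample itself is near uniform", {
  set.seed(32)
  null <- data.frame(F_raw = 2.5 * rf(4000, 3, 8), n_points = 40L)
  cal <- suppressWarnings(calibrateNull(null, n_bins = 1))
  res <- callHits(data.frame(F_raw = null$F_raw, n_points = null$n_points),
                  cal)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("hit calling applies joint BH and zero statistics are never hits", {
  null <- data.frame(F_raw = rf(3000, 3, 10), n_points = 40L)
  set.seed(5)
  cal <- calibrateNull(null, n_bins = 1)
  res <- data.frame(F_raw = c(0, 0, 0), n_points = 40L)
  out <- callHits(res, cal)
  expect_equal(out$p, rep(1, 3))
  expect_false(any(out$significant))
  # BH on the calibrated p vector is joint over everything passed in
  res2 <- callHits(data.frame(F_raw = c(80, 60, 0.5), n_points = 40L), cal)
  expect_equal(res2$p_adj, p.adjust(res2$p, "BH"))
  # counts outside the calibrated range fall into the nearest edge bin
  res3 <- callHits(data.frame(F_raw = 1, n_points = 999L), cal)
  expect_equal(res3$bin_id, 1L)
})

test_that("classification follows significance and initial-slope direction", {
  tt <- c(0.5, 1, 2, 3, 4.5, 6, 9)
  cmp <- list(list(protein_id = "P", peptide_id = "p", mod_type = "none",
                   peptide = data.frame(time_h = tt, phi = -0.2 * tt),
                   reference = data.frame(time_h = tt, phi = -0.1 * tt)))
  res <- data.frame(rss0 = 2, rss1 = 1, significant = TRUE)
  out <- classifyHits(res, cmp)
  expect_equal(out$class, "faster")
  expect_equal(out$signed_effect, 1)
  expect_equal(out$k_app_peptide, 0.2, tolerance = 1e-10)
  res$significant <- FALSE
  expect_equal(classifyHits(res, cmp)$class, "ns")
  # slower case with negative signed effect
  cmp[[1]]$peptide$phi <- -0.05 * tt
  res$significant <- TRUE
  out2 <- classifyHits(res, cmp)
  expect_equal(out2$class, "slower")
  expect_lt(out2$signed_effect, 0)
})

test_that("planted wirings are recovered with the implied direction end-to-end", {
  reps3 <- data.frame(replicate = 1:3, t_cc = c(28.0, 26.5, 27.0),
                      label_orientation = rep("new_is_heavy", 3))
  cfg <- simConfig(n_proteins = 60, phospho_fraction = 0.5, p_model_1_2 = 0.5,
                   replicates = reps3, sigma = 0.02,
                   rates = list(
                     k_deg = c(meanlog = log(0.04), sdlog = 0.5),
                     k_deg_stable = c(meanlog = log(5e-4), sdlog = 0.5),
                     k_w = c(min = 0.1, max = 0.5),
                     k_e = c(min = 0.1, max = 0.5),
                     k_w_nterm = c(meanlog = log(0.4), sdlog = 0.4),
                     k_e_nterm = c(meanlog = log(0.005), sdlog = 0.4)))
  truth <- sampleProteome(cfg, seed = 61)
  meas <- simulateMeasurements(truth, cfg, seed = 62)
  filt <- filterMeasurements(meas)
  growth <- suppressWarnings(estimateCellCycle(filt$table))
  traces <- reproducibilityFilter(correctGrowth(filt$table, growth))$traces
  det <- suppressWarnings(testClearance(traces, seed = 63))
  res <- det$results
  tc <- truth$peptides$true_class[match(paste(res$peptide_id, res$mod_type),
          paste(truth$peptides$peptide_id, truth$peptides$mod_type))]
  hits <- res$significant & tc %in% c("faster", "slower")
  expect_gt(sum(hits), 10)
  expect_gt(mean(res$class[hits] == tc[hits]), 0.9)
  # phosphopeptides on the forward wiring are called slower, reversed faster
  phos <- res$mod_type == "phospho" & res$significant
  mod <- truth$proteins$model[match(res$protein_id, truth$proteins$protein_id)]
  expect_true(all(res$class[phos & mod == "model_1_2"] == "slower"))
  expect_true(all(res$class[phos & mod == "model_1_2r"] == "faster"))
  # skip table carries reasons
  expect_true(all(det$skipped$reason %in%
                    c("too_few_points", "insufficient_reference")))
})
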