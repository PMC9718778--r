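# Shared helpers: an independent ODE oracle for clearance profiles, random
# parameter draws, and small simulation shortcuts used across test files.

# clearance profile via adaptive ODE integration (deSolve::lsoda), fully
# independent of the eigen/matrix-exponential path in the package
odeClearanceOracle <- function(model, params, times,
                               observables = defaultObservables(model)) {
  A <- systemMatrix(model, params)
  u0 <- steadyState(model, params)
  sol <- deSolve::ode(y = u0, times = times,
                      func = function(t, y, parms) list(A %*% y),
                      atol = 1e-13, rtol = 1e-11)
  U <- sol[, -1, drop = FALSE]
  sapply(observables, function(w) {
    ww <- rep(0, length(u0)); names(ww) <- names(u0)
    ww[names(w)] <- w
    log(as.numeric(U %*% ww) / sum(ww * u0))
  })
}

# random strictly-positive parameter draw for a preset wiring; the upper
# bound keeps the old pool well above the ODE oracle's absolute tolerance
# over the comparison horizon, so log-scale agreement is meaningful
randomRates <- function(model, min = 0.02, max = 0.3) {
  syms <- rateSymbols(model)
  p <- exp(runif(length(syms), log(min), log(max)))
  names(p) <- syms
  p
}

# small single-protein measurement table with exact exponential kinetics,
# built directly (no simulator), for preprocessing unit tests
exactProteinTable <- function(protein_id, k_deg, t_cc, times,
                              n_peptides = 3, replicate = 1L,
                              orientation = "new_is_heavy") {
  rows <- expand.grid(pep = seq_len(n_peptides), time_h = times,
                      KEEP.OUT.ATTRS = FALSE)
  ratio <- exp((k_deg + log(2) / t_cc) * rows$time_h) - 1
  old <- 1e6
  new <- ratio * old
  data.frame(protein_id = protein_id,
             peptide_id = sprintf("%s_p%d", protein_id, rows$pep),
             mod_type = "none", site_positions = "",
             replicate = replicate, label_orientation = orientation,
             time_h = rows$time_h,
             intensity_light = if (orientation == "new_is_heavy") old else new,
             intensity_heavy = if (orientation == "new_is_heavy") new else old,
             id_score = 0.01, stringsAsFactors = FALSE)
}

# default time grid without the last (excluded) point
gridTimes <- function() c(0.5, 1, 2, 3, 4.5, 6, 9, 24, 28)
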