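# Fitting the simplified two-species model (shared degradation constant) to
# the three measured observables of a modification site: the modified
# peptide(s) O_P, the unmodified counterpart(s) O_u, and the protein pool O.
# Yields writing/erasing rates, mean time to modify (1/k_w), steady-state
# occupancy, and confidence flags from the Gauss-Newton covariance.

#' Assemble the three observables of a site
#'
#' For each collated site, gathers the modified-peptide trace points (O_P),
#' the unmodified counterpart points (O_u), and the protein reference (O,
#' per-(replicate, time) median of the protein's other unmodified peptides,
#' excluding the site-covering forms). Sites missing any of the three
#' observables are skipped with a reason, as are sites whose protein lacks a
#' valid reference.
#'
#' Growth dilution enters the model through the steady state: in a growing
#' culture the proteoform composition is set by `k_deg + ln2/t_cc`, so even
#' after the per-replicate growth correction of phi the curves differ from
#' the closed-culture model. When a growth estimate is supplied, each point
#' carries its replicate's dilution rate `mu` and [fitModel12()] models it;
#' without one `mu = 0` (no growth).
#'
#' @param traces a `PeptideTrace` data.frame.
#' @param pairing a `SitePairing` from [collateSites()].
#' @param growth optional data.frame `replicate` -> `t_cc` (h), as from
#'   [estimateCellCycle()].
#' @return list with `sites` (per site: meta plus a data.frame `observable`,
#'   `time_h`, `phi`, `mu`) and `skipped` (reason-coded data.frame).
#' @export
assembleObservables <- function(traces, pairing, growth = NULL) {
  muOf <- function(rep) {
    if (is.null(growth)) return(rep(0, length(rep)))
    log(2) / growth$t_cc[match(rep, growth$replicate)]
  }
  sites <- list(); skipped <- list()
  for (i in seq_len(nrow(pairing))) {
    s <- pairing[i, ]
    mod_ids <- strsplit(s$modified_peptides, ",")[[1]]
    umod_ids <- strsplit(s$unmodified_peptides, ",")[[1]]
    reason <- NULL
    if (!length(mod_ids)) reason <- "no_modified_observable"
    else if (!length(umod_ids)) reason <- "no_unmodified_counterpart"
    if (is.null(reason)) {
      oP <- traces[traces$peptide_id %in% mod_ids, , drop = FALSE]
      oU <- traces[traces$peptide_id %in% umod_ids &
                     traces$mod_type != s$mod_kind, , drop = FALSE]
      ref <- proteinReference(traces, s$protein_id,
                              exclude_peptides = c(mod_ids, umod_ids))
      if (!nrow(oP)) reason <- "no_modified_observable"
      else if (!nrow(oU)) reason <- "no_unmodified_counterpart"
      else if (is.null(ref)) reason <- "no_protein_reference"
    }
    if (!is.null(reason)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        protein_id = s$protein_id, site_position = s$site_position,
        mod_kind = s$mod_kind, reason = reason, stringsAsFactors = FALSE)
      next
    }
    pts <- rbind(
      data.frame(observable = "O_P", time_h = oP$time_h, phi = oP$phi,
                 mu = muOf(oP$replicate)),
      data.frame(observable = "O_u", time_h = oU$time_h, phi = oU$phi,
                 mu = muOf(oU$replicate)),
      data.frame(observable = "O", time_h = ref$time_h, phi = ref$phi,
                 mu = muOf(ref$replicate)))
    sites[[length(sites) + 1L]] <- list(
      protein_id = s$protein_id, site_position = s$site_position,
      mod_kind = s$mod_kind, points = pts)
  }
  list(sites = sites,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(protein_id = character(), site_position = integer(),
                    mod_kind = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

model12Residuals <- function(logp, pts) {
  k <- exp(logp)
  mu <- if (is.null(pts$mu)) 0 else pts$mu
  # the culture's proteoform steady state is set by k_deg + mu; the growth
  # correction adds mu*t back onto the model clearance
  f <- fracOldModel12(pts$time_h, k_deg = k[1] + mu, k_w = k[2], k_e = k[3],
                      reversed = FALSE, observable = pts$observable)
  pts$phi - (mu * pts$time_h + log(f))
}

numJacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + eps
    J[, j] <- (fn(xp) - f0) / eps
  }
  J
}

#' Fit the simplified two-species model to a site's observables
#'
#' Minimises the summed squared residuals between the measured phi points of
#' all three observables and the model clearance curves, over the
#' log-parameters (ln k_deg, ln k_w, ln k_e) -- log-parameterisation enforces
#' positivity and handles rates spanning decades. Multi-start local
#' optimisation (log-uniform starts in [1e-3, 10] h^-1); standard deviations
#' from the Gauss-Newton covariance at the optimum, mapped to the natural
#' scale by the delta method. Occupancy `k_w/(k_w+k_e+k_deg)` and mean time
#' to modify `1/k_w` are derived from the estimates with delta-method SDs.
#'
#' @param site a site entry from [assembleObservables()] (list with `points`
#'   and metadata), or a bare data.frame `observable`, `time_h`, `phi`.
#' @param n_starts number of optimisation starts (default 20).
#' @param seed integer seed for the start draws.
#' @param exclude_time time point excluded from the fit (default `NA`: keep
#'   all; the pipeline passes the last experimental time point, consistent
#'   with the comparative test).
#' @param sd_cutoff relative-SD threshold below which all three rates must
#'   fall for `high_confidence` (default 0.5).
#' @param weights optional per-observable weights (named numeric); default
#'   equal.
#' @return a one-row `Model12Fit` data.frame: site key, `k_deg`, `k_w`,
#'   `k_e` with `sd_` columns, `mean_time_to_modify`, `occupancy`,
#'   `sd_occupancy`, `rss`, `n_points`, `n_starts_converged`,
#'   `high_confidence`.
#' @export
fitModel12 <- function(site, n_starts = 20, seed = 1, exclude_time = NA,
                       sd_cutoff = 0.5, weights = NULL) {
  pts <- if (is.data.frame(site)) site else site$points
  if (!is.na(exclude_time))
    pts <- pts[pts$time_h < exclude_time, , drop = FALSE]
  pts <- pts[is.finite(pts$phi), , drop = FALSE]
  if (nrow(pts) < 6L)
    stop("need >= 6 points across observables to fit the model")
  w <- rep(1, nrow(pts))
  if (!is.null(weights)) w <- sqrt(weights[pts$observable])
  obj <- function(logp) {
    r <- model12Residuals(logp, pts)
    sum((w * r)^2)
  }
  starts <- withSeed(seed,
    matrix(log(10^runif(3 * n_starts, -3, 1)), ncol = 3))
  best <- NULL; n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("no optimisation start converged")
  logp <- best$par
  k <- exp(logp)
  rss <- best$value
  n <- nrow(pts)
  J <- numJacobian(function(p) w * model12Residuals(p, pts), logp)
  sigma2 <- rss / max(n - 3, 1)
  covlog <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(covlog) || any(!is.finite(covlog)) || any(diag(covlog) < 0)) {
    sd_log <- rep(Inf, 3)
    covlog <- diag(Inf, 3)
  } else {
    sd_log <- sqrt(diag(covlog))
  }
  sd_k <- k * sd_log                      # delta method, natural scale
  occ <- occupancyModel12(k[2], k[3], k[1])
  S <- sum(k)
  # gradient of occupancy wrt log-rates: d occ/d log k_i = k_i * d occ/d k_i
  g <- c(-k[1] * k[2] / S^2,
         k[2] * (k[3] + k[1]) / S^2,
         -k[3] * k[2] / S^2)
  sd_occ <- sqrt(drop(t(g) %*% covlog %*% g))
  rel <- sd_k / k
  out <- data.frame(
    protein_id = if (is.data.frame(site)) NA_character_ else site$protein_id,
    site_position = if (is.data.frame(site)) NA_integer_ else site$site_position,
    mod_kind = if (is.data.frame(site)) NA_character_ else site$mod_kind,
    k_deg = k[1], k_w = k[2], k_e = k[3],
    sd_k_deg = sd_k[1], sd_k_w = sd_k[2], sd_k_e = sd_k[3],
    mean_time_to_modify = 1 / k[2],
    occupancy = occ, sd_occupancy = sd_occ,
    rss = rss, n_points = n, n_starts_converged = n_conv,
    high_confidence = all(is.finite(rel)) && all(rel < sd_cutoff),
    stringsAsFactors = FALSE)
  class(out) <- c("Model12Fit", "data.frame")
  out
}

#' Fit all assembled sites
#'
#' @param assembled output of [assembleObservables()].
#' @param ... passed to [fitModel12()].
#' @return a `Model12Fit` data.frame with one row per fitted site; sites
#'   whose fit errors out are dropped with a warning.
#' @export
fitAllSites <- function(assembled, ...) {
  fits <- lapply(assembled$sites, function(s)
    tryCatch(fitModel12(s, ...), error = function(e) NULL))
  failed <- sum(vapply(fits, is.null, TRUE))
  if (failed)
    warning(failed, " site fit(s) failed and were dropped")
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) return(NULL)
  out <- do.call(rbind, fits)
  class(out) <- c("Model12Fit", "data.frame")
  out
}

#' Summarise fitted rates by group
#'
#' Per-group medians of the fitted parameters plus two-sided Welch t tests
#' between exactly two groups (rates and mean time to modify on the log
#' scale, since they span decades; occupancy on the raw scale). Only
#' high-confidence fits enter, and each group needs at least 2 of them.
#'
#' @param fits a `Model12Fit` data.frame (e.g. from [fitAllSites()]).
#' @param group_col column holding the group label (default `"mod_kind"`).
#' @return data.frame with one row per parameter: group medians, the p-value
#'   of the two-group comparison, and group sizes.
#' @export
summarizeFits <- function(fits, group_col = "mod_kind") {
  fits <- fits[fits$high_confidence, , drop = FALSE]
  groups <- unique(fits[[group_col]])
  if (length(groups) != 2L)
    stop("need exactly 2 groups with high-confidence fits, got ",
         length(groups))
  g1 <- fits[fits[[group_col]] == groups[1], , drop = FALSE]
  g2 <- fits[fits[[group_col]] == groups[2], , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g2) < 2L)
    stop("each group needs >= 2 high-confidence fits")
  pars <- c("k_deg", "k_w", "k_e", "mean_time_to_modify", "occupancy")
  rows <- lapply(pars, function(p) {
    x1 <- g1[[p]]; x2 <- g2[[p]]
    tx1 <- if (p == "occupancy") x1 else log(x1)
    tx2 <- if (p == "occupancy") x2 else log(x2)
    pv <- tryCatch(t.test(tx1, tx2)$p.value, error = function(e) NA_real_)
    df <- data.frame(parameter = p, median_1 = median(x1),
                     median_2 = median(x2), p_value = pv,
                     n_1 = length(x1), n_2 = length(x2),
                     stringsAsFactors = FALSE)
    names(df)[2:3] <- paste0("median_", groups)
    names(df)[5:6] <- paste0("n_", groups)
    df
  })
  do.call(rbind, rows)
}
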