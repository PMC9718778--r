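# Comparative spline fit with empirically calibrated F statistics: detect
# peptides whose clearance deviates from their protein's reference.
#
# Each peptide trace is compared against the per-(replicate, time) median of
# all *other* unmodified peptides of the protein. Both traces are fitted with
# a natural cubic spline with 3 degrees of freedom, either jointly (H0) or
# separately (H1), and an F statistic is formed from the residual sums of
# squares. pSILAC ratio noise is heteroscedastic (phi variance grows with
# labelling time), so the nominal F null is wrong; effective degrees of
# freedom are instead estimated from a label-permutation null, in bins of the
# per-comparison data-point count.

#' Reference trace of a protein
#'
#' The per-(replicate, time point) median of phi over the unmodified-fraction
#' peptides of the protein except the excluded ones. By default, unmodified
#' peptides that cover a measured modification site are also left out: they
#' are candidate non-majority proteoforms (the unmodified counterpart of a
#' modified site), and with few quantified peptides per protein they can
#' drag the median away from the whole-pool behaviour it is meant to
#' represent. At least two distinct contributing peptides are required.
#'
#' @param traces a `PeptideTrace` data.frame.
#' @param protein_id protein to summarise.
#' @param exclude_peptides peptide ids to leave out (the peptide under
#'   test).
#' @param exclude_site_covering drop unmodified peptides with annotated
#'   site positions from the median (default `TRUE`).
#' @return data.frame `replicate`, `time_h`, `phi`, or `NULL` (with
#'   attribute-free silence left to the caller) when fewer than 2 unique
#'   reference peptides remain.
#' @export
proteinReference <- function(traces, protein_id, exclude_peptides = character(),
                             exclude_site_covering = TRUE) {
  d <- traces[traces$protein_id == protein_id &
                traces$mod_type == "none" &
                !(traces$peptide_id %in% exclude_peptides), , drop = FALSE]
  if (exclude_site_covering)
    d <- d[is.na(d$site_positions) | d$site_positions == "", , drop = FALSE]
  if (length(unique(d$peptide_id)) < 2L) return(NULL)
  agg <- stats::aggregate(phi ~ replicate + time_h, data = d, FUN = median)
  agg[order(agg$replicate, agg$time_h), , drop = FALSE]
}

# shared natural-cubic-spline design (3 df + intercept) over pooled times
splineDesign3 <- function(t_all) {
  if (length(unique(t_all)) < 4L)
    stop("need >= 4 distinct pooled times for a 3-df spline")
  cbind(1, splines::ns(t_all, df = 3))
}

rssOf <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Spline F statistic for one peptide-vs-reference comparison
#'
#' H0 fits one 3-df natural cubic spline to the pooled peptide + reference
#' points; H1 fits each group separately with the same basis (knots placed at
#' quantiles of the pooled times). The raw statistic uses the nominal scaling
#' `F = ((RSS0 - RSS1)/p1) / (RSS1/p2)` with `p1 = 4` extra parameters and
#' `p2 = n - 8` residual degrees of freedom; its null distribution is
#' recalibrated empirically (see [calibrateNull()]).
#'
#' @param peptide,reference data.frames with columns `time_h` and `phi`
#'   (replicates pooled as independent points; the last experimental time
#'   point is excluded upstream).
#' @return list `rss0`, `rss1`, `F_raw`, `p1`, `p2`, `n_points`.
#' @export
splineFTest <- function(peptide, reference) {
  t_all <- c(peptide$time_h, reference$time_h)
  y <- c(peptide$phi, reference$phi)
  g <- rep(c(0L, 1L), c(nrow(peptide), nrow(reference)))
  X0 <- splineDesign3(t_all)
  rss0 <- rssOf(X0, y)
  X1 <- cbind(X0 * (g == 0L), X0 * (g == 1L))
  rss1 <- rssOf(X1, y)
  p1 <- 4L
  p2 <- length(y) - 8L
  if (p2 < 1L) stop("too few pooled points for separate spline fits")
  dRSS <- max(rss0 - rss1, 0)
  F_raw <- if (rss1 <= 0) {
    if (dRSS <= 1e-12) 0 else Inf
  } else {
    (dRSS / p1) / (rss1 / p2)
  }
  list(rss0 = rss0, rss1 = rss1, F_raw = F_raw, p1 = p1, p2 = p2,
       n_points = length(y))
}

# Gather all testable peptide-vs-reference comparisons.
# Inclusion rules: points at the last experimental time point are excluded;
# the peptide needs >= min_timepoints distinct times and >= min_points points;
# the reference needs >= 2 unique unmodified peptides besides the tested one.
assembleComparisons <- function(traces,
                                exclude_time = max(traces$time_h),
                                min_points = 6L, min_timepoints = 4L) {
  tr <- traces[traces$time_h < exclude_time | is.na(exclude_time), ,
               drop = FALSE]
  pep_keys <- unique(tr[, c("protein_id", "peptide_id", "mod_type")])
  comparisons <- list()
  skipped <- list()
  refCache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pep_keys))) {
    k <- pep_keys[i, ]
    pep <- tr[tr$peptide_id == k$peptide_id & tr$mod_type == k$mod_type, ,
              drop = FALSE]
    if (nrow(pep) < min_points ||
        length(unique(pep$time_h)) < min_timepoints) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        peptide_id = k$peptide_id, mod_type = k$mod_type,
        reason = "too_few_points", stringsAsFactors = FALSE)
      next
    }
    ckey <- paste(k$protein_id, k$peptide_id, sep = "\r")
    ref <- if (!is.null(refCache[[ckey]])) refCache[[ckey]] else {
      r <- proteinReference(tr, k$protein_id, exclude_peptides = k$peptide_id)
      refCache[[ckey]] <- if (is.null(r)) list(NULL) else r
      refCache[[ckey]]
    }
    if (is.null(ref) || (is.list(ref) && !is.data.frame(ref))) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        peptide_id = k$peptide_id, mod_type = k$mod_type,
        reason = "insufficient_reference", stringsAsFactors = FALSE)
      next
    }
    comparisons[[length(comparisons) + 1L]] <- list(
      protein_id = k$protein_id, peptide_id = k$peptide_id,
      mod_type = k$mod_type,
      peptide = pep[, c("time_h", "phi")],
      reference = ref[, c("time_h", "phi")])
  }
  list(comparisons = comparisons,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(peptide_id = character(), mod_type = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

#' Randomization null of the spline F statistic
#'
#' Builds a null sample of F statistics by randomizing the peptide/median
#' labels: for each real comparison, an unmodified peptide of the same
#' protein is drawn at random, labelled "peptide", and tested against the
#' median of the remaining unmodified peptides. Because no proteoform signal
#' distinguishes a random unmodified peptide from its protein's median,
#' these statistics sample the null while keeping everything that the
#' nominal F distribution ignores: heteroscedastic phi noise that grows with
#' labelling time, the unequal variance of a single peptide versus a median
#' trace, and the truncation introduced by the reproducibility filter.
#' Deterministic given the seed.
#'
#' The default scheme is `"peptide_label"`; `scheme = "points"` instead
#' permutes the peptide/reference point labels within each comparison
#' (group sizes preserved), which removes class differences but also
#' equalises the group variances and is kept for diagnostics.
#'
#' @param traces the trace table the comparisons were assembled from, with
#'   the last time point already excluded (as in [testClearance()]).
#' @param comparisons the `comparisons` element of an assembled comparison
#'   set (see [testClearance()]).
#' @param n_permutations null draws per comparison (default 10).
#' @param seed integer seed (required for reproducibility).
#' @param scheme `"peptide_label"` (default) or `"points"`.
#' @param min_points,min_timepoints eligibility of a pseudo-peptide trace
#'   (same thresholds as the real comparisons).
#' @return data.frame `F_raw`, `n_points`.
#' @export
buildNull <- function(traces, comparisons, n_permutations = 10, seed,
                      scheme = c("peptide_label", "points"),
                      min_points = 6L, min_timepoints = 4L) {
  scheme <- match.arg(scheme)
  withSeed(seed, {
    if (scheme == "points")
      return(buildNullPoints(comparisons, n_permutations))
    # the null draws from the same peptide pool the real reference uses:
    # unmodified peptides not covering a measured modification site
    # (site-covering counterparts are candidate proteoform signals and
    # would contaminate the null)
    unmod <- traces[traces$mod_type == "none" &
                      (is.na(traces$site_positions) |
                         traces$site_positions == ""), , drop = FALSE]
    byProt <- split(unmod, unmod$protein_id)
    out <- vector("list", length(comparisons))
    for (i in seq_along(comparisons)) {
      d <- byProt[[comparisons[[i]]$protein_id]]
      if (is.null(d)) next
      byPep <- split(d, d$peptide_id)
      # eligible pseudo-peptides: enough points themselves and >= 2 other
      # peptides left for the median
      elig <- names(byPep)[vapply(byPep, function(p)
        nrow(p) >= min_points &&
          length(unique(p$time_h)) >= min_timepoints, TRUE)]
      if (length(elig) < 1L || length(byPep) < 3L) next
      Fs <- rep(NA_real_, n_permutations)
      np <- rep(NA_integer_, n_permutations)
      picks <- sample(elig, n_permutations, replace = TRUE)
      for (j in seq_len(n_permutations)) {
        q <- picks[j]
        pep <- byPep[[q]]
        others <- d[d$peptide_id != q, , drop = FALSE]
        ref <- stats::aggregate(phi ~ replicate + time_h, data = others,
                                FUN = median)
        st <- tryCatch(
          splineFTest(pep[, c("time_h", "phi")],
                      ref[, c("time_h", "phi")]),
          error = function(e) NULL)
        if (!is.null(st)) {
          Fs[j] <- st$F_raw
          np[j] <- st$n_points
        }
      }
      out[[i]] <- data.frame(F_raw = Fs, n_points = np)
    }
    res <- do.call(rbind, out)
    res[is.finite(res$F_raw), , drop = FALSE]
  })
}

buildNullPoints <- function(comparisons, n_permutations) {
  out <- vector("list", length(comparisons))
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    t_all <- c(cmp$peptide$time_h, cmp$reference$time_h)
    y <- c(cmp$peptide$phi, cmp$reference$phi)
    n_pep <- nrow(cmp$peptide)
    n <- length(y)
    Fs <- numeric(n_permutations)
    for (j in seq_len(n_permutations)) {
      idx <- sample.int(n)
      pep <- data.frame(time_h = t_all[idx[seq_len(n_pep)]],
                        phi = y[idx[seq_len(n_pep)]])
      ref <- data.frame(time_h = t_all[idx[-seq_len(n_pep)]],
                        phi = y[idx[-seq_len(n_pep)]])
      Fs[j] <- tryCatch(splineFTest(pep, ref)$F_raw,
                        error = function(e) NA_real_)
    }
    out[[i]] <- data.frame(F_raw = Fs, n_points = n)
  }
  res <- do.call(rbind, out)
  res[is.finite(res$F_raw), , drop = FALSE]
}

# moment-based initialisation: with the scale carrying the sample mean, a
# mid-range (d1, d2) start is stable across the bins seen in practice
momInitF <- function(x) {
  c(d1 = 3, d2 = 10, scale = max(mean(x), 1e-3))
}

# ML fit of a scaled F distribution: F_raw / scale ~ F(d1, d2). The scale
# absorbs the variance inflation that the reproducibility filter and the
# peptide-vs-median variance imbalance leave in the statistic; d1 and d2 are
# the effective degrees of freedom of its shape. The fit is truncated at the
# `trunc` quantile (central-matching): randomized-label null draws can pick
# up genuine proteoform peptides of the unmodified fraction, which land in
# the extreme tail and would otherwise drag the fitted tail weight up.
fitFdist <- function(x, trunc = 0.98) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 10 || sd(x) == 0)
    stop("degenerate null sample: cannot estimate effective degrees of freedom")
  cutoff <- quantile(x, trunc)
  xs <- x[x <= cutoff]
  init <- momInitF(xs)
  nll <- function(p) {
    d1 <- exp(p[1]); d2 <- exp(p[2]); s <- exp(p[3])
    -sum(stats::df(xs / s, d1, d2, log = TRUE) - log(s)) +
      length(xs) * pf(cutoff / s, d1, d2, log.p = TRUE)
  }
  fit <- optim(log(init), nll, method = "Nelder-Mead",
               control = list(maxit = 2000))
  c(d1 = unname(exp(fit$par[1])), d2 = unname(exp(fit$par[2])),
    scale = unname(exp(fit$par[3])))
}

# ML fit of a generalized Pareto distribution to exceedances y > 0;
# returns c(beta, xi). Used for the far tail of the null, where the scaled-F
# body fit overstates tail weight (the pooled null is a mixture of
# comparison-specific scales: F-ish body, faster-decaying tail).
fitGPD <- function(y) {
  nll <- function(p) {
    beta <- exp(p[1]); xi <- p[2]
    if (xi < -0.99) return(1e10)
    if (abs(xi) < 1e-8)
      return(length(y) * log(beta) + sum(y) / beta)
    z <- 1 + xi * y / beta
    if (any(z <= 0)) return(1e10)
    length(y) * log(beta) + (1 + 1 / xi) * sum(log(z))
  }
  fit <- optim(c(log(mean(y)), 0.1), nll, method = "Nelder-Mead",
               control = list(maxit = 1000))
  c(beta = unname(exp(fit$par[1])), xi = unname(fit$par[2]))
}

gpdTail <- function(y, beta, xi) {
  # P(Y > y) for GPD exceedances
  if (abs(xi) < 1e-8) return(exp(-y / beta))
  z <- 1 + xi * y / beta
  ifelse(z <= 0, 0, z^(-1 / xi))
}

#' Calibrate effective degrees of freedom from a permutation null
#'
#' Splits the null statistics into (up to) `n_bins` quantile bins of the
#' per-comparison data-point count and, per bin, estimates the effective
#' degrees of freedom (d1, d2) and a scale by maximum-likelihood fit of a
#' scaled F distribution, `F_raw / scale ~ F(d1, d2)` (moment-based
#' initialisation). The scale is needed because the calibrated statistic is
#' stochastically larger than any nominal F: the reproducibility filter
#' truncates within-trace scatter without touching peptide-level offsets,
#' and a single peptide is noisier than the median trace it is compared to.
#'
#' Because the pooled null mixes comparison-specific scales, its far tail
#' decays faster than the fitted F body; per bin a generalized Pareto tail
#' is therefore fitted to the exceedances over the null's 95% quantile and
#' spliced onto the body continuously when computing p-values.
#'
#' @param null data.frame `F_raw`, `n_points` from [buildNull()].
#' @param n_bins number of data-count bins (default 6).
#' @return a `CalibrationModel`: data.frame `bin_id`, `lo`, `hi` (count
#'   range, inclusive; ties at an edge fall in the lower bin), `d1`, `d2`,
#'   `scale`, `tail_u`, `tail_beta`, `tail_xi`, `n_null`, with the bin
#'   breaks stored in `attr(, "breaks")`.
#' @export
calibrateNull <- function(null, n_bins = 6) {
  if (!nrow(null)) stop("empty null sample")
  breaks <- unique(quantile(null$n_points,
                            probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- binByCount(null$n_points, breaks)
  rows <- lapply(sort(unique(bin)), function(b) {
    x <- null$F_raw[bin == b]
    if (length(x) < 200)
      warning("calibration bin ", b, " has only ", length(x),
              " null statistics")
    dd <- fitFdist(x)
    # far tail: GPD fit to exceedances over the 95% quantile; the scaled-F
    # body would otherwise overstate the tail weight of the pooled null
    u <- unname(quantile(x[is.finite(x)], 0.95))
    exceed <- x[is.finite(x) & x > u] - u
    gp <- if (length(exceed) >= 50) fitGPD(exceed) else
      c(beta = NA_real_, xi = NA_real_)
    data.frame(bin_id = b,
               lo = min(null$n_points[bin == b]),
               hi = max(null$n_points[bin == b]),
               d1 = dd[["d1"]], d2 = dd[["d2"]], scale = dd[["scale"]],
               tail_u = u, tail_beta = gp[["beta"]], tail_xi = gp[["xi"]],
               n_null = length(x))
  })
  cal <- do.call(rbind, rows)
  attr(cal, "breaks") <- breaks
  class(cal) <- c("CalibrationModel", "data.frame")
  cal
}

# assign counts to quantile bins; ties at an edge go to the lower bin
binByCount <- function(n_points, breaks) {
  b <- findInterval(n_points, breaks, rightmost.closed = TRUE,
                    left.open = TRUE)
  pmin(pmax(b, 1L), max(length(breaks) - 1L, 1L))
}

#' Calibrated p-values and hit calling
#'
#' Computes each comparison's p-value from the calibrated F tail
#' (`pf(F_raw / scale, d1, d2)` with its bin's effective degrees of freedom
#' and scale), applies Benjamini-Hochberg adjustment
#' jointly over all comparisons (both MS fractions together), and marks hits
#' at `p_adj <= alpha`.
#'
#' @param results a comparison-results data.frame (from [testClearance()]'s
#'   internals) with columns `F_raw` and `n_points`.
#' @param calibration a `CalibrationModel` from [calibrateNull()].
#' @param alpha adjusted-p threshold (default 0.001).
#' @return `results` with added `bin_id`, `d1`, `d2`, `p`, `p_adj`,
#'   `significant`.
#' @export
callHits <- function(results, calibration, alpha = 0.001) {
  breaks <- attr(calibration, "breaks")
  bin <- binByCount(results$n_points, breaks)
  idx <- match(bin, calibration$bin_id)
  if (anyNA(idx)) stop("calibration does not cover all data-count bins")
  results$bin_id <- bin
  results$d1 <- calibration$d1[idx]
  results$d2 <- calibration$d2[idx]
  results$scale <- calibration$scale[idx]
  results$p <- pf(results$F_raw / results$scale, results$d1, results$d2,
                  lower.tail = FALSE)
  # splice the GPD tail on continuously at the body's value at tail_u
  u <- calibration$tail_u[idx]
  beta <- calibration$tail_beta[idx]
  xi <- calibration$tail_xi[idx]
  inTail <- !is.na(beta) & results$F_raw > u
  if (any(inTail)) {
    pAtU <- pf(u[inTail] / results$scale[inTail], results$d1[inTail],
               results$d2[inTail], lower.tail = FALSE)
    ptail <- mapply(gpdTail, results$F_raw[inTail] - u[inTail],
                    beta[inTail], xi[inTail])
    results$p[inTail] <- pmax(pAtU * ptail, 1e-300)
  }
  results$p[results$F_raw == 0] <- 1
  results$p_adj <- p.adjust(results$p, method = "BH")
  results$significant <- results$p_adj <= alpha
  results
}

#' Classify a hit as faster or slower by initial slope
#'
#' Apparent rates are through-origin slopes of phi vs t on the early window;
#' `delta_slope = k_app_peptide - k_app_reference`. A significant comparison
#' with positive delta is `faster`, negative `slower`; non-significant
#' comparisons are `ns` regardless of slope. The signed effect size is
#' `sign(delta_slope) * sqrt(max(RSS0 - RSS1, 0))`.
#'
#' @param results output of [callHits()] augmented with per-comparison point
#'   sets (internal use via [testClearance()]).
#' @param comparisons assembled comparison point sets.
#' @param window_h initial-slope window in hours (default 6).
#' @return `results` with `k_app_peptide`, `k_app_reference`, `delta_slope`,
#'   `signed_effect`, `class`, `slope_window_flag`.
#' @export
classifyHits <- function(results, comparisons, window_h = 6) {
  n <- nrow(results)
  kp <- kr <- numeric(n)
  flag <- logical(n)
  for (i in seq_len(n)) {
    cmp <- comparisons[[i]]
    kp_i <- tryCatch(apparentRate(cmp$peptide, window_h = window_h),
                     error = function(e) NA_real_)
    kr_i <- tryCatch(apparentRate(cmp$reference, window_h = window_h),
                     error = function(e) NA_real_)
    if (is.na(kp_i) || is.na(kr_i)) {
      # sparse window: fall back to the full-range slope and flag it
      kp_i <- apparentRate(cmp$peptide, window_h = Inf)
      kr_i <- apparentRate(cmp$reference, window_h = Inf)
      flag[i] <- TRUE
    }
    kp[i] <- kp_i; kr[i] <- kr_i
  }
  results$k_app_peptide <- kp
  results$k_app_reference <- kr
  results$delta_slope <- kp - kr
  results$signed_effect <- sign(results$delta_slope) *
    sqrt(pmax(results$rss0 - results$rss1, 0))
  results$class <- ifelse(!results$significant, "ns",
                          ifelse(results$delta_slope > 0, "faster", "slower"))
  results$slope_window_flag <- flag
  results
}

#' Detect peptides with deviating clearance
#'
#' End-to-end comparative test: assembles peptide-vs-protein-reference
#' comparisons (excluding the last experimental time point), computes spline
#' F statistics, builds a label-permutation null, calibrates effective
#' degrees of freedom in data-count bins, calls hits with BH-adjusted
#' calibrated p-values over both MS fractions jointly, and classifies hits
#' as faster or slower by initial slope.
#'
#' @param traces a `PeptideTrace` data.frame (growth-corrected, filtered).
#' @param alpha BH-adjusted p threshold (default 0.001).
#' @param n_permutations permutations per comparison for the null
#'   (default 10).
#' @param seed integer seed for the permutation null.
#' @param window_h initial-slope window (default 6 h).
#' @param exclude_time time point excluded from all fits (default: the last
#'   time point present in `traces`).
#' @param min_points,min_timepoints inclusion thresholds for the peptide
#'   trace (defaults 6 points, 4 distinct time points).
#' @param n_bins calibration bins (default 6).
#' @return list with `results` (one row per tested peptide: RSS0, RSS1,
#'   F_raw, bin, effective dfs, p, p_adj, apparent rates, signed effect,
#'   class), `skipped` (reason-coded), `calibration`, and `null` (the
#'   permutation-null sample).
#' @export
testClearance <- function(traces, alpha = 0.001, n_permutations = 10,
                          seed = 1, window_h = 6,
                          exclude_time = max(traces$time_h),
                          min_points = 6L, min_timepoints = 4L,
                          n_bins = 6) {
  asm <- assembleComparisons(traces, exclude_time = exclude_time,
                             min_points = min_points,
                             min_timepoints = min_timepoints)
  cmps <- asm$comparisons
  if (!length(cmps))
    return(list(results = NULL, skipped = asm$skipped, calibration = NULL,
                null = NULL))
  stats_list <- lapply(cmps, function(cmp)
    splineFTest(cmp$peptide, cmp$reference))
  results <- data.frame(
    protein_id = vapply(cmps, `[[`, "", "protein_id"),
    peptide_id = vapply(cmps, `[[`, "", "peptide_id"),
    mod_type = vapply(cmps, `[[`, "", "mod_type"),
    n_points = vapply(stats_list, `[[`, 0L, "n_points"),
    n_timepoints = vapply(cmps, function(cmp)
      length(unique(cmp$peptide$time_h)), 0L),
    rss0 = vapply(stats_list, `[[`, 0, "rss0"),
    rss1 = vapply(stats_list, `[[`, 0, "rss1"),
    F_raw = vapply(stats_list, `[[`, 0, "F_raw"),
    stringsAsFactors = FALSE)
  tr <- traces[traces$time_h < exclude_time | is.na(exclude_time), ,
               drop = FALSE]
  null <- buildNull(tr, cmps, n_permutations = n_permutations, seed = seed,
                    min_points = min_points,
                    min_timepoints = min_timepoints)
  calibration <- calibrateNull(null, n_bins = n_bins)
  results <- callHits(results, calibration, alpha = alpha)
  results <- classifyHits(results, cmps, window_h = window_h)
  list(results = results, skipped = asm$skipped, calibration = calibration,
       null = null)
}
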