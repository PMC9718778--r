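# Synthetic pulsed-SILAC data with known ground-truth kinetics.
#
# The generator emulates the structure of a two-label pSILAC phosphoproteomics
# time course: 9 time points from 30 min to 28 h, 4 replicates with the label
# orientation reversed in the last one, growth dilution with doubling times in
# the 22-28 h range, several unmodified peptides per protein plus site-covering
# peptides measured in modified and unmodified form, heteroscedastic
# multiplicative ratio noise, dropout and single-channel rows.

# run code under a local seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' Simulation configuration
#'
#' Defaults describe the emulated experimental design: 9 sampling times from
#' 0.5 h to 28 h (no t = 0 sample), 4 replicates with doubling times
#' 28.0 / 26.5 / 27.0 / 22.2 h and the SILAC label orientation reversed in
#' replicate 4, log-normal rate-constant distributions, multiplicative
#' log-normal noise on the new/old ratio, and random dropout plus a detection
#' floor below which a channel goes missing (producing single-channel rows).
#'
#' @param n_proteins number of proteins.
#' @param peptides_per_protein `c(min, lambda)`: each protein gets
#'   `min + rpois(lambda)` peptides that track the whole protein pool `O`.
#' @param phospho_fraction fraction of proteins carrying one phosphosite
#'   whose covering peptide is measured in both modified and unmodified form.
#' @param p_model_1_2 probability that a phosphosite follows the
#'   synthesis-then-modification wiring (modified form clears slower); the
#'   rest follow the reversed wiring (clears faster).
#' @param nterm_fraction fraction of proteins with an N-terminal maturation
#'   site (acetylated mature form plus unprocessed intermediate), modelled as
#'   a fast-writer / near-zero-eraser two-species site.
#' @param n_site_peptides number of peptide forms per site observable
#'   (>1 emulates miscleavage variants sharing the site).
#' @param stable_fraction fraction of proteins that are effectively
#'   non-degrading over the time course (histone-like long-lived proteins);
#'   their degradation rate is drawn from `rates$k_deg_stable`. This
#'   subpopulation is what the 1-percent-longest-lived rule of the growth
#'   estimator latches onto, as it does in real proteomes.
#' @param rates named list of sampling distributions for `k_deg`,
#'   `k_deg_stable`, `k_w`, `k_e` (h^-1), and `k_w_nterm`, `k_e_nterm` for
#'   N-terminal sites. Each entry is either `c(meanlog, sdlog)` (log-normal)
#'   or `c(min, max)` (log-uniform).
#' @param replicates data.frame with columns `replicate`, `t_cc` (h),
#'   `label_orientation` (`"new_is_heavy"` or `"new_is_light"`).
#' @param times sampling grid in hours (all > 0).
#' @param sigma scale of the log-normal multiplicative noise on the new/old
#'   ratio; yields phi noise that grows with labelling time.
#' @param dropout probability that a measurement row is lost at random.
#' @param intensity `c(meanlog, sdlog)` of per-peptide base intensity.
#' @param detection_floor intensity below which a channel is not quantified;
#'   the row is then emitted with a single channel.
#' @param duplicate_rate probability of emitting a duplicate row for a
#'   (peptide, replicate, time) key, exercising duplicate resolution.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(n_proteins = 300,
                      peptides_per_protein = c(3, 2),
                      phospho_fraction = 0.4,
                      p_model_1_2 = 0.6,
                      nterm_fraction = 0,
                      n_site_peptides = 1,
                      stable_fraction = 0.02,
                      rates = list(
                        k_deg = c(meanlog = log(0.04), sdlog = 0.5),
                        k_deg_stable = c(meanlog = log(5e-4), sdlog = 0.5),
                        k_w = c(meanlog = log(0.15), sdlog = 0.6),
                        k_e = c(meanlog = log(0.15), sdlog = 0.6),
                        k_w_nterm = c(meanlog = log(0.4), sdlog = 0.4),
                        k_e_nterm = c(meanlog = log(0.005), sdlog = 0.4)),
                      replicates = data.frame(
                        replicate = 1:4,
                        t_cc = c(28.0, 26.5, 27.0, 22.2),
                        label_orientation = c("new_is_heavy", "new_is_heavy",
                                              "new_is_heavy", "new_is_light")),
                      times = c(0.5, 1, 2, 3, 4.5, 6, 9, 24, 28),
                      sigma = 0.05,
                      dropout = 0.02,
                      intensity = c(meanlog = log(5e5), sdlog = 1.2),
                      detection_floor = 1e4,
                      duplicate_rate = 0) {
  cfg <- list(n_proteins = n_proteins,
              peptides_per_protein = peptides_per_protein,
              phospho_fraction = phospho_fraction,
              p_model_1_2 = p_model_1_2,
              nterm_fraction = nterm_fraction,
              n_site_peptides = n_site_peptides,
              stable_fraction = stable_fraction,
              rates = rates, replicates = replicates, times = times,
              sigma = sigma, dropout = dropout, intensity = intensity,
              detection_floor = detection_floor,
              duplicate_rate = duplicate_rate)
  stopifnot(all(cfg$times > 0),
            cfg$sigma >= 0,
            cfg$stable_fraction >= 0, cfg$stable_fraction <= 1,
            cfg$phospho_fraction >= 0, cfg$phospho_fraction <= 1,
            cfg$nterm_fraction >= 0,
            cfg$phospho_fraction + cfg$nterm_fraction <= 1,
            cfg$p_model_1_2 >= 0, cfg$p_model_1_2 <= 1,
            all(cfg$replicates$t_cc > 0),
            all(cfg$replicates$label_orientation %in%
                  c("new_is_heavy", "new_is_light")))
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_proteins, "proteins,",
      nrow(x$replicates), "replicates,",
      length(x$times), "time points in [",
      min(x$times), ",", max(x$times), "] h, sigma =", x$sigma, "\n")
  invisible(x)
}

#' Sample a ground-truth proteome
#'
#' Draws per-protein degradation rates and, for site-carrying proteins, a
#' wiring (forward or reversed two-species model) with writing/erasing rates,
#' then lays out the peptides observing each pool. The true faster/slower
#' class of every peptide relative to its protein pool follows from the
#' wiring: with synthesis entering the unmodified pool the modified form
#' clears slower and the site-covering unmodified form faster; the reversed
#' wiring mirrors this.
#'
#' @param config a [simConfig()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return list of class `GroundTruth` with data.frames `proteins`
#'   (protein_id, k_deg, model, k_w, k_e, site_position, mod_kind) and
#'   `peptides` (protein_id, peptide_id, observable, mod_type,
#'   site_positions, true_class, base_intensity), plus the replicate design.
#' @export
sampleProteome <- function(config = simConfig(), seed = 1) {
  withSeed(seed, {
    n <- config$n_proteins
    if (n == 0) {
      truth <- list(proteins = data.frame(), peptides = data.frame(),
                    replicates = config$replicates, config = config)
      class(truth) <- "GroundTruth"
      return(truth)
    }
    r <- config$rates
    pid <- sprintf("PROT%04d", seq_len(n))
    k_deg <- drawRate(n, r$k_deg)
    stable <- runif(n) < config$stable_fraction
    if (any(stable))
      k_deg[stable] <- drawRate(sum(stable), r$k_deg_stable)
    kind <- sample(c("phospho", "nterm_ac", "none"), n, replace = TRUE,
                   prob = c(config$phospho_fraction, config$nterm_fraction,
                            1 - config$phospho_fraction - config$nterm_fraction))
    model <- ifelse(kind == "none", "none",
             ifelse(kind == "nterm_ac", "model_1_2",
                    ifelse(runif(n) < config$p_model_1_2,
                           "model_1_2", "model_1_2r")))
    k_w <- ifelse(kind == "phospho", drawRate(n, r$k_w),
                  drawRate(n, r$k_w_nterm))
    k_e <- ifelse(kind == "phospho", drawRate(n, r$k_e),
                  drawRate(n, r$k_e_nterm))
    k_w[kind == "none"] <- NA_real_
    k_e[kind == "none"] <- NA_real_
    site <- ifelse(kind == "nterm_ac", 2L,
                   ifelse(kind == "phospho",
                          sample(10:490, n, replace = TRUE), NA_integer_))
    proteins <- data.frame(protein_id = pid, k_deg = k_deg, model = model,
                           k_w = k_w, k_e = k_e, site_position = site,
                           mod_kind = kind, stringsAsFactors = FALSE)

    nO <- config$peptides_per_protein[1] +
      rpois(n, config$peptides_per_protein[2])
    pep <- vector("list", n)
    imu <- config$intensity["meanlog"]; isd <- config$intensity["sdlog"]
    for (i in seq_len(n)) {
      ids <- sprintf("%s_pep%02d", pid[i], seq_len(nO[i]))
      df <- data.frame(protein_id = pid[i], peptide_id = ids,
                       observable = "O", mod_type = "none",
                       site_positions = "", true_class = "none",
                       stringsAsFactors = FALSE)
      if (kind[i] != "none") {
        rev <- model[i] == "model_1_2r"
        m <- config$n_site_peptides
        # site-covering peptide forms: boundary-shifted ids emulate
        # modification-induced miscleavage
        modtype <- if (kind[i] == "phospho") "phospho" else "nterm_ac"
        umodtype <- if (kind[i] == "phospho") "none" else "nterm_unprocessed"
        sdf <- data.frame(
          protein_id = pid[i],
          peptide_id = c(sprintf("%s_siteU%02d", pid[i], seq_len(m)),
                         sprintf("%s_siteM%02d", pid[i], seq_len(m))),
          observable = rep(c("O_u", "O_P"), each = m),
          mod_type = rep(c(umodtype, modtype), each = m),
          site_positions = as.character(site[i]),
          true_class = rep(if (rev) c("slower", "faster")
                           else c("faster", "slower"), each = m),
          stringsAsFactors = FALSE)
        df <- rbind(df, sdf)
      }
      pep[[i]] <- df
    }
    peptides <- do.call(rbind, pep)
    peptides$base_intensity <- rlnorm(nrow(peptides), imu, isd)
    truth <- list(proteins = proteins, peptides = peptides,
                  replicates = config$replicates, config = config)
    class(truth) <- "GroundTruth"
    truth
  })
}

# draw n rates from a distribution spec: c(meanlog, sdlog) -> log-normal,
# c(min, max) -> log-uniform
drawRate <- function(n, spec) {
  if (all(c("meanlog", "sdlog") %in% names(spec)))
    rlnorm(n, spec[["meanlog"]], spec[["sdlog"]])
  else if (all(c("min", "max") %in% names(spec)))
    exp(runif(n, log(spec[["min"]]), log(spec[["max"]])))
  else stop("rate spec needs names (meanlog, sdlog) or (min, max)")
}

# vectorised fraction of old material remaining for the two-species model
# with shared degradation constant; all arguments recycled to equal length.
fracOldModel12 <- function(time, k_deg, k_w, k_e, reversed, observable) {
  lam <- k_w + k_e
  su <- ifelse(reversed,
               NA_real_,
               1 / (k_deg + k_w - k_w * k_e / (k_e + k_deg)))
  sP <- ifelse(reversed,
               1 / (k_deg + k_e - k_e * k_w / (k_w + k_deg)),
               NA_real_)
  su <- ifelse(reversed, k_e * sP / (k_w + k_deg), su)
  sP <- ifelse(reversed, sP, k_w * su / (k_e + k_deg))
  tot <- su + sP
  P0u <- k_e * tot / lam
  P0P <- k_w * tot / lam
  ed <- exp(-k_deg * time)
  el <- exp(-lam * time)
  Uu <- ed * (P0u + el * (su - P0u))
  UP <- ed * (P0P + el * (sP - P0P))
  ifelse(observable == "O", (Uu + UP) / tot,
         ifelse(observable == "O_u", Uu / su, UP / sP))
}

#' Simulate a pulsed-SILAC measurement table
#'
#' For every peptide, replicate and time, the fraction of old material is
#' computed from the kinetic model with the replicate's growth dilution
#' (`ln 2 / t_cc` added to every degradation rate), converted to a new/old
#' ratio, noised multiplicatively, and split into light/heavy intensities
#' according to the replicate's label orientation. Rows drop out at random;
#' a channel below the detection floor is left unquantified, producing a
#' single-channel row.
#'
#' @param truth a `GroundTruth` from [sampleProteome()].
#' @param config the [simConfig()] used to create `truth` (defaults to the
#'   one stored in `truth`).
#' @param seed integer seed.
#' @return a `MeasurementTable` data.frame with columns `protein_id`,
#'   `peptide_id`, `mod_type`, `site_positions`, `replicate`,
#'   `label_orientation`, `time_h`, `intensity_light`, `intensity_heavy`,
#'   `id_score`.
#' @export
simulateMeasurements <- function(truth, config = truth$config, seed = 1) {
  withSeed(seed, {
    pep <- truth$peptides
    if (!nrow(pep)) return(emptyMeasurementTable())
    reps <- truth$replicates
    times <- config$times
    grid <- expand.grid(pep_row = seq_len(nrow(pep)),
                        rep_row = seq_len(nrow(reps)),
                        time_h = times, KEEP.OUT.ATTRS = FALSE)
    d <- data.frame(
      protein_id = pep$protein_id[grid$pep_row],
      peptide_id = pep$peptide_id[grid$pep_row],
      mod_type = pep$mod_type[grid$pep_row],
      site_positions = pep$site_positions[grid$pep_row],
      replicate = reps$replicate[grid$rep_row],
      label_orientation = reps$label_orientation[grid$rep_row],
      time_h = grid$time_h,
      stringsAsFactors = FALSE)
    prot <- truth$proteins[match(d$protein_id, truth$proteins$protein_id), ]
    mu <- log(2) / reps$t_cc[grid$rep_row]
    kd_eff <- prot$k_deg + mu
    obs <- pep$observable[grid$pep_row]
    f_old <- ifelse(obs == "O" & prot$model == "none",
                    exp(-kd_eff * d$time_h), NA_real_)
    need <- is.na(f_old)
    if (any(need)) {
      f_old[need] <- fracOldModel12(
        d$time_h[need], kd_eff[need], prot$k_w[need], prot$k_e[need],
        reversed = prot$model[need] == "model_1_2r",
        observable = obs[need])
    }
    ratio <- 1 / f_old - 1
    if (config$sigma > 0)
      ratio <- ratio * exp(rnorm(nrow(d), 0, config$sigma))
    base <- pep$base_intensity[grid$pep_row] *
      exp(rnorm(nrow(d), 0, 0.2))
    i_old <- base / (1 + ratio)
    i_new <- base * ratio / (1 + ratio)
    new_is_heavy <- d$label_orientation == "new_is_heavy"
    d$intensity_light <- ifelse(new_is_heavy, i_old, i_new)
    d$intensity_heavy <- ifelse(new_is_heavy, i_new, i_old)
    d$id_score <- runif(nrow(d))
    # detection floor: a channel below it is not quantified
    d$intensity_light[d$intensity_light < config$detection_floor] <- NA_real_
    d$intensity_heavy[d$intensity_heavy < config$detection_floor] <- NA_real_
    d <- d[!(is.na(d$intensity_light) & is.na(d$intensity_heavy)), ,
           drop = FALSE]
    if (config$dropout > 0)
      d <- d[runif(nrow(d)) >= config$dropout, , drop = FALSE]
    if (config$duplicate_rate > 0) {
      pick <- which(runif(nrow(d)) < config$duplicate_rate)
      if (length(pick)) {
        dup <- d[pick, , drop = FALSE]
        jit <- exp(rnorm(nrow(dup), 0, 0.2))
        dup$intensity_light <- dup$intensity_light * jit
        dup$intensity_heavy <- dup$intensity_heavy * jit
        dup$id_score <- runif(nrow(dup))
        d <- rbind(d, dup)
      }
    }
    rownames(d) <- NULL
    d
  })
}

emptyMeasurementTable <- function() {
  data.frame(protein_id = character(), peptide_id = character(),
             mod_type = character(), site_positions = character(),
             replicate = integer(), label_orientation = character(),
             time_h = numeric(), intensity_light = numeric(),
             intensity_heavy = numeric(), id_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Write ground truth as TSV
#'
#' @param truth a `GroundTruth`.
#' @param path output file; protein-level and peptide-level truth are merged
#'   into one long table keyed by peptide.
#' @return the merged data.frame, invisibly.
#' @export
writeGroundTruthTSV <- function(truth, path) {
  df <- merge(truth$peptides, truth$proteins, by = "protein_id",
              sort = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
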