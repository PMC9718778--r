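# Filtering, growth correction and site collation of pSILAC peptide tables.

measurementColumns <- c("protein_id", "peptide_id", "mod_type",
                        "site_positions", "replicate", "label_orientation",
                        "time_h", "intensity_light", "intensity_heavy",
                        "id_score")

checkMeasurementSchema <- function(table) {
  missing <- setdiff(measurementColumns, names(table))
  if (length(missing))
    stop("measurement table is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(table)
}

# MS fraction a peptide was measured in: the phospho-enriched eluate or the
# unmodified flow-through
fractionOf <- function(mod_type) {
  ifelse(mod_type == "phospho", "phospho", "unmodified")
}

pasteKey <- function(...) do.call(paste, c(list(...), sep = "\r"))

#' Filter a raw measurement table
#'
#' Applies, in order: (1) removal of rows quantified in only one SILAC
#' channel; (2) duplicate resolution per (peptide, modification state,
#' replicate, time), keeping the entry with the lowest identification error
#' score and, on ties, the highest summed intensity; (3) retention of
#' peptides present in at least 2 replicates and at least 2 time points.
#'
#' @param table a `MeasurementTable` data.frame.
#' @return list with `table` (the filtered table) and `report` (a data.frame
#'   of rows removed per rule).
#' @export
filterMeasurements <- function(table) {
  checkMeasurementSchema(table)
  n0 <- nrow(table)
  ok <- !is.na(table$intensity_light) & !is.na(table$intensity_heavy) &
    table$intensity_light > 0 & table$intensity_heavy > 0
  table <- table[ok, , drop = FALSE]
  n1 <- nrow(table)

  if (n1) {
    key <- pasteKey(table$peptide_id, table$mod_type, table$replicate,
                    table$time_h)
    total <- table$intensity_light + table$intensity_heavy
    ord <- order(key, table$id_score, -total)
    table <- table[ord, , drop = FALSE]
    table <- table[!duplicated(key[ord]), , drop = FALSE]
  }
  n2 <- nrow(table)

  if (n2) {
    pkey <- pasteKey(table$peptide_id, table$mod_type)
    nrep <- tapply(table$replicate, pkey, function(x) length(unique(x)))
    ntp <- tapply(table$time_h, pkey, function(x) length(unique(x)))
    keep <- names(nrep)[nrep >= 2 & ntp >= 2]
    table <- table[pkey %in% keep, , drop = FALSE]
  }
  n3 <- nrow(table)
  rownames(table) <- NULL
  report <- data.frame(
    rule = c("single_channel", "duplicate", "presence_2rep_2tp"),
    removed = c(n0 - n1, n1 - n2, n2 - n3))
  list(table = table, report = report)
}

newOldRatio <- function(table) {
  new <- ifelse(table$label_orientation == "new_is_heavy",
                table$intensity_heavy, table$intensity_light)
  old <- ifelse(table$label_orientation == "new_is_heavy",
                table$intensity_light, table$intensity_heavy)
  new / old
}

#' Estimate the cell-cycle (doubling) time per replicate
#'
#' In a steadily growing culture the label-incorporation relationship is
#' `ln(new/old + 1) = (k_deg + ln2/t_cc) * t`, so for non-degrading proteins
#' the slope is `ln2 / t_cc` alone. Per replicate, each protein's slope is
#' fitted through the origin on the protein-median `ln(new/old + 1)` values
#' of its unmodified peptides; the doubling time is `ln2` over the median
#' slope of the `long_lived_fraction` of proteins with the smallest slopes.
#'
#' @param table a filtered `MeasurementTable`.
#' @param long_lived_fraction fraction of proteins treated as non-degrading
#'   (default 0.01).
#' @return data.frame with one row per replicate: `replicate`, `t_cc`,
#'   `slope`, `n_proteins` (size of the long-lived subset).
#' @export
estimateCellCycle <- function(table, long_lived_fraction = 0.01) {
  checkMeasurementSchema(table)
  tab <- table[table$mod_type == "none", , drop = FALSE]
  if (!nrow(tab)) stop("no unmodified-fraction rows to estimate growth from")
  tab$y <- log(newOldRatio(tab) + 1)
  tab <- tab[is.finite(tab$y), , drop = FALSE]
  # protein-median y per (replicate, protein, time)
  agg <- stats::aggregate(y ~ replicate + protein_id + time_h, data = tab,
                          FUN = median)
  out <- lapply(split(agg, agg$replicate), function(d) {
    sl <- vapply(split(d, d$protein_id), function(p) {
      if (length(unique(p$time_h)) < 2) return(NA_real_)
      sum(p$time_h * p$y) / sum(p$time_h^2)   # through the origin
    }, numeric(1))
    sl <- sl[is.finite(sl)]
    if (!length(sl))
      stop("no proteins with >= 2 time points in replicate ",
           d$replicate[1])
    if (length(sl) < 100)
      warning("cell-cycle estimate for replicate ", d$replicate[1],
              " uses only ", length(sl), " proteins")
    k <- max(1L, floor(long_lived_fraction * length(sl)))
    subset <- sort(sl)[seq_len(k)]
    slope <- median(subset)
    if (slope <= 0)
      stop("non-positive long-lived slope in replicate ", d$replicate[1],
           "; cannot form a doubling time")
    data.frame(replicate = d$replicate[1], t_cc = log(2) / slope,
               slope = slope, n_proteins = k)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Growth-correct SILAC ratios into clearance traces
#'
#' Converts each row to the log fraction of old material remaining,
#' corrected for dilution by cell growth:
#' `phi = -ln(new/old + 1) + (ln2 / t_cc) * t`,
#' with new/old read from the intensities according to the replicate's label
#' orientation. Rows whose old channel is zero (ratio undefined) are dropped
#' with a warning.
#'
#' @param table a filtered `MeasurementTable`.
#' @param growth data.frame `replicate` -> `t_cc` as returned by
#'   [estimateCellCycle()] (or known truth).
#' @return a `PeptideTrace` data.frame: `protein_id`, `peptide_id`,
#'   `mod_type`, `site_positions`, `replicate`, `time_h`, `phi`.
#' @export
correctGrowth <- function(table, growth) {
  checkMeasurementSchema(table)
  idx <- match(table$replicate, growth$replicate)
  if (anyNA(idx))
    stop("no t_cc estimate for replicate(s): ",
         paste(unique(table$replicate[is.na(idx)]), collapse = ", "))
  ratio <- newOldRatio(table)
  bad <- !is.finite(ratio) | ratio < 0
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped: old-channel intensity is zero or",
            " missing, the new/old ratio cannot be formed")
    table <- table[!bad, , drop = FALSE]
    ratio <- ratio[!bad]
    idx <- idx[!bad]
  }
  phi <- -log(ratio + 1) + (log(2) / growth$t_cc[idx]) * table$time_h
  out <- data.frame(protein_id = table$protein_id,
                    peptide_id = table$peptide_id,
                    mod_type = table$mod_type,
                    site_positions = table$site_positions,
                    replicate = table$replicate,
                    time_h = table$time_h,
                    phi = phi,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-replicate reproducibility filter
#'
#' For each peptide and time point, each replicate's distance to the
#' cross-replicate median of phi is computed; entries farther than
#' `n_sd` standard deviations of the pooled distance distribution of their
#' MS fraction (unmodified or phospho-enriched) are removed. Applied once,
#' not iteratively.
#'
#' @param traces a `PeptideTrace` data.frame.
#' @param n_sd cutoff in pooled-distance standard deviations (default 2).
#' @return list with `traces` (filtered) and `report` (per fraction: number
#'   and percentage removed).
#' @export
reproducibilityFilter <- function(traces, n_sd = 2) {
  frac <- fractionOf(traces$mod_type)
  key <- pasteKey(traces$peptide_id, traces$mod_type, traces$time_h)
  med <- stats::ave(traces$phi, key, FUN = median)
  dist <- abs(traces$phi - med)
  keep <- rep(TRUE, nrow(traces))
  rep_rows <- lapply(unique(frac), function(f) {
    i <- which(frac == f)
    s <- sd(dist[i])
    # the 1e-9 floor keeps floating-point dust on effectively identical
    # replicates from being flagged
    drop <- if (is.finite(s) && s > 0)
      dist[i] > n_sd * s & dist[i] > 1e-9 else rep(FALSE, length(i))
    keep[i[drop]] <<- FALSE
    data.frame(fraction = f, n = length(i), removed = sum(drop),
               pct_removed = 100 * mean(drop))
  })
  list(traces = traces[keep, , drop = FALSE],
       report = do.call(rbind, rep_rows))
}

#' Collate modified and unmodified peptides at the site level
#'
#' Pairs peptides covering the same modified residue of a protein regardless
#' of their tryptic boundaries (modification-induced miscleavage shifts
#' peptide boundaries, so matching is by (protein, site position), not by
#' sequence). Phosphosites pair phosphopeptides with unmodified-fraction
#' peptides covering the residue; N-terminal sites pair the acetylated form
#' with the unprocessed intermediate.
#'
#' @param traces a `PeptideTrace` data.frame with `site_positions` populated
#'   (comma-separated 1-based residue positions) for site-covering peptides.
#' @return a `SitePairing` data.frame: `protein_id`, `site_position`,
#'   `mod_kind`, `modified_peptides`, `unmodified_peptides` (comma-separated
#'   peptide ids; empty string when no counterpart is measured).
#' @export
collateSites <- function(traces) {
  has_site <- !is.na(traces$site_positions) & traces$site_positions != ""
  st <- unique(traces[has_site,
                      c("protein_id", "peptide_id", "mod_type",
                        "site_positions")])
  if (!nrow(st))
    return(data.frame(protein_id = character(), site_position = integer(),
                      mod_kind = character(), modified_peptides = character(),
                      unmodified_peptides = character(),
                      stringsAsFactors = FALSE))
  expand <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    pos <- as.integer(strsplit(st$site_positions[i], ",")[[1]])
    data.frame(protein_id = st$protein_id[i], peptide_id = st$peptide_id[i],
               mod_type = st$mod_type[i], site_position = pos,
               stringsAsFactors = FALSE)
  }))
  keys <- unique(expand[expand$mod_type %in% c("phospho", "nterm_ac"),
                        c("protein_id", "site_position", "mod_type")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    here <- expand[expand$protein_id == k$protein_id &
                     expand$site_position == k$site_position, ]
    counterpart <- if (k$mod_type == "phospho") "none" else "nterm_unprocessed"
    data.frame(
      protein_id = k$protein_id, site_position = k$site_position,
      mod_kind = k$mod_type,
      modified_peptides = paste(sort(unique(
        here$peptide_id[here$mod_type == k$mod_type])), collapse = ","),
      unmodified_peptides = paste(sort(unique(
        here$peptide_id[here$mod_type == counterpart])), collapse = ","),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$protein_id, res$site_position), , drop = FALSE]
}
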