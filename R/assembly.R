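## Assembly-process classification and habitat-scale aggregation.

processLabels <- c("heterogeneous_selection", "homogeneous_selection",
                   "dispersal_limitation", "homogenizing_dispersal",
                   "drift", "unclassified")

scaleLevels <- c("region", "site", "plot", "host")

#' Classify community pairs into assembly processes
#'
#' Maps each pair's (betaNTI, RCbray) values onto the standard
#' selection / dispersal / drift partition:
#' * betaNTI > 2: heterogeneous selection;
#' * betaNTI < -2: homogeneous selection;
#' * otherwise RCbray > 0.95: dispersal limitation;
#' * otherwise RCbray < -0.95: homogenizing dispersal;
#' * otherwise (|RCbray| <= 0.95): drift.
#'
#' All thresholds are strict inequalities, so boundary values (|betaNTI| =
#' 2, |RCbray| = 0.95) fall through to the next rule. Non-finite inputs
#' give `unclassified`. The five regions partition the plane, and
#' `selection` aggregates the two selection labels downstream.
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RCbray values (recycled pairwise with
#'   `bnti`).
#' @return factor with levels
#'   `heterogeneous_selection, homogeneous_selection, dispersal_limitation,
#'    homogenizing_dispersal, drift, unclassified`.
#' @export
classifyPairs <- function(bnti, rc) {
  stopifnot(length(bnti) == length(rc))
  lab <- rep("unclassified", length(bnti))
  ok <- is.finite(bnti) & is.finite(rc)
  lab[ok] <- "drift"
  lab[ok & rc > 0.95] <- "dispersal_limitation"
  lab[ok & rc < -0.95] <- "homogenizing_dispersal"
  lab[ok & bnti > 2] <- "heterogeneous_selection"
  lab[ok & bnti < -2] <- "homogeneous_selection"
  factor(lab, levels = processLabels)
}

## Per-scale counts and percentages (over classified pairs) including the
## selection aggregate.
summarizeProcesses <- function(pairs) {
  out <- lapply(split(pairs, pairs$level), function(pp) {
    tab <- table(factor(pp$process, levels = processLabels))
    nClassified <- sum(tab) - tab[["unclassified"]]
    agg <- tab[["heterogeneous_selection"]] + tab[["homogeneous_selection"]]
    proc <- c(processLabels, "selection")
    nn <- c(as.integer(tab), as.integer(agg))
    pct <- ifelse(proc == "unclassified", NA_real_,
                  if (nClassified > 0) 100 * nn / nClassified else NA_real_)
    pct[proc == "unclassified"] <- NA_real_
    data.frame(level = pp$level[1], process = proc, n = nn,
               pct = pct, n_classified = nClassified,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$level <- factor(res$level, levels = intersect(scaleLevels, res$level))
  res <- res[order(res$level), ]
  rownames(res) <- NULL
  res
}

#' Partition community turnover into assembly processes across scales
#'
#' At each requested habitat scale, betaNTI ([betaNti()]) and RCbray
#' ([rcBray()]) are computed with the null pool restricted to each unit's
#' samples, every within-unit pair is classified with [classifyPairs()],
#' and counts are aggregated over units of the level. The relative
#' contribution of a process at a scale is the number (and percentage) of
#' community-community turnovers assigned to it. Pairs spanning two units
#' at a level are not evaluated at that level: the null pool is defined
#' per unit. Units with fewer than `minUnit` samples are skipped with a
#' warning.
#'
#' @param ds an [AssemblyDataset].
#' @param levels habitat scales to evaluate (subset of
#'   `region, site, plot, host`).
#' @param nNull null replicates for both null models.
#' @param seed integer seed; per-unit child seeds are derived from it
#'   deterministically.
#' @param weighted abundance weighting for betaMNTD (default TRUE).
#' @param minUnit minimum samples per unit (default 2).
#' @return an [AssemblyPartition].
#' @export
partitionByScale <- function(ds, levels = scaleLevels, nNull = 999,
                             seed = NULL, weighted = TRUE, minUnit = 2L) {
  levels <- match.arg(levels, scaleLevels, several.ok = TRUE)
  allPairs <- list()
  uidx <- 0L
  for (lev in levels) {
    units <- scaleUnits(ds, lev)
    for (u in unique(units)) {
      uidx <- uidx + 1L
      pool <- sampleNames(ds)[units == u]
      if (length(pool) < minUnit) {
        warning("skipping unit '", u, "' at level '", lev, "': ",
                length(pool), " sample(s)", call. = FALSE)
        next
      }
      bn <- betaNti(ds, pool, nNull = nNull, seed = subSeed(seed, 2L * uidx),
                    weighted = weighted, poolId = u)
      rc <- rcBray(ds, pool, nNull = nNull, seed = subSeed(seed, 2L * uidx + 1L),
                   poolId = u)
      lb <- turnoverLong(bn)
      lr <- turnoverLong(rc)
      allPairs[[length(allPairs) + 1L]] <- data.frame(
        level = lev, unit = u,
        sample_a = lb$sample_a, sample_b = lb$sample_b,
        bnti = ifelse(lb$valid, lb$value, NA_real_),
        rcbray = ifelse(lr$valid, lr$value, NA_real_),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(allPairs)) stop("no unit with >= ", minUnit, " samples at any level")
  pairs <- do.call(rbind, allPairs)
  pairs$process <- classifyPairs(pairs$bnti, pairs$rcbray)
  new("AssemblyPartition", pairs = pairs,
      byScale = summarizeProcesses(pairs),
      params = list(levels = levels, nNull = nNull, seed = seed,
                    weighted = weighted, minUnit = minUnit))
}

#' Chi-square test of a process's proportion across scales
#'
#' Tests whether the proportion of pairs assigned to one assembly process
#' differs across habitat scales: a chi-square test of homogeneity (no
#' continuity correction) on the 2 x S table of (assigned to process,
#' assigned to any other process) by scale, df = S - 1. `process =
#' "selection"` aggregates the two selection labels. With
#' `omnibus = TRUE` a single test on the full process-by-scale table is
#' returned instead.
#'
#' @param x an [AssemblyPartition] (or its `assemblyPairs()` data.frame).
#' @param process one of the five process labels or `"selection"`.
#' @param omnibus test the full 5 x S table instead of assigned-vs-not.
#' @return data.frame with `process`, `chisq`, `df`, `p`, `min_expected`
#'   and a `warning` flag set when any expected cell < 1.
#' @export
chiSquareAcrossScales <- function(x, process = "selection", omnibus = FALSE) {
  pairs <- if (is(x, "AssemblyPartition")) assemblyPairs(x) else x
  pairs <- pairs[pairs$process != "unclassified" & !is.na(pairs$process), ]
  lev <- unique(as.character(pairs$level))
  if (length(lev) < 2L) stop("need >= 2 scales with classified pairs")
  if (omnibus) {
    tab <- table(factor(as.character(pairs$process)),
                 factor(pairs$level, levels = lev))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(data.frame(process = "omnibus",
                      chisq = unname(ct$statistic), df = unname(ct$parameter),
                      p = ct$p.value, min_expected = min(ct$expected),
                      warning = min(ct$expected) < 1))
  }
  assigned <- if (process == "selection") {
    pairs$process %in% c("heterogeneous_selection", "homogeneous_selection")
  } else {
    stopifnot(process %in% processLabels)
    pairs$process == process
  }
  tab <- rbind(
    yes = tapply(assigned, factor(pairs$level, levels = lev), sum),
    no  = tapply(!assigned, factor(pairs$level, levels = lev), sum)
  )
  if (any(rowSums(tab) == 0)) {
    ## degenerate homogeneity table: all (or none) assigned everywhere
    return(data.frame(process = process, chisq = 0, df = length(lev) - 1L,
                      p = 1, min_expected = min(rowSums(tab)), warning = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  data.frame(process = process,
             chisq = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value, min_expected = min(ct$expected),
             warning = min(ct$expected) < 1)
}

#' NTI by habitat scale with t and Tukey tests
#'
#' Computes per-sample NTI ([ntiScores()]) at each habitat scale with the
#' null pool restricted to the sample's unit, then (a) tests the mean NTI
#' at each scale against 0 with a two-sided one-sample t test (positive
#' mean = phylogenetic clustering), and (b) compares scales with all-pairs
#' Tukey HSD on a one-way ANOVA of NTI by scale.
#'
#' @inheritParams partitionByScale
#' @return list with `values` (per sample x scale NTI data.frame),
#'   `summary` (per-scale mean, sd, n, t, p), and `tukey` (pairwise scale
#'   contrasts; `NULL` if fewer than 2 scales).
#' @export
ntiByScale <- function(ds, levels = scaleLevels, nNull = 999, seed = NULL,
                       weighted = TRUE, minUnit = 2L) {
  levels <- match.arg(levels, scaleLevels, several.ok = TRUE)
  vals <- list()
  uidx <- 0L
  for (lev in levels) {
    units <- scaleUnits(ds, lev)
    for (u in unique(units)) {
      uidx <- uidx + 1L
      pool <- sampleNames(ds)[units == u]
      if (length(pool) < minUnit) {
        warning("skipping unit '", u, "' at level '", lev, "': ",
                length(pool), " sample(s)", call. = FALSE)
        next
      }
      nt <- ntiScores(ds, pool, nNull = nNull, seed = subSeed(seed, uidx),
                      weighted = weighted)
      nt$level <- lev
      nt$unit <- u
      vals[[length(vals) + 1L]] <- nt
    }
  }
  values <- do.call(rbind, vals)
  smry <- do.call(rbind, lapply(split(values, values$level), function(vv) {
    x <- vv$nti[vv$valid]
    if (length(x) < 2L) stop("fewer than 2 valid NTI values at level ", vv$level[1])
    if (sd(x) < 1e-12) stop("degenerate (all-identical) NTI values at level ", vv$level[1])
    tt <- t.test(x, mu = 0)
    data.frame(level = vv$level[1], n = length(x), mean_nti = mean(x),
               sd_nti = sd(x), t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  smry$level <- factor(smry$level, levels = intersect(scaleLevels, smry$level))
  smry <- smry[order(smry$level), ]
  rownames(smry) <- NULL
  tk <- NULL
  if (length(unique(values$level)) >= 2L) {
    vv <- values[values$valid, ]
    fit <- aov(nti ~ factor(level, levels = unique(level)), data = vv)
    th <- TukeyHSD(fit)[[1]]
    tk <- data.frame(contrast = rownames(th), th, row.names = NULL,
                     check.names = FALSE)
  }
  list(values = values, summary = smry, tukey = tk)
}
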