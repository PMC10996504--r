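# Per-unit sensory-response statistics: trial window counts with
# cross-modal overlap exclusion, ANOVA + Holm-Bonferroni response
# classification with post-hoc signed-rank labeling, the selectivity
# index SI, response latency from 10-ms PSTHs, offset-period group
# comparisons, and the anatomical-position linear model of selectivity.

#' Presentations retained after cross-modal overlap exclusion
#'
#' A presentation is dropped when any stimulus of the *other* modality has
#' an onset within 6 s of its own onset (symmetric: both members of a
#' close pair are dropped).
#'
#' @param schedule A [stim_schedule()].
#' @param overlap_window_s Exclusion distance between onsets of different
#'   modalities (default 6 s, inclusive).
#' @return Logical vector over `schedule$events` rows: `TRUE` = retained.
#' @export
retained_presentations <- function(schedule, overlap_window_s = 6) {
  ev <- schedule$events
  on_t <- ev$onset_s[ev$modality == "tactile"]
  on_v <- ev$onset_s[ev$modality == "visual"]
  near_other <- function(x, other) {
    if (length(other) == 0L) {
      return(rep(FALSE, length(x)))
    }
    vapply(x, function(o) any(abs(other - o) <= overlap_window_s), logical(1))
  }
  keep <- rep(TRUE, nrow(ev))
  keep[ev$modality == "tactile"] <- !near_other(on_t, on_v)
  keep[ev$modality == "visual"] <- !near_other(on_v, on_t)
  keep
}

#' Trial window spike counts for one unit
#'
#' One row per retained presentation. Baseline window `(onset-1, onset-0.05]`,
#' stimulus window `(onset+0.05, onset+1]` (the +/-50 ms band around onset
#' is ambiguous and excluded), offset window `(offset, offset+2]`.
#'
#' @param spike_times Sorted spike times, seconds.
#' @param schedule A [stim_schedule()].
#' @param overlap_window_s Cross-modal exclusion distance (default 6 s).
#' @param ambiguity_s Half-width of the excluded onset band (default 0.05).
#' @param window_s Length of the baseline/stimulus analysis windows (1 s).
#' @param offset_window_s Length of the post-offset window (2 s).
#' @return Data frame of class `trial_windows`: `stim_id`, `modality`,
#'   `rewarded`, `onset_s`, counts and rates per window. Empty (with a
#'   message) when no presentation is retained.
#' @export
build_trial_windows <- function(spike_times, schedule, overlap_window_s = 6,
                                ambiguity_s = 0.05, window_s = 1,
                                offset_window_s = 2) {
  ev <- schedule$events
  keep <- retained_presentations(schedule, overlap_window_s)
  idx <- which(keep)
  if (length(idx) == 0L) {
    message("no presentations retained after overlap exclusion")
  }
  on <- ev$onset_s[idx]
  off <- on + ev$duration_s[idx]
  blen <- window_s - ambiguity_s
  base_n <- count_in_windows(spike_times, on - window_s, on - ambiguity_s)
  stim_n <- count_in_windows(spike_times, on + ambiguity_s, on + window_s)
  off_n <- count_in_windows(spike_times, off, off + offset_window_s)
  out <- data.frame(
    stim_id = idx,
    modality = ev$modality[idx],
    rewarded = ev$rewarded[idx],
    onset_s = on,
    baseline_count = base_n,
    stimulus_count = stim_n,
    offset_count = off_n,
    baseline_rate = base_n / blen,
    stimulus_rate = stim_n / blen,
    offset_rate = off_n / offset_window_s
  )
  class(out) <- c("trial_windows", class(out))
  out
}

#' Selectivity index
#'
#' `SI = (|FR_A - FR_B| - |FR_V - FR_B|) / (|FR_A - FR_B| + |FR_V - FR_B|)`.
#' +1: the unit responds only to the air puff; -1: only to the drifting
#' grating; 0: equal-magnitude responses to both. Undefined (`NA`) when
#' both absolute deviations are zero.
#'
#' @param fr_b Mean baseline firing rate (Hz).
#' @param fr_a Mean air-puff stimulus-period rate (Hz).
#' @param fr_v Mean visual stimulus-period rate (Hz).
#' @return SI in `[-1, 1]`, or `NA`. Vectorized.
#' @examples
#' selectivity_index(2, 10, 2) # +1
#' selectivity_index(2, 6, 6) # 0
#' selectivity_index(2, 2, 10) # -1
#' @export
selectivity_index <- function(fr_b, fr_a, fr_v) {
  stopifnot(all(is.finite(fr_b)), all(is.finite(fr_a)), all(is.finite(fr_v)))
  da <- abs(fr_a - fr_b)
  dv <- abs(fr_v - fr_b)
  ifelse(da + dv > 0, (da - dv) / (da + dv), NA_real_)
}

# one-way ANOVA p over three groups; NA when untestable (zero variance)
anova3_p <- function(base, puff, grat) {
  y <- c(base, puff, grat)
  g <- factor(rep(c("base", "puff", "grat"), c(
    length(base), length(puff), length(grat)
  )))
  if (length(unique(g)) < 2L || stats::sd(y) == 0) {
    return(NA_real_)
  }
  p <- tryCatch(
    summary(stats::aov(y ~ g))[[1L]][["Pr(>F)"]][1L],
    error = function(e) NA_real_
  )
  if (is.null(p) || !is.finite(p)) NA_real_ else p
}

#' Classify sensory responses across a unit population
#'
#' Per unit, a one-way ANOVA compares three groups of per-presentation
#' rates: all baseline rates (both modalities pooled), air-puff
#' stimulus-period rates, and visual stimulus-period rates. ANOVA p-values
#' are Holm-Bonferroni corrected within each cohort x region family. For
#' corrected-significant units, paired Wilcoxon signed-rank tests of
#' stimulus-period vs same-presentation baseline rates (per modality, at
#' `alpha`, uncorrected) yield the label `none` / `puff` / `grating` /
#' `both`; SI is computed for corrected-significant units only.
#'
#' @param windows_list Named list of [build_trial_windows()] tables.
#' @param units_meta Optional data frame (`unit_id`, `cohort`, `region`)
#'   defining correction families; one family when omitted.
#' @param alpha Significance level (default 0.05).
#' @return Data frame (one row per unit): `unit_id`, trial counts, `fr_b`,
#'   `fr_a`, `fr_v`, `anova_p`, `corrected_p`, `corrected_significant`,
#'   `untestable`, `p_puff`, `p_grating`, `label`, `si`.
#' @export
classify_responses <- function(windows_list, units_meta = NULL, alpha = 0.05) {
  ids <- names(windows_list)
  stopifnot(!is.null(ids), all(nzchar(ids)))
  per_unit <- lapply(ids, function(id) {
    w <- windows_list[[id]]
    wt <- w[w$modality == "tactile", , drop = FALSE]
    wv <- w[w$modality == "visual", , drop = FALSE]
    if (nrow(wt) < 2L || nrow(wv) < 2L) {
      return(data.frame(
        unit_id = id, n_tactile = nrow(wt), n_visual = nrow(wv),
        fr_b = NA_real_, fr_a = NA_real_, fr_v = NA_real_,
        anova_p = NA_real_, untestable = TRUE,
        p_puff = NA_real_, p_grating = NA_real_
      ))
    }
    base_all <- w$baseline_rate
    p <- anova3_p(base_all, wt$stimulus_rate, wv$stimulus_rate)
    data.frame(
      unit_id = id, n_tactile = nrow(wt), n_visual = nrow(wv),
      fr_b = mean(base_all),
      fr_a = mean(wt$stimulus_rate),
      fr_v = mean(wv$stimulus_rate),
      anova_p = p, untestable = is.na(p),
      p_puff = paired_signrank_p(wt$stimulus_rate, wt$baseline_rate),
      p_grating = paired_signrank_p(wv$stimulus_rate, wv$baseline_rate)
    )
  })
  res <- do.call(rbind, per_unit)
  if (is.null(units_meta)) {
    family <- rep("all", nrow(res))
  } else {
    m <- match(res$unit_id, units_meta$unit_id)
    family <- paste(units_meta$cohort[m], units_meta$region[m], sep = ".")
  }
  res$corrected_p <- NA_real_
  for (f in unique(family)) {
    sel <- family == f
    res$corrected_p[sel] <- stats::p.adjust(res$anova_p[sel], method = "holm")
  }
  res$corrected_significant <- !is.na(res$corrected_p) &
    res$corrected_p < alpha
  sig_puff <- res$corrected_significant & res$p_puff < alpha
  sig_grat <- res$corrected_significant & res$p_grating < alpha
  res$label <- ifelse(res$untestable, NA_character_,
    ifelse(sig_puff & sig_grat, "both",
      ifelse(sig_puff, "puff",
        ifelse(sig_grat, "grating", "none")
      )
    )
  )
  res$si <- NA_real_
  sel <- res$corrected_significant
  if (any(sel)) {
    res$si[sel] <- selectivity_index(res$fr_b[sel], res$fr_a[sel], res$fr_v[sel])
  }
  res
}

# latency detector on a binned trial-averaged rate; exposed internally so
# properties (e.g. invariance to a constant rate offset) can be checked
# directly on rate arrays
latency_from_binned <- function(mean_rate, bin_s, n_baseline_bins,
                                max_latency_s = 0.5, z = 2.576,
                                sd_floor = 1e-9) {
  base <- mean_rate[seq_len(n_baseline_bins)]
  m <- mean(base)
  s <- stats::sd(base)
  if (!is.finite(s) || s < sd_floor) {
    message("baseline SD floored at ", sd_floor, " for latency detection")
    s <- sd_floor
  }
  post <- mean_rate[-seq_len(n_baseline_bins)]
  outside <- abs(post - m) > z * s
  max_start <- ceiling(max_latency_s / bin_s)
  n_post <- length(outside)
  for (i in seq_len(min(max_start, n_post - 1L))) {
    if (outside[i] && outside[i + 1L]) {
      return((i - 1L) * bin_s)
    }
  }
  NA_real_
}

#' Sensory response latency of one unit
#'
#' The unit's firing rate is binned at 10 ms and trial-averaged, aligned to
#' retained presentations of one modality. Baseline mean and SD come from
#' the 1-s pre-onset bins. The latency is the left edge of the first bin
#' starting a run of >= 2 consecutive bins whose rate leaves the 99%
#' confidence band (2.576 baseline SDs, two-sided: increases and decreases
#' both count). Units with no such run starting within 500 ms of onset
#' return `NA`.
#'
#' @param spike_times Sorted spike times, seconds.
#' @param schedule A [stim_schedule()].
#' @param modality `"tactile"` or `"visual"`.
#' @param bin_s PSTH bin width (default 0.01 s).
#' @param baseline_s Baseline span before onset (default 1 s).
#' @param max_latency_s Latest allowed run start (default 0.5 s).
#' @param z Threshold multiplier (default 2.576, the 99% normal quantile).
#' @param min_trials Minimum retained presentations (default 10).
#' @param overlap_window_s Cross-modal exclusion distance (default 6 s).
#' @return Latency in seconds, or `NA`.
#' @export
response_latency <- function(spike_times, schedule, modality,
                             bin_s = 0.01, baseline_s = 1,
                             max_latency_s = 0.5, z = 2.576,
                             min_trials = 10, overlap_window_s = 6) {
  modality <- match.arg(modality, c("tactile", "visual"))
  ev <- schedule$events
  keep <- retained_presentations(schedule, overlap_window_s)
  onsets <- ev$onset_s[keep & ev$modality == modality]
  if (length(onsets) < min_trials) {
    stop(sprintf(
      "only %d retained presentations (need >= %d)",
      length(onsets), min_trials
    ), call. = FALSE)
  }
  n_base <- round(baseline_s / bin_s)
  # allow the second bin of a threshold run to start just past max latency
  n_post <- ceiling(max_latency_s / bin_s) + 1L
  edges <- (-n_base:n_post) * bin_s
  counts <- numeric(length(edges) - 1L)
  for (o in onsets) {
    counts <- counts + count_in_windows(
      spike_times, o + edges[-length(edges)], o + edges[-1L]
    )
  }
  mean_rate <- counts / (length(onsets) * bin_s)
  latency_from_binned(mean_rate, bin_s, n_base, max_latency_s, z)
}

#' Offset-period and stimulus-period group comparisons
#'
#' Per unit and modality, the baseline-subtracted rate change during the
#' stimulus period and the 2-s post-offset period. Within each cohort,
#' paired signed-rank tests compare the air-puff and grating changes; a
#' between-factor two-way ANOVA (conditioning type x stimulus type) tests
#' the population structure of each period.
#'
#' @param windows_list Named list of [build_trial_windows()] tables.
#' @param units_meta Data frame with `unit_id` and `cohort`.
#' @return List: `per_unit` (long data frame of rate changes), `wilcoxon`
#'   (per cohort x period), `anova` (per period; `NULL` with one cohort).
#' @export
offset_period_analysis <- function(windows_list, units_meta) {
  ids <- names(windows_list)
  rows <- lapply(ids, function(id) {
    w <- windows_list[[id]]
    cohort <- units_meta$cohort[match(id, units_meta$unit_id)]
    per_mod <- lapply(c("tactile", "visual"), function(m) {
      wm <- w[w$modality == m, , drop = FALSE]
      if (nrow(wm) == 0L) {
        return(NULL)
      }
      data.frame(
        unit_id = id, cohort = cohort, modality = m,
        d_stimulus = mean(wm$stimulus_rate - wm$baseline_rate),
        d_offset = mean(wm$offset_rate - wm$baseline_rate)
      )
    })
    do.call(rbind, per_mod)
  })
  per_unit <- do.call(rbind, rows)
  cohorts <- unique(per_unit$cohort)
  wilcox <- do.call(rbind, lapply(cohorts, function(co) {
    d <- per_unit[per_unit$cohort == co, ]
    wide <- merge(
      d[d$modality == "tactile", c("unit_id", "d_stimulus", "d_offset")],
      d[d$modality == "visual", c("unit_id", "d_stimulus", "d_offset")],
      by = "unit_id", suffixes = c("_puff", "_grating")
    )
    data.frame(
      cohort = co,
      period = c("stimulus", "offset"),
      p = c(
        paired_signrank_p(wide$d_stimulus_puff, wide$d_stimulus_grating),
        paired_signrank_p(wide$d_offset_puff, wide$d_offset_grating)
      ),
      median_diff = c(
        stats::median(wide$d_stimulus_puff - wide$d_stimulus_grating),
        stats::median(wide$d_offset_puff - wide$d_offset_grating)
      )
    )
  }))
  anova_tab <- NULL
  if (length(cohorts) >= 2L) {
    anova_tab <- lapply(
      stats::setNames(nm = c("d_stimulus", "d_offset")),
      function(v) {
        fit <- stats::aov(
          per_unit[[v]] ~ factor(per_unit$cohort) * factor(per_unit$modality)
        )
        tab <- summary(fit)[[1L]]
        data.frame(
          term = c("conditioning", "stimulus", "interaction"),
          F = tab[["F value"]][1:3],
          p = tab[["Pr(>F)"]][1:3]
        )
      }
    )
  }
  list(per_unit = per_unit, wilcoxon = wilcox, anova = anova_tab)
}

#' Linear model of selectivity index on anatomical position
#'
#' Least-squares fit of `SI ~ DV + ML + AP + CT + CT:DV + CT:ML + CT:AP`
#' where CT is the two-level conditioning-type factor. Requires >= 20
#' units with defined SI and both cohorts present; a rank-deficient design
#' is rejected.
#'
#' @param si_table Data frame with columns `si`, `ap_mm`, `dv_mm`, `ml_mm`,
#'   `cohort`.
#' @param min_units Minimum number of complete rows (default 20).
#' @return Object of class `position_model_fit`: `coefficients` (term,
#'   estimate, p), `model_p`, `adjusted_r2`, `n`, and the underlying `lm`
#'   fit.
#' @export
position_selectivity_model <- function(si_table, min_units = 20) {
  d <- si_table[
    is.finite(si_table$si) & is.finite(si_table$ap_mm) &
      is.finite(si_table$dv_mm) & is.finite(si_table$ml_mm),
    ,
    drop = FALSE
  ]
  if (nrow(d) < min_units) {
    stop(sprintf(
      "need >= %d units with defined SI (got %d)", min_units, nrow(d)
    ), call. = FALSE)
  }
  if (length(unique(d$cohort)) < 2L) {
    stop("both conditioning cohorts must be present", call. = FALSE)
  }
  d$ct <- factor(d$cohort)
  X <- stats::model.matrix(~ (dv_mm + ml_mm + ap_mm) * ct, data = d)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (degenerate positions?)",
      call. = FALSE
    )
  }
  fit <- stats::lm(si ~ (dv_mm + ml_mm + ap_mm) * ct, data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  structure(
    list(
      coefficients = data.frame(
        term = rownames(sm$coefficients),
        estimate = sm$coefficients[, "Estimate"],
        p = sm$coefficients[, "Pr(>|t|)"],
        row.names = NULL
      ),
      model_p = unname(model_p),
      adjusted_r2 = sm$adj.r.squared,
      n = nrow(d),
      fit = fit
    ),
    class = "position_model_fit"
  )
}

#' @export
print.position_model_fit <- function(x, ...) {
  cat(sprintf(
    "<position_model_fit> n = %d, model p = %.3g, adj R^2 = %.3f\n",
    x$n, x$model_p, x$adjusted_r2
  ))
  print(x$coefficients, digits = 3)
  invisible(x)
}
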