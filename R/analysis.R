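#' Analysis frequencies
#'
#' The detailed analysis is run at five frequencies of diagnostic and
#' therapeutic interest within the sweep: 3, 30, 300, 607 and 1000 kHz.
#'
#' @param targets_khz target frequencies, kHz.
#' @return numeric vector (kHz) with class `analysis_frequencies`.
#' @export
analysis_frequencies <- function(targets_khz = c(3, 30, 300, 607, 1000)) {
  t <- as.numeric(targets_khz)
  if (!length(t) || anyNA(t) || any(t <= 0))
    stop_config("analysis frequencies must be positive")
  structure(t, class = "analysis_frequencies")
}

# Round half away from zero (report rendering; R's round() is banker's).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pick grid frequencies nearest to the analysis targets
#'
#' For each target the nearest grid frequency is selected (ties broken toward
#' the lower frequency) and reported alongside the conductivity there, so
#' downstream tables always state the frequency actually used.
#'
#' @param spec a [conductivity_spectrum()].
#' @param targets an [analysis_frequencies()] (kHz).
#' @return data frame: `target_khz`, `frequency_hz` (grid point used),
#'   `sigma` (S/m).
#' @export
pick_frequencies <- function(spec, targets = analysis_frequencies()) {
  stopifnot(inherits(spec, "conductivity_spectrum"))
  t_hz <- as.numeric(targets) * 1e3
  f <- spec$frequency
  if (any(t_hz < min(f)) || any(t_hz > max(f)))
    stop_config("target frequency outside the grid span [%g, %g] Hz", min(f), max(f))
  idx <- vapply(t_hz, function(t) {
    d <- abs(f - t)
    which(d == min(d))[1L]   # ties: lower frequency (grid is increasing)
  }, integer(1))
  data.frame(target_khz = as.numeric(targets), frequency_hz = f[idx],
             sigma = spec$sigma[idx])
}

#' Per-group conductivity summaries at the analysis frequencies
#'
#' Sample mean and sample SD (n - 1 denominator) of conductivity per
#' (tissue class, state) group - optionally split further by tumor type - at
#' each target frequency. Cirrhotic records form their own class and are
#' never pooled with normal tissue. Groups of one report the mean only (SD is
#' absent, not zero).
#'
#' @param cohort calibrated cohort (records carrying conductivity spectra).
#' @param targets an [analysis_frequencies()].
#' @param by_tumor_type split tumor groups by tumor type (HCC / MET / CCA)?
#' @return data frame: `tissue_class`, `state`, (`tumor_type`,)
#'   `frequency_khz`, `frequency_hz_used`, `n`, `mean`, `sd` (NA when n = 1).
#' @export
summarize_groups <- function(cohort, targets = analysis_frequencies(),
                             by_tumor_type = FALSE) {
  if (!length(cohort)) stop_data("empty cohort")
  rows <- list()
  for (rec in cohort) {
    if (!inherits(rec$spectrum, "conductivity_spectrum"))
      stop_data("record '%s' is not calibrated (no conductivity spectrum)",
                rec$patient_id)
    pk <- pick_frequencies(rec$spectrum, targets)
    rows[[length(rows) + 1L]] <- data.frame(
      tissue_class = rec$tissue_class, state = rec$state,
      tumor_type = rec$tumor_type, target_khz = pk$target_khz,
      frequency_hz = pk$frequency_hz, sigma = pk$sigma)
  }
  df <- do.call(rbind, rows)
  keys <- if (by_tumor_type)
    c("tissue_class", "state", "tumor_type", "target_khz") else
    c("tissue_class", "state", "target_khz")
  agg <- do.call(rbind, lapply(split(df, df[keys], drop = TRUE), function(g) {
    out <- g[1L, keys, drop = FALSE]
    out$frequency_hz_used <- g$frequency_hz[1L]
    out$n <- nrow(g)
    out$mean <- mean(g$sigma)
    out$sd <- if (nrow(g) > 1L) stats::sd(g$sigma) else NA_real_
    out
  }))
  names(agg)[names(agg) == "target_khz"] <- "frequency_khz"
  agg <- agg[order(agg$tissue_class, agg$state, agg$frequency_khz), ]
  rownames(agg) <- NULL
  agg
}

#' Conductivity ratios between tissue conditions
#'
#' The six ratios of group *means* reported per frequency:
#' Tin/Nin, Tin/Tex, Tex/Nin, Tin/Cin, Tex/Cin, Nin/Cin, where T/N/C denote
#' tumor / normal / cirrhotic and in/ex the in vivo / ex vivo state. Defined
#' as ratio-of-means (not mean of per-patient ratios) because group sizes are
#' unequal and unpaired. Values are reported raw and rounded to 1 decimal
#' (half away from zero).
#'
#' @param summaries output of [summarize_groups()] (not split by tumor type),
#'   or any data frame with columns `tissue_class`, `state`, `frequency_khz`,
#'   `mean`.
#' @return data frame: `frequency_khz`, `ratio` (label), `numerator`,
#'   `denominator`, `value` (raw), `value_rounded`.
#' @export
ratio_table <- function(summaries) {
  need <- c("tissue_class", "state", "frequency_khz", "mean")
  if (!all(need %in% names(summaries)))
    stop_config("summaries must have columns %s", paste(need, collapse = ", "))
  defs <- data.frame(
    ratio = c("Tin/Nin", "Tin/Tex", "Tex/Nin", "Tin/Cin", "Tex/Cin", "Nin/Cin"),
    num_class = c("tumor", "tumor", "tumor", "tumor", "tumor", "normal"),
    num_state = c("in_vivo", "in_vivo", "ex_vivo", "in_vivo", "ex_vivo", "in_vivo"),
    den_class = c("normal", "tumor", "normal", "cirrhotic", "cirrhotic", "cirrhotic"),
    den_state = c("in_vivo", "ex_vivo", "in_vivo", "in_vivo", "in_vivo", "in_vivo"))
  grp_mean <- function(cl, st, fk) {
    m <- summaries$mean[summaries$tissue_class == cl & summaries$state == st &
                        summaries$frequency_khz == fk]
    if (length(m) != 1L) NA_real_ else m
  }
  out <- list()
  for (fk in sort(unique(summaries$frequency_khz))) {
    for (i in seq_len(nrow(defs))) {
      num <- grp_mean(defs$num_class[i], defs$num_state[i], fk)
      den <- grp_mean(defs$den_class[i], defs$den_state[i], fk)
      out[[length(out) + 1L]] <- data.frame(
        frequency_khz = fk, ratio = defs$ratio[i],
        numerator = num, denominator = den, value = num / den)
    }
  }
  out <- do.call(rbind, out)
  if (anyNA(out$value)) {
    miss <- unique(out$ratio[is.na(out$value)])
    stop_data("missing group(s) for ratio(s): %s", paste(miss, collapse = ", "))
  }
  out$value_rounded <- round_half_away(out$value, 1)
  out
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Omnibus nonparametric comparison of k groups. Mid-ranks are assigned over
#' the pooled sample; the statistic is
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar r_i - \tfrac{N+1}{2})^2,}
#' corrected for ties by \eqn{H^* = H / (1 - \sum (t^3 - t)/(N^3 - N))}, and
#' referred to the chi-square distribution with k - 1 degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors of conductivities (each n >= 1,
#'   total N >= 3).
#' @return list with class `kw_result`: `h_statistic` (tie-corrected),
#'   `h_uncorrected`, `degrees_freedom`, `p_value`, `tie_corrected` (logical:
#'   were ties present), `n_total`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_config("kruskal_wallis() needs a list of at least two groups")
  x <- lapply(groups, function(g) {
    g <- as.numeric(g)
    if (!length(g) || anyNA(g) || any(!is.finite(g)))
      stop_data("groups must be non-empty, finite and non-missing")
    g
  })
  n_i <- lengths(x)
  pooled <- unlist(x, use.names = FALSE)
  N <- length(pooled)
  if (N < 3L) stop_data("Kruskal-Wallis needs a total of at least 3 observations")
  if (length(unique(pooled)) == 1L)
    stop_analysis("degenerate data: all observations identical, ranks are uninformative")
  r <- rank(pooled)           # mid-ranks
  idx <- rep(seq_along(x), n_i)
  rbar <- tapply(r, idx, mean)
  H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  tie_sizes <- table(pooled)
  ties <- tie_sizes[tie_sizes > 1L]
  correction <- 1 - sum(as.numeric(ties)^3 - as.numeric(ties)) / (N^3 - N)
  H_star <- H / correction
  df <- length(x) - 1L
  p <- stats::pchisq(H_star, df, lower.tail = FALSE)
  structure(list(h_statistic = H_star, h_uncorrected = H,
                 degrees_freedom = df, p_value = p,
                 tie_corrected = length(ties) > 0L, n_total = N),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f (df = %d), p = %.4g%s\n",
              x$h_statistic, x$degrees_freedom, x$p_value,
              if (x$tie_corrected) " [tie-corrected]" else ""))
  invisible(x)
}

#' Per-frequency significance report
#'
#' Runs the tie-corrected Kruskal-Wallis test across the cohort's
#' (tissue class, state) groups at each analysis frequency and flags
#' p < alpha.
#'
#' @param cohort calibrated cohort.
#' @param targets an [analysis_frequencies()].
#' @param alpha significance level (default 0.05).
#' @return data frame: `frequency_khz`, `n_groups`, `h_statistic`,
#'   `degrees_freedom`, `p_value`, `significant`.
#' @export
significance_report <- function(cohort, targets = analysis_frequencies(),
                                alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop_config("alpha must be in (0, 1]")
  out <- list()
  for (fk in as.numeric(targets)) {
    vals <- list()
    for (rec in cohort) {
      pk <- pick_frequencies(rec$spectrum, analysis_frequencies(fk))
      key <- paste(rec$tissue_class, rec$state, sep = "/")
      vals[[key]] <- c(vals[[key]], pk$sigma)
    }
    kw <- kruskal_wallis(vals)
    out[[length(out) + 1L]] <- data.frame(
      frequency_khz = fk, n_groups = length(vals),
      h_statistic = kw$h_statistic, degrees_freedom = kw$degrees_freedom,
      p_value = kw$p_value, significant = kw$p_value < alpha)
  }
  do.call(rbind, out)
}
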