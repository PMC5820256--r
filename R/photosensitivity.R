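#' Classify one unit as photosensitive
#'
#' A unit is photosensitive when its ON-period spike distribution is
#' inconsistent with the rate model fitted on the OFF (pre-stimulation)
#' period. The procedure:
#' \enumerate{
#'   \item fit the OFF model (\code{kind}, default constant — tonic
#'     subthalamic firing) on the first half of OFF and self-check it with
#'     the four Ogata tests on the held-out second half (rescaled under the
#'     first-half fit). A failed self-check means the OFF model itself
#'     misfits; the unit is flagged unclassifiable and excluded from
#'     population fractions;
#'   \item refit the model on the full OFF period, rescale the ON spikes
#'     under it, and run the Ogata suite on them;
#'   \item photosensitive = (OFF self-check passes) AND (ON under the OFF
#'     model is rejected overall).
#' }
#' Mean rates of all three periods and the ON firing-rate change
#' (100 x (on - off) / off, defined when the OFF rate is positive) are
#' always populated.
#'
#' @param record a \code{\link{spike_record}} with all three periods.
#' @param config a \code{\link{run_config}} (uses \code{gof_alpha}).
#' @param kind OFF model family passed to \code{\link{fit_rate}}.
#' @param bandwidth_or_binwidth_s passed to \code{\link{fit_rate}} for
#'   non-constant kinds.
#' @return an object of class \code{unit_decision}: \code{unit_id},
#'   \code{photosensitive} (TRUE/FALSE, or NA when unclassifiable),
#'   \code{gof_on_vs_off}, \code{gof_off_selfcheck} (both
#'   \code{gof_report}s), \code{rate_off_hz}, \code{rate_on_hz},
#'   \code{rate_post_hz}, \code{pct_change_on}.
#' @export
classify_photosensitive <- function(record, config = run_config(),
                                    kind = "constant",
                                    bandwidth_or_binwidth_s = 1) {
  stopifnot(inherits(record, "spike_record"))
  validate_run_config(config)
  alpha <- config$gof_alpha

  off <- period_spikes(record, "OFF")
  on <- period_spikes(record, "ON")
  post <- period_spikes(record, "POST")
  rate_off <- length(off$times) / off$duration
  rate_on <- length(on$times) / on$duration
  rate_post <- length(post$times) / post$duration

  # OFF self-check: fit on first half, Ogata on held-out second half
  mid <- off$start + off$duration / 2
  first_half <- make_subrecord(record, off$start, mid)
  fit_half <- fit_rate(first_half, "OFF", kind, bandwidth_or_binwidth_s)
  held <- off$times[off$times > mid]
  # rescale held-out spikes by extending the fitted intensity over the
  # second half (the fitted profile is tiled forward in time)
  tau_self <- extend_rescale(fit_half, held, mid, off$end)
  gof_self <- ogata_tests(tau_self$tau, tau_self$total, alpha,
                          estimation_events = fit_half$n_events)

  # ON under the full-OFF model
  fit_full <- fit_rate(record, "OFF", kind, bandwidth_or_binwidth_s)
  tau_on <- extend_rescale(fit_full, on$times, on$start, on$end)
  gof_on <- ogata_tests(tau_on$tau, tau_on$total, alpha,
                        estimation_events = fit_full$n_events)

  photosensitive <- if (gof_self$overall_reject) NA else gof_on$overall_reject
  if (is.na(photosensitive))
    ot_log("classify_photosensitive: unit ", record$unit_id,
           " OFF self-check failed; unit unclassifiable", level = "warn")

  structure(list(unit_id = record$unit_id,
                 photosensitive = photosensitive,
                 gof_on_vs_off = gof_on,
                 gof_off_selfcheck = gof_self,
                 rate_off_hz = rate_off, rate_on_hz = rate_on,
                 rate_post_hz = rate_post,
                 pct_change_on = if (rate_off > 0)
                   100 * (rate_on - rate_off) / rate_off else NA_real_),
            class = "unit_decision")
}

#' Assemble a unit decision from externally determined values
#'
#' Builds a \code{unit_decision} without running the classifier — for
#' aggregating decisions made elsewhere (another session, another lab's
#' classification) into \code{\link{population_stats}}. Per-period rates
#' default to NA and are then excluded from rate summaries.
#'
#' @param unit_id unit identifier.
#' @param photosensitive TRUE/FALSE, or NA for unclassifiable.
#' @param rate_off_hz,rate_on_hz,rate_post_hz optional mean rates, Hz.
#' @return an object of class \code{unit_decision}.
#' @export
unit_decision <- function(unit_id, photosensitive,
                          rate_off_hz = NA_real_, rate_on_hz = NA_real_,
                          rate_post_hz = NA_real_) {
  stopifnot(is.logical(photosensitive), length(photosensitive) == 1)
  structure(list(unit_id = unit_id, photosensitive = photosensitive,
                 gof_on_vs_off = NULL, gof_off_selfcheck = NULL,
                 rate_off_hz = rate_off_hz, rate_on_hz = rate_on_hz,
                 rate_post_hz = rate_post_hz,
                 pct_change_on = if (!is.na(rate_off_hz) && rate_off_hz > 0)
                   100 * (rate_on_hz - rate_off_hz) / rate_off_hz
                 else NA_real_),
            class = "unit_decision")
}

#' @export
print.unit_decision <- function(x, ...) {
  cat(sprintf(
    "unit_decision: %s  photosensitive = %s  rates OFF/ON/POST = %.2f/%.2f/%.2f Hz (%+.1f%%)\n",
    x$unit_id, ifelse(is.na(x$photosensitive), "unclassifiable",
                      x$photosensitive),
    x$rate_off_hz, x$rate_on_hz, x$rate_post_hz, x$pct_change_on))
  invisible(x)
}

# A spike_record restricted to [t0, t1] within the OFF period, with OFF
# bounds replaced (used for the half-OFF fit). ON/POST bounds are kept.
make_subrecord <- function(record, t0, t1) {
  pb <- record$period_bounds_s
  pb$start_s[pb$period == "OFF"] <- t0
  pb$end_s[pb$period == "OFF"] <- t1
  keep <- record$spike_times_s
  off_row <- pb[pb$period == "OFF", ]
  in_any <- vapply(keep, function(t)
    any(t >= pb$start_s & t <= pb$end_s), logical(1))
  spike_record(record$unit_id, keep[in_any], pb, record$subject_id)
}

# Rescale spikes on [t0, t1] under a model fitted on another interval, by
# translating the model's intensity onto [t0, t1]: constant models extend
# naturally; piecewise/kernel models are applied modulo their own span
# (the fitted profile is tiled). Returns tau and the Lambda-span.
extend_rescale <- function(model, times, t0, t1) {
  span <- model$t1 - model$t0
  shift <- function(t) {
    # map analysis time onto the model's support, tiling its profile
    model$t0 + (t - t0) %% span
  }
  n_whole <- function(t) floor((t - t0) / span)
  Lam_span <- model$integral_fn(model$t1) - model$integral_fn(model$t0)
  Lam <- function(t) {
    n_whole(t) * Lam_span +
      (model$integral_fn(shift(t)) - model$integral_fn(model$t0))
  }
  tau <- Lam(times) - Lam(t0)
  if (length(tau) > 1 && any(diff(tau) <= 0))
    stop("time_rescale: model intensity is zero over an interval ",
         "containing spikes")
  list(tau = tau, total = Lam(t1) - Lam(t0))
}

#' Population photosensitivity and firing-rate statistics
#'
#' Aggregates unit decisions: the photosensitive fraction
#' (100 k / n over classified units), mean +/- sem firing rates per period
#' over photosensitive units, a one-way repeated-measures ANOVA across the
#' OFF/ON/POST rates of the photosensitive units with Greenhouse–Geisser
#' sphericity correction (epsilon-corrected degrees of freedom and p are
#' reported alongside the uncorrected ones; Mauchly's test is reported
#' too), Tukey HSD pairwise comparisons on the ANOVA error term, and a
#' Shapiro–Wilk normality test of the per-unit ON - OFF rate differences.
#'
#' Units flagged unclassifiable (\code{photosensitive} = NA) are excluded
#' from the denominator. With fewer than 3 photosensitive units the ANOVA
#' block is reported as unavailable but the fraction is still computed.
#'
#' @param decisions list of \code{\link{unit_decision}}s.
#' @return an object of class \code{population_stats}: \code{n_units},
#'   \code{n_photosensitive}, \code{fraction_pct}, \code{rates} (data
#'   frame period/mean/sem), \code{anova} (list: F, df1, df2, p,
#'   epsilon_gg, df1_gg, df2_gg, p_gg, mauchly_p, sphericity_corrected),
#'   \code{tukey} (data frame of pairwise comparisons), \code{shapiro}
#'   (statistic W and p).
#' @export
population_stats <- function(decisions) {
  stopifnot(length(decisions) >= 1,
            all(vapply(decisions, inherits, TRUE, "unit_decision")))
  cls <- vapply(decisions, `[[`, logical(1), "photosensitive")
  classified <- decisions[!is.na(cls)]
  if (length(classified) == 0)
    stop("population_stats: no classifiable units")
  n <- length(classified)
  k <- sum(vapply(classified, `[[`, logical(1), "photosensitive"))
  fraction <- 100 * k / n

  photo <- classified[vapply(classified, `[[`, logical(1), "photosensitive")]
  rates <- NULL; anova <- NULL; tukey <- NULL; shapiro <- NULL
  X <- t(vapply(photo, function(d)
    c(OFF = d$rate_off_hz, ON = d$rate_on_hz, POST = d$rate_post_hz),
    numeric(3)))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k_rates <- nrow(X)
  if (k_rates >= 1) {
    sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    rates <- data.frame(period = colnames(X),
                        mean_hz = colMeans(X),
                        sem_hz = apply(X, 2, sem), row.names = NULL)
    if (k_rates >= 3) {
      anova <- rm_anova_gg(X)
      tukey <- rm_tukey(X, anova)
      dif <- X[, "ON"] - X[, "OFF"]
      shapiro <- if (length(unique(dif)) > 2) {
        sw <- shapiro.test(dif)
        c(W = unname(sw$statistic), p = sw$p.value)
      } else c(W = NA_real_, p = NA_real_)
    }
  }
  if (k >= 1 && is.null(anova))
    ot_log("population_stats: fewer than 3 photosensitive units with ",
           "complete rates; ANOVA unavailable", level = "warn")
  structure(list(n_units = n, n_photosensitive = k,
                 fraction_pct = fraction, rates = rates, anova = anova,
                 tukey = tukey, shapiro = shapiro),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("population_stats: %d / %d photosensitive (%.1f%%)\n",
              x$n_photosensitive, x$n_units,
              round(x$fraction_pct, 1)))
  if (!is.null(x$rates)) {
    for (i in seq_len(nrow(x$rates)))
      cat(sprintf("  %-4s %6.2f +/- %.2f Hz\n", x$rates$period[i],
                  x$rates$mean_hz[i], x$rates$sem_hz[i]))
  }
  if (!is.null(x$anova))
    cat(sprintf("  RM-ANOVA: F(%.3f, %.2f) = %.2f, p = %.4g (GG-corrected)\n",
                x$anova$df1_gg, x$anova$df2_gg, x$anova$F, x$anova$p_gg))
  invisible(x)
}

# One-way repeated-measures ANOVA on an n x J matrix (units x conditions)
# with Greenhouse-Geisser epsilon and Mauchly's sphericity test.
rm_anova_gg <- function(X) {
  n <- nrow(X); J <- ncol(X)
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  ss_subj <- J * sum((row_m - grand)^2)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_tot <- sum((X - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- J - 1; df2 <- (J - 1) * (n - 1)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  F_ <- ms_cond / ms_err

  S <- stats::cov(X)
  C <- t(stats::contr.helmert(J))            # (J-1) x J contrasts
  C <- C / sqrt(rowSums(C^2))
  M <- C %*% S %*% t(C)
  eps <- (sum(diag(M)))^2 / ((J - 1) * sum(M * M))
  eps <- min(1, max(1 / (J - 1), eps))

  # Mauchly's W
  detM <- det(M)
  mauchly_p <- NA_real_
  if (detM > 0) {
    W <- detM / (sum(diag(M)) / (J - 1))^(J - 1)
    d <- J - 1
    cc <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
    chi2 <- -(n - 1) * cc * log(W)
    mdf <- d * (d + 1) / 2 - 1
    mauchly_p <- pchisq(chi2, mdf, lower.tail = FALSE)
  }
  list(F = F_, df1 = df1, df2 = df2,
       p = pf(F_, df1, df2, lower.tail = FALSE),
       epsilon_gg = eps, df1_gg = eps * df1, df2_gg = eps * df2,
       p_gg = pf(F_, eps * df1, eps * df2, lower.tail = FALSE),
       mauchly_p = mauchly_p,
       sphericity_corrected = !is.na(mauchly_p) && mauchly_p < 0.05,
       ms_err = ms_err)
}

# Tukey HSD on the repeated-measures error term.
rm_tukey <- function(X, anova) {
  J <- ncol(X); n <- nrow(X)
  cm <- colMeans(X)
  pairs <- utils::combn(J, 2)
  out <- data.frame(
    comparison = apply(pairs, 2, function(ij)
      paste(colnames(X)[ij[2]], "-", colnames(X)[ij[1]])),
    diff_hz = apply(pairs, 2, function(ij) cm[ij[2]] - cm[ij[1]]))
  se <- sqrt(anova$ms_err / n)
  out$q <- abs(out$diff_hz) / se
  out$p_adj <- ptukey(out$q, nmeans = J, df = anova$df2,
                      lower.tail = FALSE)
  out
}

#' Fluorescence change between paired measurement sessions
#'
#' Percentage change of the mean intensity between paired before/after
#' measures (100 x (mean(after) - mean(before)) / mean(before)) with an
#' exact two-sided Wilcoxon signed-rank test on the paired differences
#' (exact null distribution for n <= 25 without ties; zero differences
#' dropped per the standard convention; all-zero differences give p = 1
#' with a warning).
#'
#' @param before,after equal-length numeric vectors of paired intensity
#'   measures (n >= 5 for the exact test).
#' @return a list: \code{pct_change}, \code{p_value}, \code{n_effective}
#'   (pairs after dropping zeros).
#' @export
fluorescence_change <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 5,
            all(is.finite(before)), all(is.finite(after)))
  pct <- 100 * (mean(after) - mean(before)) / mean(before)
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0) {
    ot_log("fluorescence_change: all paired differences are zero; ",
           "p undefined, reported as 1", level = "warn")
    return(list(pct_change = pct, p_value = 1, n_effective = 0L))
  }
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact,
                                     correct = FALSE))
  list(pct_change = pct, p_value = wt$p.value,
       n_effective = length(d))
}
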