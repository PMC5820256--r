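#' Ground truth for a synthetic spike train
#'
#' One unit firing at \code{baseline_rate_hz} during the OFF and POST
#' periods and at \code{baseline_rate_hz * on_rate_multiplier} during ON.
#' The renewal process is either Poisson (exponential gaps) or a
#' gamma-renewal process with the given shape (shape > 1: more regular than
#' Poisson, ISI coefficient of variation 1/sqrt(shape)).
#'
#' The defaults (18.2 Hz baseline, 60 s periods) reflect tonic subthalamic
#' firing at the rates typical of awake primate recordings.
#'
#' @param baseline_rate_hz baseline firing rate, Hz (> 0).
#' @param on_rate_multiplier ON-period rate multiplier (> 0); 1 = unresponsive.
#' @param process \code{"poisson"} or \code{"gamma"}.
#' @param gamma_shape shape of the gamma-renewal process (> 0; ignored for
#'   Poisson).
#' @param responsive logical ground-truth flag (defaults to
#'   \code{on_rate_multiplier != 1}).
#' @param period_durations_s OFF/ON/POST durations, seconds.
#' @return an object of class \code{spike_ground_truth}.
#' @export
spike_ground_truth <- function(baseline_rate_hz = 18.2,
                               on_rate_multiplier = 1,
                               process = c("poisson", "gamma"),
                               gamma_shape = 1,
                               responsive = NULL,
                               period_durations_s = c(60, 60, 60)) {
  process <- match.arg(process)
  stopifnot(baseline_rate_hz > 0, on_rate_multiplier > 0, gamma_shape > 0,
            length(period_durations_s) == 3, all(period_durations_s > 0))
  if (is.null(responsive)) responsive <- on_rate_multiplier != 1
  structure(list(baseline_rate_hz = baseline_rate_hz,
                 on_rate_multiplier = on_rate_multiplier,
                 process = process, gamma_shape = gamma_shape,
                 responsive = responsive,
                 period_durations_s = as.numeric(period_durations_s)),
            class = "spike_ground_truth")
}

#' Synthetic spike trains with OFF/ON/POST periods
#'
#' Generates one \code{\link{spike_record}} per ground-truth unit. Periods
#' are contiguous: OFF starts at 0, ON and POST follow. Within each period,
#' gaps are drawn from the unit's renewal process at the period's rate
#' (exponential for Poisson; gamma with shape k and rate k*lambda for the
#' gamma-renewal process, so the mean rate is lambda either way). The
#' renewal process restarts at each period boundary. Deterministic for a
#' fixed \code{rng_seed}.
#'
#' @param population list of \code{\link{spike_ground_truth}} objects (a
#'   single object is accepted).
#' @param rng_seed integer seed.
#' @return a list with \code{records} (named list of
#'   \code{\link{spike_record}}s, unit ids \code{"u1"}, \code{"u2"}, ...)
#'   and \code{truth} (data frame of ground-truth parameters per unit).
#' @export
#' @examples
#' out <- make_spike_trains(list(spike_ground_truth(on_rate_multiplier = 1.5)),
#'                          rng_seed = 7)
#' out$records[["u1"]]
make_spike_trains <- function(population, rng_seed = 1L) {
  if (inherits(population, "spike_ground_truth")) population <- list(population)
  stopifnot(all(vapply(population, inherits, TRUE, "spike_ground_truth")))
  with_seed(rng_seed, {
    records <- vector("list", length(population))
    truth <- do.call(rbind, lapply(seq_along(population), function(i) {
      g <- population[[i]]
      data.frame(unit_id = paste0("u", i),
                 baseline_rate_hz = g$baseline_rate_hz,
                 on_rate_multiplier = g$on_rate_multiplier,
                 process = g$process, gamma_shape = g$gamma_shape,
                 responsive = g$responsive)
    }))
    for (i in seq_along(population)) {
      g <- population[[i]]
      bounds <- cumsum(c(0, g$period_durations_s))
      pb <- data.frame(period = c("OFF", "ON", "POST"),
                       start_s = bounds[1:3], end_s = bounds[2:4])
      rates <- g$baseline_rate_hz * c(1, g$on_rate_multiplier, 1)
      times <- unlist(lapply(1:3, function(j)
        pb$start_s[j] + renewal_times(rates[j], g$period_durations_s[j],
                                      g$process, g$gamma_shape)))
      records[[i]] <- spike_record(paste0("u", i), times, pb)
    }
    names(records) <- paste0("u", seq_along(population))
    list(records = records, truth = truth)
  })
}

# Event times of a renewal process on (0, duration), open at both ends.
renewal_times <- function(rate_hz, duration_s, process, shape) {
  n_guess <- max(20, ceiling(rate_hz * duration_s + 6 * sqrt(rate_hz * duration_s)))
  gaps <- numeric(0)
  total <- 0
  while (total < duration_s) {
    new <- if (process == "poisson") rexp(n_guess, rate_hz)
           else rgamma(n_guess, shape = shape, rate = shape * rate_hz)
    gaps <- c(gaps, new)
    total <- sum(gaps)
  }
  t <- cumsum(gaps)
  t[t < duration_s]
}
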