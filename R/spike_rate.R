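#' Fit a firing-rate model to one period of a spike record
#'
#' Models the spike occurrences of a period as an (in)homogeneous Poisson
#' process with one of three intensity families:
#' \describe{
#'   \item{constant}{lambda = n / T — the default for tonically firing
#'     subthalamic units;}
#'   \item{piecewise}{bin counts / bin width on bins of
#'     \code{bandwidth_or_binwidth_s} (last bin possibly shorter); the
#'     integrated intensity is exact (piecewise linear);}
#'   \item{kernel}{Gaussian kernel intensity with reflection edge
#'     correction at both period ends; the integrated intensity is
#'     tabulated on a fine grid (step = bandwidth / 20) and interpolated,
#'     accurate to ~1e-8 relative for smooth rates.}
#' }
#' A kernel fit on zero events falls back to the constant-0 model with a
#' warning.
#'
#' @param record a \code{\link{spike_record}}.
#' @param period \code{"OFF"}, \code{"ON"} or \code{"POST"}.
#' @param kind \code{"constant"}, \code{"piecewise"} or \code{"kernel"}.
#' @param bandwidth_or_binwidth_s bin width (piecewise) or kernel bandwidth
#'   (kernel), seconds.
#' @return an object of class \code{rate_model}: functions
#'   \code{rate_fn(t)} and \code{integral_fn(t)} (both vectorized, defined
#'   on [t0, t1]), plus \code{kind}, \code{t0}, \code{t1}.
#' @export
fit_rate <- function(record, period = c("OFF", "ON", "POST"),
                     kind = c("constant", "piecewise", "kernel"),
                     bandwidth_or_binwidth_s = 1) {
  period <- match.arg(period)
  kind <- match.arg(kind)
  stopifnot(inherits(record, "spike_record"))
  ps <- period_spikes(record, period)
  t0 <- ps$start; t1 <- ps$end; times <- ps$times
  n <- length(times)
  if (kind == "kernel" && n == 0) {
    ot_log("fit_rate: kernel fit on 0 events; falling back to constant 0",
           level = "warn")
    kind <- "constant"
  }
  model <- switch(kind,
    constant = {
      lam <- n / (t1 - t0)
      list(rate_fn = function(t) rep(lam, length(t)),
           integral_fn = function(t) lam * (t - t0),
           lambda = lam)
    },
    piecewise = {
      bw <- bandwidth_or_binwidth_s
      stopifnot(bw > 0)
      edges <- unique(c(seq(t0, t1, by = bw), t1))
      counts <- graphics::hist(times, breaks = edges, plot = FALSE,
                               right = FALSE)$counts
      # spikes exactly at t1 fall in the last bin
      counts[length(counts)] <- counts[length(counts)] +
        sum(times == t1)
      widths <- diff(edges)
      rates <- counts / widths
      cum <- c(0, cumsum(rates * widths))
      rate_fn <- function(t) {
        i <- pmin(length(rates), pmax(1L, findInterval(t, edges,
                                                       rightmost.closed = TRUE)))
        rates[i]
      }
      integral_fn <- function(t) {
        i <- pmin(length(rates), pmax(1L, findInterval(t, edges,
                                                       rightmost.closed = TRUE)))
        cum[i] + rates[i] * (t - edges[i])
      }
      list(rate_fn = rate_fn, integral_fn = integral_fn,
           edges = edges, rates = rates)
    },
    kernel = {
      h <- bandwidth_or_binwidth_s
      stopifnot(h > 0)
      rate_fn <- function(t) {
        vapply(t, function(tt) {
          sum(stats::dnorm(tt, times, h) +
              stats::dnorm(2 * t0 - tt, times, h) +
              stats::dnorm(2 * t1 - tt, times, h))
        }, numeric(1))
      }
      grid <- seq(t0, t1, by = h / 20)
      if (grid[length(grid)] < t1) grid <- c(grid, t1)
      vals <- rate_fn(grid)
      cumint <- c(0, cumsum((head(vals, -1) + tail(vals, -1)) / 2 *
                              diff(grid)))
      integral_fn <- function(t) approx(grid, cumint, xout = t,
                                        rule = 2)$y
      list(rate_fn = rate_fn, integral_fn = integral_fn)
    })
  structure(c(model, list(kind = kind, t0 = t0, t1 = t1, n_events = n)),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("rate_model (", x$kind, ") on [", x$t0, ", ", x$t1, "] s, ",
      x$n_events, " events, Lambda = ",
      signif(x$integral_fn(x$t1), 6), "\n", sep = "")
  invisible(x)
}

#' Time-rescale spike times under a rate model
#'
#' Applies the time-rescaling theorem: with integrated intensity Lambda,
#' the transformed times tau_k = Lambda(t_k) - Lambda(t0) form a unit-rate
#' Poisson process exactly when the model is correct. Event count and order
#' are preserved; tau is strictly increasing whenever the model intensity
#' is positive between events.
#'
#' @param spike_times sorted spike times within the model's support.
#' @param model a \code{\link{fit_rate}} model.
#' @return numeric vector of rescaled times, with attribute
#'   \code{"total_rescaled_time"} = Lambda(t1) - Lambda(t0).
#' @export
time_rescale <- function(spike_times, model) {
  stopifnot(inherits(model, "rate_model"))
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 0) {
    if (min(spike_times) < model$t0 - 1e-9 ||
        max(spike_times) > model$t1 + 1e-9)
      stop("time_rescale: spikes outside the model support [",
           model$t0, ", ", model$t1, "]")
    if (is.unsorted(spike_times, strictly = TRUE))
      stop("time_rescale: spike times must be strictly increasing")
  }
  tau <- model$integral_fn(spike_times) - model$integral_fn(model$t0)
  if (length(tau) > 1 && any(diff(tau) <= 0))
    stop("time_rescale: model intensity is zero over an interval ",
         "containing spikes (rescaled times not strictly increasing)")
  total <- model$integral_fn(model$t1) - model$integral_fn(model$t0)
  attr(tau, "total_rescaled_time") <- total
  tau
}
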