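#' Spike records
#'
#' A spike record holds the sorted spike times of one unit together with the
#' boundaries of the OFF (pre-stimulation), ON (stimulation) and POST
#' (post-stimulation) periods. Periods must be disjoint and ordered
#' OFF < ON < POST; every spike must fall inside one of them.
#'
#' @param unit_id identifier of the unit.
#' @param spike_times_s numeric vector of event times, seconds.
#' @param period_bounds_s data frame with columns \code{period}
#'   (\code{"OFF"}, \code{"ON"}, \code{"POST"}), \code{start_s},
#'   \code{end_s}.
#' @param subject_id optional subject identifier.
#' @return an object of class \code{spike_record}.
#' @export
spike_record <- function(unit_id, spike_times_s, period_bounds_s,
                         subject_id = NA_character_) {
  spike_times_s <- as.numeric(spike_times_s)
  if (is.unsorted(spike_times_s, strictly = TRUE))
    stop("spike_record: spike times must be strictly increasing (unit ",
         unit_id, ")")
  pb <- as.data.frame(period_bounds_s)
  need <- c("period", "start_s", "end_s")
  if (!all(need %in% names(pb)))
    stop("spike_record: period table must have columns ",
         paste(need, collapse = ", "))
  pb$period <- toupper(as.character(pb$period))
  if (!setequal(pb$period, c("OFF", "ON", "POST")) || nrow(pb) != 3)
    stop("spike_record: exactly the three periods OFF, ON, POST are required")
  pb <- pb[match(c("OFF", "ON", "POST"), pb$period), ]
  if (any(pb$end_s <= pb$start_s))
    stop("spike_record: each period must have positive duration")
  if (any(diff(as.vector(rbind(pb$start_s, pb$end_s))) < 0))
    stop("spike_record: periods must be disjoint and ordered OFF < ON < POST")
  inside <- vapply(spike_times_s, function(t)
    any(t >= pb$start_s & t <= pb$end_s), logical(1))
  if (!all(inside))
    stop("spike_record: ", sum(!inside), " spike(s) of unit ", unit_id,
         " fall outside all periods")
  structure(list(unit_id = unit_id, spike_times_s = spike_times_s,
                 period_bounds_s = pb, subject_id = subject_id),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat("spike_record: unit", x$unit_id, "-", length(x$spike_times_s),
      "spikes over",
      sprintf("%.1f s", max(x$period_bounds_s$end_s) -
                min(x$period_bounds_s$start_s)), "\n")
  invisible(x)
}

# Spikes of one record restricted to a named period.
period_spikes <- function(record, period) {
  pb <- record$period_bounds_s
  row <- pb[pb$period == period, ]
  if (nrow(row) != 1) stop("unknown period: ", period)
  t <- record$spike_times_s
  list(times = t[t >= row$start_s & t <= row$end_s],
       start = row$start_s, end = row$end_s,
       duration = row$end_s - row$start_s)
}

#' Read and write spike trains
#'
#' Spikes are stored as a CSV with columns \code{unit_id}, \code{time_s}
#' (and optionally \code{subject_id}); period boundaries come from a sidecar
#' CSV with columns \code{period}, \code{start_s}, \code{end_s} (one shared
#' table, or per-unit tables with an extra \code{unit_id} column). Units
#' listed in a per-unit period table but absent from the spike file yield
#' records with zero events.
#'
#' @param path spike CSV path.
#' @param periods_path sidecar CSV path (default \code{<path>.periods.csv}).
#' @param records list of \code{\link{spike_record}}s.
#' @return \code{read_spikes}: a named list of \code{spike_record}s;
#'   \code{write_spikes}: \code{path}, invisibly.
#' @export
read_spikes <- function(path, periods_path = NULL) {
  if (!file.exists(path)) stop("read_spikes: no such file: ", path)
  if (is.null(periods_path)) periods_path <- paste0(path, ".periods.csv")
  if (!file.exists(periods_path))
    stop("read_spikes: no period sidecar found at ", periods_path)
  sp <- read.csv(path)
  if (!all(c("unit_id", "time_s") %in% names(sp)))
    stop("read_spikes: spike CSV must have columns 'unit_id', 'time_s'")
  pp <- read.csv(periods_path)
  per_unit <- "unit_id" %in% names(pp)
  unit_ids <- if (per_unit) unique(c(pp$unit_id, sp$unit_id))
              else unique(sp$unit_id)
  recs <- lapply(unit_ids, function(u) {
    times <- sort(sp$time_s[sp$unit_id == u])
    if (anyDuplicated(times))
      stop("read_spikes: duplicate timestamps within unit ", u)
    pb <- if (per_unit) pp[pp$unit_id == u, ] else pp
    subj <- if ("subject_id" %in% names(sp) && any(sp$unit_id == u))
      sp$subject_id[sp$unit_id == u][1] else NA_character_
    spike_record(u, times, pb, subject_id = subj)
  })
  names(recs) <- as.character(unit_ids)
  ot_log("read_spikes: ", length(recs), " unit(s), ",
         nrow(sp), " spikes from ", path)
  recs
}

#' @rdname read_spikes
#' @export
write_spikes <- function(records, path) {
  stopifnot(all(vapply(records, inherits, TRUE, "spike_record")))
  sp <- do.call(rbind, lapply(records, function(r)
    if (length(r$spike_times_s) == 0) NULL else
    data.frame(unit_id = r$unit_id, time_s = r$spike_times_s,
               subject_id = r$subject_id)))
  if (is.null(sp))
    sp <- data.frame(unit_id = character(0), time_s = numeric(0),
                     subject_id = character(0))
  write.csv(sp, path, row.names = FALSE)
  pp <- do.call(rbind, lapply(records, function(r)
    cbind(unit_id = r$unit_id, r$period_bounds_s)))
  write.csv(pp, paste0(path, ".periods.csv"), row.names = FALSE)
  invisible(path)
}
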