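#' Percent pill-count adherence
#'
#' Primary adherence endpoint:
#' \code{100 * (n_prescribed - n_remaining) / days between dispensing and
#' return}, assuming one prescribed pill per day. Values may exceed 100 when
#' a bottle is returned late; they are reported as computed — clamping to
#' [0, 100] is a separate, explicit step applied only before the logit
#' transform (see \code{\link{logit_transform}}).
#'
#' @param n_prescribed pills dispensed.
#' @param n_remaining pills returned.
#' @param dispense_date,return_date dates (\code{Date} or parseable strings);
#'   alternatively supply \code{days} directly.
#' @param days interval length in days (overrides the dates).
#' @return Percentage (possibly > 100).
#' @examples
#' pill_count_pct(28, 7, days = 28)  # 75
#' @export
pill_count_pct <- function(n_prescribed, n_remaining,
                           dispense_date = NULL, return_date = NULL,
                           days = NULL) {
  if (is.null(days)) {
    days <- as.numeric(as.Date(return_date) - as.Date(dispense_date))
  }
  if (any(days <= 0)) stop("return date must be after dispensing date")
  if (any(n_remaining > n_prescribed)) stop("more pills remaining than prescribed")
  100 * (n_prescribed - n_remaining) / days
}

# Unwrap hours-since-midnight around the sample median so a habitual dose
# time near midnight does not split into 0h and 24h clusters.
.unwrap_hours <- function(hours) {
  med <- stats::median(hours)
  hours - 24 * round((hours - med) / 24)
}

#' Percent of MEMS doses taken on schedule (within +/- 6 h)
#'
#' Secondary adherence endpoint from the electronic cap-opening log: the
#' percentage of scheduled days with an opening within
#' \code{window_hours} of the participant's usual dosing time, where the
#' usual time per day is estimated by fitting a least-squares line to the
#' (day index, clock time) pairs of the first opening of each day. Days
#' without any opening count as missed; extra same-day openings are ignored.
#' The window is inclusive (a residual of exactly \code{window_hours} counts
#' as on schedule).
#'
#' @param open_timestamps opening times (\code{POSIXct} or parseable
#'   strings, UTC assumed).
#' @param schedule_start,schedule_end first and last scheduled dosing dates
#'   (inclusive); one dose is expected per calendar day.
#' @param window_hours half-width of the on-schedule window (default 6).
#' @return Percentage of scheduled days on schedule. With fewer than two
#'   openings the line cannot be fit: returns 0 with a warning.
#' @export
mems_on_schedule_pct <- function(open_timestamps, schedule_start,
                                 schedule_end, window_hours = 6) {
  ts <- as.POSIXct(open_timestamps, tz = "UTC")
  start <- as.Date(schedule_start)
  end <- as.Date(schedule_end)
  n_days <- as.numeric(end - start) + 1
  if (n_days < 1) stop("schedule_end precedes schedule_start")
  if (length(ts) >= 2 && any(diff(as.numeric(ts)) < 0))
    stop("open_timestamps must be sorted ascending")
  day <- as.Date(ts, tz = "UTC")
  if (length(ts) && (any(day < start) || any(day > end)))
    stop("MEMS events outside the dosing schedule")
  if (length(ts) < 2) {
    warning("fewer than 2 MEMS events: cannot fit a dosing-time line")
    return(structure(0, too_few_events = TRUE))
  }

  day_index <- as.numeric(day - start)
  first <- !duplicated(day_index)
  day_index <- day_index[first]
  if (length(day_index) < 2) {
    warning("fewer than 2 dosing days: cannot fit a dosing-time line")
    return(structure(0, too_few_events = TRUE))
  }
  hours <- .unwrap_hours(
    as.numeric(difftime(ts[first], as.POSIXct(paste(day[first], "00:00:00"),
                                              tz = "UTC"), units = "hours")))
  fit <- stats::lm.fit(cbind(1, day_index), hours)
  expected <- fit$coefficients[1] + fit$coefficients[2] * day_index
  # inclusive boundary, with an epsilon so an exactly-6 h residual is not
  # dropped by floating-point noise in the line fit
  on_schedule <- abs(hours - expected) <= window_hours + 1e-9
  100 * sum(on_schedule) / n_days
}

#' QIDS-SR remission and response
#'
#' Remission: total score at or below the threshold (default 5, the standard
#' QIDS-SR convention). Response: at least a 50% reduction from the baseline
#' score.
#'
#' @param score,baseline QIDS-SR totals in [0, 27].
#' @param threshold remission cut-off (default 5).
#' @return logical.
#' @export
qids_remission <- function(score, threshold = 5) {
  if (any(score < 0 | score > 27)) stop("QIDS-SR scores must lie in [0, 27]")
  score <= threshold
}

#' @rdname qids_remission
#' @export
qids_response <- function(score, baseline) {
  if (any(c(score, baseline) < 0 | c(score, baseline) > 27))
    stop("QIDS-SR scores must lie in [0, 27]")
  score <= 0.5 * baseline
}

#' Intention-to-treat non-adherence imputation
#'
#' Participants who withdraw or are lost to follow-up are considered
#' non-adherent for the remainder of the schedule: every scheduled visit at
#' or after the withdrawal week gets both adherence endpoints set to 0 and
#' the \code{imputed} flag raised; a missing scheduled visit row is created
#' if needed, so after imputation every participant has one record per
#' scheduled visit.
#'
#' @param records data.frame with columns \code{participant_id},
#'   \code{visit_week}, \code{pill_count_pct}, \code{mems_pct}, and
#'   optionally \code{arm} and \code{imputed}.
#' @param withdrawal_weeks named vector/list mapping participant id to
#'   withdrawal week (participants absent from the map did not withdraw), or
#'   a data.frame with columns \code{participant_id}, \code{withdrawal_week}.
#' @param schedule scheduled visit weeks (default \code{c(2, 4, 8)}).
#' @param participants optional vector of all randomized participant ids
#'   (covers participants who withdrew before contributing any record);
#'   defaults to the ids present in \code{records}.
#' @return data.frame with one row per participant x scheduled visit,
#'   ordered by participant then week, with an \code{imputed} flag.
#' @export
itt_impute <- function(records, withdrawal_weeks = NULL,
                       schedule = c(2, 4, 8), participants = NULL) {
  if (is.data.frame(withdrawal_weeks)) {
    withdrawal_weeks <- stats::setNames(
      withdrawal_weeks$withdrawal_week,
      withdrawal_weeks$participant_id)
  }
  withdrawal_weeks <- withdrawal_weeks[!is.na(withdrawal_weeks)]
  if (!"imputed" %in% names(records)) records$imputed <- FALSE
  ids <- unique(c(records$participant_id, participants))
  full <- expand.grid(participant_id = ids, visit_week = schedule,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(full, records, by = c("participant_id", "visit_week"),
               all.x = TRUE, sort = FALSE)
  if ("arm" %in% names(records)) {
    arm_map <- records$arm[match(out$participant_id, records$participant_id)]
    out$arm <- ifelse(is.na(out$arm), arm_map, out$arm)
  }
  out$imputed[is.na(out$imputed)] <- FALSE
  ww <- unlist(withdrawal_weeks)[as.character(out$participant_id)]
  hit <- !is.na(ww) & out$visit_week >= ww
  out$pill_count_pct[hit] <- 0
  out$mems_pct[hit] <- 0
  out$imputed[hit] <- TRUE
  missed <- is.na(out$pill_count_pct) & is.na(out$mems_pct)
  if (any(missed & !hit))
    warning("missing visit records for non-withdrawn participants retained as NA")
  out[order(match(out$participant_id, ids), out$visit_week), , drop = FALSE]
}

#' Derive the adherence endpoint table from raw visit and MEMS records
#'
#' Applies \code{\link{pill_count_pct}} per dispensing interval and
#' \code{\link{mems_on_schedule_pct}} per participant x interval to produce
#' the long-format endpoint table consumed by the mixed model, then applies
#' the intention-to-treat imputation rule.
#'
#' @param visits data.frame with columns \code{participant_id}, \code{arm},
#'   \code{visit_week}, \code{n_prescribed}, \code{n_remaining},
#'   \code{dispense_date}, \code{return_date}, \code{qids},
#'   \code{withdrawal_week} (NA if completed).
#' @param mems_events data.frame with columns \code{participant_id},
#'   \code{timestamp}.
#' @param schedule scheduled visit weeks (default \code{c(2, 4, 8)}).
#' @return data.frame: participant_id, arm, visit_week, pill_count_pct,
#'   mems_pct, qids, imputed.
#' @export
derive_endpoints <- function(visits, mems_events, schedule = c(2, 4, 8)) {
  obs <- visits[visits$visit_week %in% schedule &
                  !is.na(visits$n_prescribed), , drop = FALSE]
  obs$pill_count_pct <- pill_count_pct(
    obs$n_prescribed, obs$n_remaining,
    obs$dispense_date, obs$return_date)
  obs$mems_pct <- vapply(seq_len(nrow(obs)), function(i) {
    ev <- mems_events$timestamp[
      mems_events$participant_id == obs$participant_id[i]]
    ev <- sort(as.POSIXct(ev, tz = "UTC"))
    start <- as.Date(obs$dispense_date[i])
    end <- as.Date(obs$return_date[i]) - 1
    ev <- ev[as.Date(ev, tz = "UTC") >= start & as.Date(ev, tz = "UTC") <= end]
    suppressWarnings(as.numeric(mems_on_schedule_pct(ev, start, end)))
  }, numeric(1))
  keep <- c("participant_id", "arm", "visit_week", "pill_count_pct",
            "mems_pct", "qids")
  obs <- obs[, intersect(keep, names(obs)), drop = FALSE]
  ww <- unique(visits[, c("participant_id", "withdrawal_week")])
  res <- itt_impute(obs, ww, schedule = schedule,
                    participants = unique(visits$participant_id))
  res$arm <- visits$arm[match(res$participant_id, visits$participant_id)]
  res
}
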