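# Threshold-exceedance classification and daily beach-advisory experiments:
# ideal advisories, model-informed advisories, and simulated weekly
# water-quality sampling with its laboratory lag.

#' Confusion counts
#'
#' Counts (or fractions) of the four binary-comparison conditions between a
#' predicted and a true exceedance field.
#'
#' @param tp,fp,fn,tn Nonnegative counts or fractions.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(!is.finite(v)))
    stop("confusion_counts: counts must be finite and nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  tot <- x$tp + x$fp + x$fn + x$tn
  cat(sprintf("Confusion: TP %g, FP %g, FN %g, TN %g (agreement %.1f%%)\n",
              x$tp, x$fp, x$fn, x$tn, 100 * agreement(x)))
  invisible(x)
}

#' Threshold exceedance field
#'
#' Strict exceedance `C > c_bac` per time step per location; a concentration
#' exactly at the threshold does not exceed.
#'
#' @param field A [tracer_field()].
#' @param c_bac Advisory threshold (> 0); a [source_config()] may be given.
#' @return A `binary_field`: list with `time`, `y` and logical matrix `x`.
#' @export
exceedance <- function(field, c_bac = 5e-4) {
  stopifnot(inherits(field, "tracer_field"))
  if (inherits(c_bac, "source_config")) c_bac <- c_bac$c_bac
  if (!is.numeric(c_bac) || length(c_bac) != 1L || c_bac <= 0)
    stop("exceedance: c_bac must be a positive scalar")
  structure(list(time = field$time, y = field$y, x = field$c > c_bac),
            class = "binary_field")
}

#' Confusion counts between predicted and true exceedance fields
#'
#' Pools all time steps and alongshore locations with equal weight.
#'
#' @param pred,truth `binary_field` objects (or logical arrays) of identical
#'   shape.
#' @return A [confusion_counts()] object.
#' @export
confusion <- function(pred, truth) {
  p <- if (inherits(pred, "binary_field")) pred$x else pred
  o <- if (inherits(truth, "binary_field")) truth$x else truth
  if (!identical(dim(p), dim(o)) || length(p) != length(o))
    stop("confusion: prediction and truth shapes differ")
  confusion_counts(tp = sum(p & o), fp = sum(p & !o),
                   fn = sum(!p & o), tn = sum(!p & !o))
}

#' Agreement, sensitivity and specificity of a confusion table
#'
#' `agreement` is the true fraction (TP + TN) / total; `sensitivity` is
#' TP / (TP + FN), the fraction of detectable positives detected;
#' `specificity` is TN / (TN + FP). Undefined ratios return `NaN` with a
#' `reason` attribute rather than a silent zero.
#'
#' @param counts A [confusion_counts()] object.
#' @return A value in `[0, 1]` (or `NaN` when undefined).
#' @export
agreement <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$tp + counts$fp + counts$fn + counts$tn
  if (tot == 0) return(structure(NaN, reason = "no comparisons"))
  (counts$tp + counts$tn) / tot
}

#' @rdname agreement
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$tp + counts$fn
  if (den == 0) return(structure(NaN, reason = "no true positives detectable"))
  counts$tp / den
}

#' @rdname agreement
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$tn + counts$fp
  if (den == 0) return(structure(NaN, reason = "no true negatives detectable"))
  counts$tn / den
}

# Calendar day (as Date) of each timestamp, in the forcing time zone.
.cal_days <- function(time, tz = NULL) {
  if (is.null(tz)) tz <- attr(time, "tzone")
  if (is.null(tz) || tz == "") tz <- "UTC"
  as.Date(format(time, "%Y-%m-%d", tz = tz))
}

.check_hourly <- function(time, what) {
  dt <- diff(as.numeric(time))
  if (length(dt) && any(abs(dt - 3600) > 1e-6))
    stop(what, ": hourly cadence required (resample at the I/O boundary)")
}

#' Daily advisory from an hourly exceedance field
#'
#' An advisory is issued at a location on a calendar day if the hourly field
#' exceeds the threshold for at least one hour of that day. Applied to the
#' reference (true) field this is the ideal advisory; applied to the model
#' field it is the model-informed advisory.
#'
#' @param bin A `binary_field` at hourly cadence.
#' @return A `daily_advisory`: list with `day` (Date), `y`, and logical
#'   matrix `a` (days x locations).
#' @export
daily_advisory <- function(bin) {
  stopifnot(inherits(bin, "binary_field"))
  .check_hourly(bin$time, "daily_advisory")
  days <- .cal_days(bin$time)
  ud <- sort(unique(days))
  a <- matrix(FALSE, length(ud), ncol(bin$x))
  di <- match(days, ud)
  for (j in seq_len(ncol(bin$x)))
    a[, j] <- as.logical(tapply(bin$x[, j], di, any))
  structure(list(day = ud, y = bin$y, a = a), class = "daily_advisory")
}

#' Daily advisory from simulated weekly sampling
#'
#' Emulates a weekly monitoring program: the true hourly field is sampled at
#' one fixed hour of the week (`sampling_hour`, 0 to 167, counted from the
#' first time step). If the sample exceeds the threshold, an advisory is
#' issued from the following calendar day (the laboratory culture lag) and
#' remains in place for 7 days, until the next sample is processed; a clean
#' sample likewise clears the advisory from the following day. Days before
#' the first processed sample carry no advisory.
#'
#' @param truth A `binary_field` of true hourly exceedances, at least one
#'   week long.
#' @param sampling_hour Integer hour-of-week offset, 0-167.
#' @return A `daily_advisory` on the same calendar days as
#'   [daily_advisory()] applied to `truth`.
#' @export
weekly_sampling_advisory <- function(truth, sampling_hour) {
  stopifnot(inherits(truth, "binary_field"))
  .check_hourly(truth$time, "weekly_sampling_advisory")
  if (length(sampling_hour) != 1L || is.na(sampling_hour) ||
      sampling_hour != round(sampling_hour) ||
      sampling_hour < 0 || sampling_hour > 167)
    stop("weekly_sampling_advisory: sampling_hour must be an integer in 0-167")
  nt <- length(truth$time)
  if (nt < 168L) stop("weekly_sampling_advisory: need at least one week")
  days <- .cal_days(truth$time)
  ud <- sort(unique(days))
  a <- matrix(FALSE, length(ud), ncol(truth$x))
  smp <- seq(sampling_hour + 1L, nt, by = 168L)   # sample time indices
  for (s in smp) {
    d0 <- match(days[s], ud) + 1L                 # advisory starts next day
    span <- d0:(d0 + 6L)
    span <- span[span <= length(ud)]
    if (length(span))
      a[span, ] <- matrix(truth$x[s, ], length(span), ncol(truth$x),
                          byrow = TRUE)
  }
  structure(list(day = ud, y = truth$y, a = a), class = "daily_advisory")
}

#' Sweep all weekly sampling hours
#'
#' Runs [weekly_sampling_advisory()] for every possible sampling hour (0-167)
#' and reports, per alongshore location, the minimum, mean and maximum
#' accuracy against the ideal advisory across the sweep.
#'
#' @param truth A `binary_field` of true hourly exceedances.
#' @param ideal Optional `daily_advisory`; defaults to
#'   `daily_advisory(truth)`.
#' @return A list with `accuracy` (168 x n_y matrix of percent agreement) and
#'   `summary` (data frame: `y`, `min`, `mean`, `max` percent).
#' @export
sampling_hour_sweep <- function(truth, ideal = NULL) {
  if (is.null(ideal)) ideal <- daily_advisory(truth)
  acc <- matrix(NA_real_, 168L, length(truth$y))
  for (h in 0:167) {
    cand <- weekly_sampling_advisory(truth, h)
    acc[h + 1L, ] <- advisory_accuracy(cand, ideal)$accuracy_pct
  }
  list(accuracy = acc,
       summary = data.frame(y = truth$y,
                            min = apply(acc, 2L, min),
                            mean = colMeans(acc),
                            max = apply(acc, 2L, max)))
}

#' Accuracy of a daily advisory schedule against the ideal schedule
#'
#' Percent of days on which the candidate advisory state matches the ideal
#' advisory, per alongshore location, together with the sensitivity and
#' specificity of the daily advisories.
#'
#' @param candidate,ideal `daily_advisory` objects on the same days and grid.
#' @return A `data.frame` with columns `y`, `accuracy_pct`, `sensitivity`,
#'   `specificity`.
#' @export
advisory_accuracy <- function(candidate, ideal) {
  stopifnot(inherits(candidate, "daily_advisory"),
            inherits(ideal, "daily_advisory"))
  if (!identical(candidate$day, ideal$day) ||
      !isTRUE(all.equal(candidate$y, ideal$y)))
    stop("advisory_accuracy: schedules are not aligned")
  ny <- length(ideal$y)
  out <- data.frame(y = ideal$y, accuracy_pct = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_)
  for (j in seq_len(ny)) {
    cc <- confusion(candidate$a[, j, drop = FALSE], ideal$a[, j, drop = FALSE])
    out$accuracy_pct[j] <- 100 * agreement(cc)
    out$sensitivity[j] <- as.numeric(sensitivity(cc))
    out$specificity[j] <- as.numeric(specificity(cc))
  }
  out
}
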