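# Model-skill statistics, applied per alongshore location.

# Drop pairwise-incomplete observations; warn above 10% missing.
.paired <- function(model, ref, what) {
  if (length(model) != length(ref))
    stop(what, ": series must have equal length")
  ok <- is.finite(model) & is.finite(ref)
  n_drop <- sum(!ok)
  if (n_drop > 0.1 * length(ref))
    warning(what, ": more than 10% of pairs missing (", n_drop, " of ",
            length(ref), ")")
  list(m = model[ok], o = ref[ok], n_dropped = n_drop)
}

#' Pearson correlation between model and reference series
#'
#' Standard Pearson r over paired time steps; pairs with missing values are
#' dropped and counted (attribute `n_dropped`).
#'
#' @param model,ref Numeric series of equal length (>= 3 complete pairs).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(model, ref) {
  p <- .paired(model, ref, "pearson_r")
  if (length(p$o) < 3L) stop("pearson_r: need at least 3 complete pairs")
  if (stats::sd(p$o) == 0 || stats::sd(p$m) == 0)
    stop("pearson_r: correlation undefined for constant input")
  structure(stats::cor(p$m, p$o), n_dropped = p$n_dropped)
}

#' Normalized root-mean-square error
#'
#' RMSE between model and reference, normalized by the time-averaged
#' reference value (as used per alongshore location).
#'
#' @inheritParams pearson_r
#' @return NRMSE (>= 0, dimensionless).
#' @export
nrmse <- function(model, ref) {
  p <- .paired(model, ref, "nrmse")
  if (length(p$o) == 0L) stop("nrmse: no complete pairs")
  mo <- mean(p$o)
  if (mo <= 0) stop("nrmse: mean of reference must be positive")
  sqrt(mean((p$m - p$o)^2)) / mo
}

#' Willmott skill score (index of agreement)
#'
#' The classic Willmott (1981) index,
#' `1 - sum((m - o)^2) / sum((|m - obar| + |o - obar|)^2)`, bounded in
#' `[0, 1]` with 1 for perfect agreement. Unlike Pearson r it penalizes bias:
#' shifting or rescaling the model alone lowers the score (a common shift of
#' both series leaves it unchanged). If both series are constant
#' and equal the denominator vanishes and 1 is returned by convention (with a
#' message).
#'
#' @inheritParams pearson_r
#' @return Skill in `[0, 1]`.
#' @export
willmott_skill <- function(model, ref) {
  p <- .paired(model, ref, "willmott_skill")
  if (length(p$o) < 2L) stop("willmott_skill: need at least 2 complete pairs")
  obar <- mean(p$o)
  den <- sum((abs(p$m - obar) + abs(p$o - obar))^2)
  if (den == 0) {
    message("willmott_skill: degenerate (constant, equal) series; ",
            "returning 1 by convention")
    return(1)
  }
  1 - sum((p$m - p$o)^2) / den
}

#' Per-location skill profile
#'
#' Applies [pearson_r()], [nrmse()] and [willmott_skill()] at each alongshore
#' location of two tracer fields sharing the same grid and time base.
#' Locations where a metric is undefined (constant or nonpositive-mean
#' reference) yield NA rather than aborting the profile.
#'
#' @param model,ref [tracer_field()] objects on a common grid and time base.
#' @return A `data.frame` with columns `y`, `r`, `nrmse`, `wss`.
#' @export
skill_profile <- function(model, ref) {
  stopifnot(inherits(model, "tracer_field"), inherits(ref, "tracer_field"))
  if (!isTRUE(all.equal(model$y, ref$y)))
    stop("skill_profile: fields must share the alongshore grid")
  if (length(model$time) != length(ref$time) ||
      any(as.numeric(model$time) != as.numeric(ref$time)))
    stop("skill_profile: fields must share the time base")
  safe <- function(f, m, o) tryCatch(suppressMessages(as.numeric(f(m, o))),
                                     error = function(e) NA_real_)
  ny <- length(model$y)
  out <- data.frame(y = model$y, r = NA_real_, nrmse = NA_real_,
                    wss = NA_real_)
  for (j in seq_len(ny)) {
    m <- model$c[, j]; o <- ref$c[, j]
    out$r[j] <- safe(pearson_r, m, o)
    out$nrmse[j] <- safe(nrmse, m, o)
    out$wss[j] <- safe(willmott_skill, m, o)
  }
  out
}
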