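# Bromoperoxidase activity from thymol-blue bromination kinetics.
#
# The assay tracks the dibromination of thymol blue at 620 nm
# (epsilon = 37.2 mM^-1 cm^-1). The linear-phase slope in AU/min is
# converted via Beer-Lambert to mM/min and to enzyme units, where
# 1 U = 1 nmol TBBr2 formed per minute (mM/min x assay volume in uL
# gives nmol/min directly).

#' Construct a kinetic trace
#'
#' @param times Time points in minutes, strictly increasing, >= 3 points
#'   (the standard assay reads 0-10 min at 0.5-min steps).
#' @param absorbance A620 readings (AU), same length as \code{times}.
#' @param sample_id Sample label.
#' @param eps Molar absorptivity in mM^-1 cm^-1 (default 37.2).
#' @param pathlength Optical pathlength in cm (default 1; microplate
#'   assays should supply their true pathlength — the value is recorded
#'   in results).
#' @param volume Assay volume in uL.
#' @return Object of class \code{vhpo_trace}.
#' @export
kinetic_trace <- function(times, absorbance, sample_id = "sample",
                          eps = 37.2, pathlength = 1, volume = 200) {
  stopifnot(length(times) == length(absorbance))
  if (length(times) < 3L) stop("a kinetic trace needs at least 3 points", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (eps <= 0 || pathlength <= 0 || volume <= 0) {
    stop("eps, pathlength and volume must be positive", call. = FALSE)
  }
  structure(list(times = as.numeric(times), absorbance = as.numeric(absorbance),
                 sample_id = sample_id, eps = eps, pathlength = pathlength,
                 volume = volume), class = "vhpo_trace")
}

#' @export
print.vhpo_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace '%s': %d points, %.2g-%.2g min\n", x$sample_id,
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

# OLS slope, intercept and r^2 for a window; r^2 defined as 1 for an
# exact fit (including constant traces, where total variance is zero)
.ols_fit <- function(t, a) {
  n <- length(t)
  mt <- mean(t); ma <- mean(a)
  sxx <- sum((t - mt)^2)
  slope <- sum((t - mt) * (a - ma)) / sxx
  resid <- a - ma - slope * (t - mt)
  ss_res <- sum(resid^2)
  ss_tot <- sum((a - ma)^2)
  r2 <- if (ss_tot <= .Machine$double.eps * n) 1 else 1 - ss_res / ss_tot
  se <- if (n > 2) sqrt(ss_res / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = ma - slope * mt, r2 = r2, slope_se = se, n = n)
}

#' Estimate the linear-phase rate of a kinetic trace
#'
#' Ordinary least-squares slope of absorbance against time, either over
#' the full trace (\code{window_policy = "full"}) or over the best linear
#' window: the longest contiguous window of at least 5 points with
#' \eqn{r^2 \ge 0.98} (earliest such window among equal lengths; falls
#' back to the full trace with a warning when no window qualifies).
#'
#' @param trace A \code{vhpo_trace}, optionally blank-corrected first
#'   with [subtract_blank()].
#' @param window_policy \code{"full"} or \code{"best_linear"}.
#' @param r2_min Linearity threshold for \code{best_linear} (default 0.98).
#' @return List: \code{slope} (AU/min), \code{slope_se}, \code{r2},
#'   \code{window} (start/end times in minutes), \code{n}.
#' @export
estimate_rate <- function(trace, window_policy = c("full", "best_linear"),
                          r2_min = 0.98) {
  stopifnot(inherits(trace, "vhpo_trace"))
  window_policy <- match.arg(window_policy)
  t <- trace$times; a <- trace$absorbance
  n <- length(t)
  if (window_policy == "full") {
    f <- .ols_fit(t, a)
    return(c(f, list(window = c(t[1], t[n]))))
  }
  best <- NULL
  lens <- if (n >= 5L) seq(n, 5L, by = -1L) else integer()
  for (len in lens) {                # longest first
    for (s in seq_len(n - len + 1L)) {  # earliest first
      idx <- s:(s + len - 1L)
      f <- .ols_fit(t[idx], a[idx])
      if (f$r2 >= r2_min) { best <- c(f, list(window = c(t[idx[1]], t[idx[len]]))); break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    warning("no contiguous window of >= 5 points reached the linearity threshold; using full trace")
    f <- .ols_fit(t, a)
    best <- c(f, list(window = c(t[1], t[n])))
  }
  best
}

#' Subtract a blank trace
#'
#' Point-wise subtraction of a blank (no-enzyme) trace measured on the
#' same time grid.
#'
#' @param trace,blank \code{vhpo_trace} objects on identical time grids.
#' @return The blank-corrected \code{vhpo_trace}.
#' @export
subtract_blank <- function(trace, blank) {
  stopifnot(inherits(trace, "vhpo_trace"), inherits(blank, "vhpo_trace"))
  if (!isTRUE(all.equal(trace$times, blank$times))) {
    stop("trace and blank must share the same time grid", call. = FALSE)
  }
  trace$absorbance <- trace$absorbance - blank$absorbance
  trace
}

#' Convert an absorbance rate to enzyme units
#'
#' Beer-Lambert: \code{rate_conc = slope / (eps * pathlength)} in mM/min;
#' \code{units_U = rate_conc * volume} (mM/min times uL gives nmol/min,
#' and 1 U = 1 nmol TBBr2/min). The slope direction is configurable
#' (product formation positive by default); the magnitude of the slope in
#' the configured direction is used and the direction recorded.
#'
#' @param slope Absorbance rate in AU/min.
#' @param eps Molar absorptivity (mM^-1 cm^-1), default 37.2.
#' @param pathlength Pathlength in cm.
#' @param volume Assay volume in uL.
#' @param direction \code{"increase"} (default) or \code{"decrease"}:
#'   which sign of the raw slope corresponds to product formation.
#' @param r2,window Optional fit diagnostics carried into the result.
#' @return Object of class \code{vhpo_activity}: \code{rate_abs}
#'   (AU/min, signed as observed), \code{rate_conc} (mM/min),
#'   \code{units_U}, \code{fit_r2}, \code{window}, \code{direction}.
#' @examples
#' rate_to_units(0.0372, eps = 37.2, pathlength = 1, volume = 200)$units_U  # 0.2 U
#' @export
rate_to_units <- function(slope, eps = 37.2, pathlength = 1, volume = 200,
                          direction = c("increase", "decrease"),
                          r2 = NA_real_, window = c(NA_real_, NA_real_)) {
  direction <- match.arg(direction)
  if (eps <= 0 || pathlength <= 0 || volume <= 0) {
    stop("eps, pathlength and volume must be positive", call. = FALSE)
  }
  signed <- if (direction == "increase") slope else -slope
  rate_conc <- max(signed, 0) / (eps * pathlength)  # mM/min in product direction
  structure(list(rate_abs = slope, rate_conc = rate_conc,
                 units_U = rate_conc * volume, specific_activity = NA_real_,
                 fit_r2 = r2, window = window, direction = direction,
                 eps = eps, pathlength = pathlength, volume = volume),
            class = "vhpo_activity")
}

#' @export
print.vhpo_activity <- function(x, ...) {
  cat(sprintf("Activity: %.4g U (%.4g mM/min from %.4g AU/min; eps %.3g, %g cm, %g uL)\n",
              x$units_U, x$rate_conc, x$rate_abs, x$eps, x$pathlength, x$volume))
  if (!is.na(x$specific_activity)) cat(sprintf("  specific activity: %.4g U/mg\n", x$specific_activity))
  invisible(x)
}

#' Specific activity
#'
#' @param result \code{vhpo_activity} from [rate_to_units()].
#' @param protein_mg Protein amount in mg (> 0).
#' @return The \code{vhpo_activity} with \code{specific_activity}
#'   (U/mg) filled in.
#' @export
specific_activity <- function(result, protein_mg) {
  stopifnot(inherits(result, "vhpo_activity"))
  if (!is.numeric(protein_mg) || protein_mg <= 0) {
    stop("protein_mg must be positive", call. = FALSE)
  }
  result$specific_activity <- result$units_U / protein_mg
  result
}

#' Select active chromatography fractions for pooling
#'
#' Fractions with activity at or above \code{threshold_frac} times the
#' maximum are selected; with \code{contiguous = TRUE} only the maximal
#' contiguous run containing the most active fraction is kept (the usual
#' pooling rule around a chromatographic peak).
#'
#' @param profile data.frame with \code{fraction_index} (unique,
#'   ordered) and \code{activity} columns.
#' @param threshold_frac Fraction of the maximum (default 0.5).
#' @param contiguous Keep only the run containing the argmax (default TRUE).
#' @return Integer vector of selected fraction indices (empty, with a
#'   warning, when no fraction has positive activity).
#' @export
select_active_fractions <- function(profile, threshold_frac = 0.5, contiguous = TRUE) {
  stopifnot(all(c("fraction_index", "activity") %in% names(profile)), nrow(profile) > 0)
  if (anyDuplicated(profile$fraction_index)) stop("fraction indices must be unique", call. = FALSE)
  profile <- profile[order(profile$fraction_index), , drop = FALSE]
  act <- profile$activity
  if (max(act) <= 0) {
    warning("no fraction with positive activity; empty selection")
    return(integer())
  }
  sel <- act >= threshold_frac * max(act)
  if (!contiguous) return(profile$fraction_index[sel])
  runs <- rle(sel)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  apex <- which.max(act)
  k <- which(runs$values & starts <= apex & apex <= ends)
  profile$fraction_index[starts[k]:ends[k]]
}

#' Read a kinetics TSV (sample_id, time_min, a620)
#'
#' @param path TSV path.
#' @param eps,pathlength,volume Assay constants applied to every trace.
#' @return Named list of \code{vhpo_trace} objects, one per sample.
#' @export
read_kinetics_tsv <- function(path, eps = 37.2, pathlength = 1, volume = 200) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time_min", "a620") %in% names(d)))
  lapply(split(d, d$sample_id), function(s) {
    s <- s[order(s$time_min), ]
    kinetic_trace(s$time_min, s$a620, sample_id = s$sample_id[1],
                  eps = eps, pathlength = pathlength, volume = volume)
  })
}
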