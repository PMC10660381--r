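# Trace preprocessing: blank-chamber background correction, hypoxia
# truncation, and the roster exclusion rules.

#' Fit the background-respiration slope of a blank chamber
#'
#' Ordinary least squares of DO concentration on time over the full blank
#' trace. The slope (expected non-positive) quantifies bacterial
#' respiration in the chamber water.
#'
#' @param blank A [do_series()] from a chamber with no animal.
#' @return A list of class `blank_slope` with `slope` (mg l^-1 min^-1),
#'   `intercept` (mg l^-1) and `r2`.
#' @export
fit_blank_slope <- function(blank) {
  if (length(unique(blank$time_min)) < 2L)
    stop("fit_blank_slope: degenerate trace (all times equal)", call. = FALSE)
  fit <- stats::lm(do_mg_l ~ time_min, data = blank)
  tss <- sum((blank$do_mg_l - mean(blank$do_mg_l))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2),
            class = "blank_slope")
}

#' @export
print.blank_slope <- function(x, ...) {
  cat(sprintf("<blank_slope> %.3g mg/l/min (intercept %.3g, R2 %.3f)\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Remove background respiration from an animal trace
#'
#' Subtracts the blank chamber's DO trend from the animal trace sample by
#' sample: `DO_corr(t) = DO_raw(t) - slope * (t - t0)`. With the usual
#' negative blank slope this adds back the oxygen consumed by bacteria, so
#' the corrected decline reflects the animal alone. Timestamps and length
#' are preserved.
#'
#' @param animal A [do_series()] recorded with an animal present.
#' @param blank_slope A [fit_blank_slope()] result or a bare slope
#'   (mg l^-1 min^-1).
#' @return The corrected [do_series()].
#' @export
correct_background <- function(animal, blank_slope) {
  s <- if (inherits(blank_slope, "blank_slope")) blank_slope$slope else blank_slope
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s))
  corrected <- animal$do_mg_l - s * (animal$time_min - animal$time_min[1L])
  rebuild_series(animal, animal$time_min, corrected, animal$temp_c,
                 animal$do_sat_pct)
}

#' Truncate a trace at the hypoxia threshold
#'
#' Respirometry below ~3 mg O2 l^-1 is unreliable for hypoxia-tolerant
#' shrimp, so the trace is cut before the first sample whose DO falls
#' strictly below the threshold; a sample exactly at the threshold is the
#' last usable one and is kept. The attribute `"truncated"` records whether
#' any samples were dropped (see [was_truncated()]).
#'
#' @param series A [do_series()].
#' @param threshold Hypoxia threshold, mg l^-1 (default 3).
#' @return The (possibly shortened) [do_series()].
#' @export
truncate_hypoxia <- function(series, threshold = 3) {
  stopifnot(threshold > 0)
  below <- which(series$do_mg_l < threshold)
  if (length(below) == 0L) {
    attr(series, "truncated") <- FALSE
    return(series)
  }
  keep <- below[1L] - 1L
  if (keep == 0L)
    stop("truncate_hypoxia: all samples below threshold (empty series)", call. = FALSE)
  if (keep < 2L)
    stop("truncate_hypoxia: fewer than 2 samples above threshold", call. = FALSE)
  out <- rebuild_series(series, series$time_min[1:keep], series$do_mg_l[1:keep],
                        series$temp_c[1:keep], series$do_sat_pct[1:keep])
  attr(out, "truncated") <- TRUE
  out
}

#' @rdname truncate_hypoxia
#' @param x A series returned by `truncate_hypoxia()`.
#' @export
was_truncated <- function(x) isTRUE(attr(x, "truncated"))

#' Apply trial exclusions to a roster
#'
#' Removes explicitly listed trials (with recorded reasons), and — when the
#' per-trial oxygen budgets are supplied — additionally removes any ramping
#' trial whose observed total O2 consumption is non-positive, since its log
#' residual is undefined. Returns the surviving roster together with an
#' accounting report: per direction, trials measured, removed and analysed
#' (measured = analysed + removed always holds).
#'
#' @param roster Roster data frame.
#' @param exclusion_list Optional data frame with columns `trial_id` and
#'   `reason`; an unknown trial id is an error.
#' @param budgets Optional budget table from [build_budgets()] used for the
#'   automatic non-positive-consumption rule.
#' @return A list with `roster` (filtered), `removals` (data frame
#'   `trial_id`, `reason`) and `counts` (data frame per direction).
#' @export
apply_exclusions <- function(roster, exclusion_list = NULL, budgets = NULL) {
  removals <- data.frame(trial_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(exclusion_list) && nrow(exclusion_list) > 0L) {
    unknown <- setdiff(exclusion_list$trial_id, roster$trial_id)
    if (length(unknown) > 0L)
      stop("apply_exclusions: unknown trial id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    removals <- rbind(removals,
                      data.frame(trial_id = exclusion_list$trial_id,
                                 reason = exclusion_list$reason,
                                 stringsAsFactors = FALSE))
  }
  if (!is.null(budgets) && nrow(budgets) > 0L) {
    nonpos <- budgets$trial_id[is.finite(budgets$observed_mg) &
                                 budgets$observed_mg <= 0]
    nonpos <- setdiff(intersect(nonpos, roster$trial_id), removals$trial_id)
    if (length(nonpos) > 0L)
      removals <- rbind(removals,
                        data.frame(trial_id = nonpos,
                                   reason = "non-positive observed O2 consumption",
                                   stringsAsFactors = FALSE))
  }
  surviving <- roster[!roster$trial_id %in% removals$trial_id, , drop = FALSE]
  dirs <- c("heating", "cooling", "stable")
  counts <- data.frame(
    direction = dirs,
    measured = vapply(dirs, function(d) sum(roster$direction == d), integer(1)),
    removed = vapply(dirs, function(d) {
      sum(roster$direction[roster$trial_id %in% removals$trial_id] == d)
    }, integer(1)),
    stringsAsFactors = FALSE)
  counts$analysed <- counts$measured - counts$removed
  list(roster = surviving, removals = removals, counts = counts)
}
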