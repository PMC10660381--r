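#' thermoramp: metabolic rates of aquatic ectotherms under temperature ramps
#'
#' Tools for closed-chamber respirometry of small aquatic ectotherms under
#' stable and continuously ramping temperature: trace preprocessing, MO2
#' estimation, thermal performance curve (TPC) fitting, integral prediction
#' of total oxygen consumption over a ramp, and Bayesian breakpoint
#' regression of log residuals on ramp rate. A forward simulator with known
#' ground truth supports verification of every stage.
#'
#' @keywords internal
"_PACKAGE"

# Units used throughout: time in minutes, dissolved oxygen in mg l^-1,
# temperature in degrees C, volume in litres, mass in kilograms, ramp rate
# (lambda) in degrees C per minute (signed: + heating, - cooling, 0 stable).

#' Construct a dissolved-oxygen time series
#'
#' A `do_series` is the record of one sealed chamber: time since sealing,
#' dissolved-oxygen concentration, temperature, and (optionally) DO
#' saturation, with the trial label and probe sampling rate carried as
#' attributes.
#'
#' @param time_min Numeric vector, minutes since the chamber was sealed;
#'   strictly increasing.
#' @param do_mg_l Dissolved O2 concentration, mg l^-1; non-negative.
#' @param temp_c Water temperature, degrees C.
#' @param do_sat_pct Optional DO saturation, percent.
#' @param trial_id Trial label.
#' @param sampling_rate Probe sampling rate, samples per minute.
#'
#' @return A data frame of class `do_series` with columns `time_min`,
#'   `do_mg_l`, `do_sat_pct`, `temp_c`.
#' @export
#' @examples
#' do_series(0:5, 8 - 0.01 * (0:5), temp_c = rep(15, 6))
do_series <- function(time_min, do_mg_l, temp_c, do_sat_pct = NULL,
                      trial_id = NA_character_, sampling_rate = NA_real_) {
  n <- length(time_min)
  if (n < 2L) stop("do_series: fewer than 2 rows", call. = FALSE)
  if (length(do_mg_l) != n || length(temp_c) != n)
    stop("do_series: columns have unequal lengths", call. = FALSE)
  if (is.null(do_sat_pct)) do_sat_pct <- rep(NA_real_, n)
  if (length(do_sat_pct) != n)
    stop("do_series: columns have unequal lengths", call. = FALSE)
  if (any(diff(time_min) <= 0))
    stop("do_series: non-monotone time", call. = FALSE)
  if (any(do_mg_l < 0))
    stop("do_series: negative DO concentration", call. = FALSE)
  out <- data.frame(time_min = as.numeric(time_min),
                    do_mg_l = as.numeric(do_mg_l),
                    do_sat_pct = as.numeric(do_sat_pct),
                    temp_c = as.numeric(temp_c))
  attr(out, "trial_id") <- as.character(trial_id)
  attr(out, "sampling_rate") <- as.numeric(sampling_rate)
  class(out) <- c("do_series", "data.frame")
  out
}

#' @export
print.do_series <- function(x, ...) {
  cat(sprintf("<do_series> trial %s: %d samples, %.1f-%.1f min, DO %.2f-%.2f mg/l\n",
              trial_id(x), nrow(x), min(x$time_min), max(x$time_min),
              min(x$do_mg_l), max(x$do_mg_l)))
  invisible(x)
}

#' @rdname do_series
#' @param x A `do_series`.
#' @export
trial_id <- function(x) attr(x, "trial_id")

#' @rdname do_series
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

# rebuild a do_series keeping attributes; used internally after transforms
rebuild_series <- function(template, time_min, do_mg_l, temp_c, do_sat_pct) {
  do_series(time_min, do_mg_l, temp_c, do_sat_pct,
            trial_id = trial_id(template),
            sampling_rate = sampling_rate(template))
}

#' Decode a trial identifier
#'
#' Trial identifiers follow the convention
#' `<animal>T<start><end>R<rate>`: an integer animal number, `T`, the start
#' and end temperatures as two digits each (degrees C), `R`, and the ramp
#' rate in degrees C per hour. `R0` with equal start and end temperatures
#' denotes a stable trial. The decoded ramp rate is converted to degrees C
#' per minute and signed (negative for cooling). The convention can be
#' bypassed entirely by supplying an explicit roster (see [read_roster()]).
#'
#' @param id Character trial identifier, e.g. `"105T1021R5"`.
#' @return A list with `animal_id`, `t_start_c`, `t_end_c`,
#'   `lambda_c_per_min` (signed) and `direction` (one of `"stable"`,
#'   `"heating"`, `"cooling"`).
#' @export
#' @examples
#' parse_trial_id("105T1021R5")   # animal 105, heating 10 -> 21 at 5 C/hr
#' parse_trial_id("28T2110R1")    # animal 28, cooling 21 -> 10 at 1 C/hr
parse_trial_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  m <- regmatches(id, regexec("^([0-9]+)T([0-9]{2})([0-9]{2})R([0-9]*\\.?[0-9]+)$", id))[[1]]
  if (length(m) == 0L) {
    # diagnose the offending token for a useful message
    if (!grepl("T", id, fixed = TRUE))
      stop(sprintf("malformed trial id '%s': missing 'T' separator", id), call. = FALSE)
    if (!grepl("^[0-9]+T", id))
      stop(sprintf("malformed trial id '%s': animal number before 'T' is not an integer", id), call. = FALSE)
    if (!grepl("^[0-9]+T[0-9]{4}", id))
      stop(sprintf("malformed trial id '%s': expected 2-digit start and end temperatures after 'T'", id), call. = FALSE)
    if (!grepl("R", id, fixed = TRUE))
      stop(sprintf("malformed trial id '%s': missing 'R' separator", id), call. = FALSE)
    stop(sprintf("malformed trial id '%s': rate after 'R' is not numeric", id), call. = FALSE)
  }
  t_start <- as.numeric(m[3])
  t_end <- as.numeric(m[4])
  rate_hr <- as.numeric(m[5])
  direction <- if (t_start < t_end) "heating" else if (t_start > t_end) "cooling" else "stable"
  if (direction == "stable" && rate_hr != 0)
    stop(sprintf("malformed trial id '%s': non-zero rate with equal start and end temperatures", id),
         call. = FALSE)
  lambda <- switch(direction,
                   stable = 0,
                   heating = rate_hr / 60,
                   cooling = -rate_hr / 60)
  list(animal_id = as.integer(m[2]), t_start_c = t_start, t_end_c = t_end,
       lambda_c_per_min = lambda, direction = direction)
}

#' Construct a one-row trial metadata record
#'
#' @param trial_id Trial label.
#' @param animal_id Integer animal number.
#' @param direction `"stable"`, `"heating"` or `"cooling"`.
#' @param t_start_c,t_end_c Start and end temperatures, degrees C.
#' @param lambda_c_per_min Signed ramp rate, degrees C min^-1.
#' @param mass_kg Animal wet mass, kg.
#' @param chamber_volume_l Chamber volume, litres.
#' @param acclim_temp_c Acclimation temperature, degrees C.
#' @return A one-row data frame; bind rows of these to form a roster.
#' @export
trial_meta <- function(trial_id, animal_id, direction, t_start_c, t_end_c,
                       lambda_c_per_min, mass_kg, chamber_volume_l,
                       acclim_temp_c = t_start_c) {
  out <- data.frame(trial_id = as.character(trial_id),
                    animal_id = as.integer(animal_id),
                    direction = as.character(direction),
                    t_start_c = t_start_c, t_end_c = t_end_c,
                    lambda_c_per_min = lambda_c_per_min,
                    mass_kg = mass_kg, chamber_volume_l = chamber_volume_l,
                    acclim_temp_c = acclim_temp_c,
                    stringsAsFactors = FALSE)
  issues <- roster_violations(out)
  if (nrow(issues) > 0L)
    stop("invalid trial metadata: ", paste(issues$message, collapse = "; "), call. = FALSE)
  out
}

#' Build trial metadata from an identifier
#'
#' Convenience wrapper around [parse_trial_id()] plus the physical fields.
#' @inheritParams trial_meta
#' @param id Trial identifier following the `<animal>T<start><end>R<rate>`
#'   convention.
#' @export
trial_meta_from_id <- function(id, mass_kg, chamber_volume_l = 0.2,
                               acclim_temp_c = NULL) {
  p <- parse_trial_id(id)
  trial_meta(id, p$animal_id, p$direction, p$t_start_c, p$t_end_c,
             p$lambda_c_per_min, mass_kg, chamber_volume_l,
             acclim_temp_c = if (is.null(acclim_temp_c)) p$t_start_c else acclim_temp_c)
}

# design constants: rates in C/hr and the probe sampling frequency used at
# each |lambda| (samples per minute)
design_rates_hr <- c(0.5, 1, 5, 10)
design_rates_min <- design_rates_hr / 60
design_sampling <- c(0.2, 0.5, 1, 1)
design_stable_temps <- c(10, 12, 15, 18, 21)

#' Roster invariant checks
#'
#' Checks every structural invariant of a roster (one row per trial):
#' direction/ramp-rate sign agreement, positive mass smaller than the
#' chamber volume, and (optionally) membership of |lambda| in the design
#' rate set.
#'
#' @param roster Data frame of [trial_meta()] rows.
#' @param design_rates_only If `TRUE`, flag ramp rates outside the design
#'   set \{0, 0.0083, 0.0167, 0.0833, 0.1667\} degrees C min^-1.
#' @return Data frame with columns `trial_id`, `check`, `message`; zero rows
#'   when the roster is valid.
#' @export
roster_violations <- function(roster, design_rates_only = FALSE) {
  bad <- list()
  note <- function(id, check, msg)
    bad[[length(bad) + 1L]] <<- data.frame(trial_id = id, check = check,
                                           message = msg, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(roster))) {
    r <- roster[i, ]
    dsign <- sign(r$t_end_c - r$t_start_c)
    if (sign(r$lambda_c_per_min) != dsign)
      note(r$trial_id, "lambda_sign",
           sprintf("%s: sign of lambda (%.4g) disagrees with start/end temperatures",
                   r$trial_id, r$lambda_c_per_min))
    expected_dir <- if (dsign > 0) "heating" else if (dsign < 0) "cooling" else "stable"
    if (!identical(r$direction, expected_dir))
      note(r$trial_id, "direction",
           sprintf("%s: direction '%s' inconsistent with temperatures", r$trial_id, r$direction))
    if (!(r$mass_kg > 0))
      note(r$trial_id, "mass", sprintf("%s: non-positive mass", r$trial_id))
    if (!(r$mass_kg < r$chamber_volume_l))
      note(r$trial_id, "mass",
           sprintf("%s: mass (%.4g kg) not below chamber volume (%.4g l)",
                   r$trial_id, r$mass_kg, r$chamber_volume_l))
    if (design_rates_only &&
        !any(abs(abs(r$lambda_c_per_min) - c(0, design_rates_min)) < 1e-6))
      note(r$trial_id, "rate",
           sprintf("%s: |lambda| = %.4g outside the design rate set", r$trial_id,
                   abs(r$lambda_c_per_min)))
  }
  if (length(bad) == 0L)
    return(data.frame(trial_id = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

# full-precision numeric formatting for text round trips
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read and write DO trace files
#'
#' Traces are CSV files with header `time_min,do_mg_l,do_sat_pct,temp_c`.
#' Writing uses 17 significant digits so that a write/read round trip
#' reproduces every value exactly; reading enforces the `do_series`
#' invariants (at least two rows, strictly increasing time).
#'
#' @param path File path.
#' @param trial_id,sampling_rate Attached to the returned series (the file
#'   itself stores only the four columns).
#' @return `read_do_series()` returns a [do_series()];
#'   `write_do_series()` returns `path` invisibly.
#' @export
read_do_series <- function(path, trial_id = NA_character_, sampling_rate = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "do_mg_l", "temp_c")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) < 2L) stop("fewer than 2 rows in ", path, call. = FALSE)
  if (any(diff(df$time_min) <= 0)) stop("non-monotone time in ", path, call. = FALSE)
  sat <- if ("do_sat_pct" %in% names(df)) df$do_sat_pct else NULL
  do_series(df$time_min, df$do_mg_l, df$temp_c, sat,
            trial_id = trial_id, sampling_rate = sampling_rate)
}

#' @rdname read_do_series
#' @param series A [do_series()].
#' @export
write_do_series <- function(series, path) {
  df <- data.frame(time_min = fmt_full(series$time_min),
                   do_mg_l = fmt_full(series$do_mg_l),
                   do_sat_pct = fmt_full(series$do_sat_pct),
                   temp_c = fmt_full(series$temp_c),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write trial rosters
#'
#' A roster CSV has one row per trial with the [trial_meta()] columns.
#'
#' @param path File path.
#' @return `read_roster()` returns a validated roster data frame.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "animal_id", "direction", "t_start_c", "t_end_c",
            "lambda_c_per_min", "mass_kg", "chamber_volume_l")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("roster missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"acclim_temp_c" %in% names(df)) df$acclim_temp_c <- df$t_start_c
  issues <- roster_violations(df)
  if (nrow(issues) > 0L)
    stop("invalid roster: ", paste(issues$message, collapse = "; "), call. = FALSE)
  df
}

#' @rdname read_roster
#' @param roster Roster data frame.
#' @export
write_roster <- function(roster, path) {
  out <- roster
  for (col in c("t_start_c", "t_end_c", "lambda_c_per_min", "mass_kg",
                "chamber_volume_l", "acclim_temp_c"))
    out[[col]] <- fmt_full(roster[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
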