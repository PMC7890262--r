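#' Temperature-humidity index
#'
#' Scalar heat-load measure combining air temperature and relative humidity:
#' \deqn{THI = T - (0.55 - 0.0055\,RH)\,(T - 14.5)}
#' with `T` in degrees Celsius and `RH` on a 0-100 scale.  At `T = 14.5` the
#' correction term vanishes and `THI = T` for any humidity; at `RH = 100` the
#' index equals the dry-bulb temperature.
#'
#' @param temp_c Numeric vector of air temperatures (degrees C).
#' @param rh Numeric vector of relative humidities on the 0-100 scale
#'   (recycled against `temp_c`).
#' @return Numeric vector of THI values.
#' @examples
#' thi(30, 70)   # 27.4425
#' thi(14.5, 0:100)  # all 14.5
#' @export
thi <- function(temp_c, rh) {
  if (!is.numeric(temp_c) || !is.numeric(rh)) {
    stop("temp_c and rh must be numeric")
  }
  bad <- which(!is.na(rh) & (rh < 0 | rh > 100))
  if (length(bad)) {
    stop("relative humidity must lie in [0, 100]; offending value(s): ",
         paste(utils::head(rh[bad], 5L), collapse = ", "))
  }
  temp_c - (0.55 - 0.0055 * rh) * (temp_c - 14.5)
}

#' Aggregate hourly weather to daily climate values
#'
#' Computes per station-date arithmetic means of temperature, relative
#' humidity, and the hourly THI (THI is evaluated on the hourly readings
#' first, then averaged -- not computed from the daily-mean temperature and
#' humidity).  Station-dates with no records are absent from the output
#' rather than zero-filled.
#'
#' @param hourly Data frame with columns `station`, `timestamp` (`POSIXct`,
#'   `Date`, or ISO-8601 strings), `temp_c`, `rh`.
#' @param min_hours Minimum number of hourly records required to emit a
#'   daily value (default 1).
#' @return Data frame with columns `station`, `date` (`Date`), `temp_mean`,
#'   `rh_mean`, `thi_mean`, `n_hours`, one row per retained station-date,
#'   ordered by station then date.
#' @export
daily_aggregate <- function(hourly, min_hours = 1L) {
  need <- c("station", "timestamp", "temp_c", "rh")
  miss <- setdiff(need, names(hourly))
  if (length(miss)) stop("hourly weather lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(hourly) == 0L) {
    return(data.frame(station = character(), date = as.Date(character()),
                      temp_mean = numeric(), rh_mean = numeric(),
                      thi_mean = numeric(), n_hours = integer()))
  }
  ts <- hourly$timestamp
  if (inherits(ts, "Date")) {
    date <- ts
  } else if (inherits(ts, "POSIXt")) {
    date <- as.Date(ts)
  } else {
    date <- as.Date(substr(as.character(ts), 1L, 10L))
  }
  if (anyNA(date)) stop("unparseable timestamps in hourly weather")
  h <- thi(hourly$temp_c, hourly$rh)
  key <- paste(hourly$station, format(date), sep = "\r")
  agg <- rowsum(cbind(temp = hourly$temp_c, rh = hourly$rh, thi = h,
                      n = rep(1, length(h))), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    station   = vapply(parts, `[`, "", 1L),
    date      = as.Date(vapply(parts, `[`, "", 2L)),
    temp_mean = agg[, "temp"] / agg[, "n"],
    rh_mean   = agg[, "rh"] / agg[, "n"],
    thi_mean  = agg[, "thi"] / agg[, "n"],
    n_hours   = as.integer(agg[, "n"]),
    row.names = NULL
  )
  out <- out[out$n_hours >= min_hours, , drop = FALSE]
  out <- out[order(out$station, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default lifetime age windows (days of age)
#'
#' Half-open intervals `[60, 92)`, `[92, 122)`, `[122, 152)` resolving the
#' shared endpoints of the nominal 60-92 / 92-122 / 122-152 day periods.
#' @return Named list of length-2 integer vectors `(start, end)`.
#' @export
default_windows <- function() {
  list("60_92" = c(60L, 92L), "92_122" = c(92L, 122L),
       "122_152" = c(122L, 152L))
}

#' Per-animal lifetime heat-load covariates
#'
#' For each animal, averages the daily climate values (temperature, relative
#' humidity, THI) of the station serving its farm over each age window,
#' yielding nine environmental covariates per animal (3 variables x 3
#' windows).  A window covariate requires at least `min_coverage` of the
#' window's days to be present in the daily series; animals with any
#' incomplete covariate are excluded and counted.
#'
#' @param animals Data frame with columns `animal`, `birth_date` (`Date` or
#'   ISO strings), `farm`.
#' @param farm_station Data frame with columns `farm`, `station` mapping
#'   every farm to a weather station.
#' @param daily Daily climate table from [daily_aggregate()].
#' @param windows Named list of `(start, end)` day-of-age pairs; each window
#'   covers dates `birth + start` to `birth + end - 1` (half-open on the
#'   day-of-age scale).  Default [default_windows()].
#' @param min_coverage Minimum fraction of window days that must have a
#'   daily value (default 0.8).
#' @return Data frame `animal` plus columns `thi_<w>`, `temp_<w>`, `rh_<w>`
#'   for each window label `<w>`; attribute `n_excluded` counts animals
#'   dropped for insufficient coverage.
#' @export
lifetime_covariates <- function(animals, farm_station, daily,
                                windows = default_windows(),
                                min_coverage = 0.8) {
  for (cn in c("animal", "birth_date", "farm")) {
    if (!cn %in% names(animals)) stop("animals table lacks column ", cn)
  }
  if (anyDuplicated(animals$animal)) stop("duplicate animal ids")
  unmapped <- setdiff(unique(animals$farm), farm_station$farm)
  if (length(unmapped)) {
    stop("farm(s) with no station mapping: ", paste(unmapped, collapse = ", "))
  }
  station <- farm_station$station[match(animals$farm, farm_station$farm)]
  birth <- as.Date(animals$birth_date)
  if (anyNA(birth)) stop("unparseable birth_date values")

  # index daily values by station-date for O(1) lookup
  dkey <- paste(daily$station, format(daily$date), sep = "\r")
  vars <- c(thi = "thi_mean", temp = "temp_mean", rh = "rh_mean")

  n <- nrow(animals)
  res <- list(animal = animals$animal)
  ok <- rep(TRUE, n)
  for (w in names(windows)) {
    win <- windows[[w]]
    offs <- seq.int(win[1L], win[2L] - 1L)
    ndays <- length(offs)
    # animal x day lookup of row indices into `daily`
    akey <- paste(rep(station, each = ndays),
                  format(rep(birth, each = ndays) + offs), sep = "\r")
    idx <- matrix(match(akey, dkey), nrow = ndays)
    cov_frac <- colMeans(!is.na(idx))
    ok <- ok & cov_frac >= min_coverage
    for (v in names(vars)) {
      vals <- matrix(daily[[vars[[v]]]][idx], nrow = ndays)
      res[[paste(v, w, sep = "_")]] <- colMeans(vals, na.rm = TRUE)
    }
  }
  out <- as.data.frame(res)
  n_excluded <- sum(!ok)
  if (n_excluded > 0L) {
    message("lifetime_covariates: excluded ", n_excluded,
            " animal(s) with < ", round(100 * min_coverage),
            "% daily-climate coverage in some window")
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
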