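#' Clock-time arithmetic on a continuous scale
#'
#' Adolescent bedtimes and sleep onset times straddle midnight, so the
#' package represents clock times as decimal hours on a continuous scale
#' spanning one evening-to-morning window: noon of day one (12) up to, but
#' excluding, noon of day two (36). Post-midnight times exceed 24 (e.g.
#' 04:30 becomes 28.5), which keeps averaging and latency addition free of
#' wraparound and matches the `hh:mm` display convention where `hh` may
#' exceed 23.
#'
#' `parse_clock()` converts `"hh:mm"` text to decimal hours; hours in
#' `[0, 12)` are mapped forward by +24 into the continuous domain.
#' `format_clock()` renders decimal hours back to `"hh:mm"`, rounded to the
#' nearest minute. The round trip is lossless to the minute.
#'
#' @param x Character vector of `"hh:mm"` times (`parse_clock`) or numeric
#'   decimal hours in `[12, 36)` (`format_clock`). `NA` passes through.
#' @return `parse_clock()`: numeric decimal hours in `[12, 36)`.
#'   `format_clock()`: character `"hh:mm"`.
#' @export
#' @examples
#' parse_clock(c("23:40", "28:30", "04:30"))
#' format_clock(22 + 25.7 / 60)
parse_clock <- function(x) {
  if (is.numeric(x)) {
    return(assert_clock(as.numeric(x)))
  }
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  ok <- is.na(x)
  m <- regmatches(x, regexec("^\\s*([0-9]{1,2}):([0-9]{2})\\s*$", x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    if (length(m[[i]]) != 3L) {
      abort_user(sprintf("malformed clock time '%s'; expected \"hh:mm\"", x[i]))
    }
    hh <- as.numeric(m[[i]][2])
    mm <- as.numeric(m[[i]][3])
    if (mm >= 60) {
      abort_user(sprintf("minutes must be < 60 in clock time '%s'", x[i]))
    }
    v <- hh + mm / 60
    if (v < 12) v <- v + 24
    out[i] <- v
  }
  assert_clock(out)
}

#' @rdname parse_clock
#' @export
format_clock <- function(x) {
  assert_clock(x)
  mins <- round(x * 60)
  out <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
  out[is.na(x)] <- NA_character_
  out
}

assert_clock <- function(x) {
  bad <- !is.na(x) & (x < 12 | x >= 36)
  if (any(bad)) {
    abort_user(sprintf(
      "clock time out of the continuous domain [12, 36): %s",
      paste(format(x[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")
    ))
  }
  x
}

#' Weighted average bedtime across weekday and weekend nights
#'
#' Habitual self-reported bedtime is a school-week weighted average of the
#' weekday and weekend questionnaire items: five weekday nights and two
#' weekend nights per week, i.e. `(5 * weekday + 2 * weekend) / 7`.
#'
#' @param weekday,weekend Bedtimes in decimal hours on the continuous clock
#'   scale (see [parse_clock()]).
#' @return Weighted bedtime in decimal hours.
#' @export
#' @examples
#' format_clock(weighted_bedtime(parse_clock("23:00"), parse_clock("24:45")))
weighted_bedtime <- function(weekday, weekend) {
  assert_clock(weekday)
  assert_clock(weekend)
  (5 * weekday + 2 * weekend) / 7
}

#' Sleep onset time from bedtime and sleep onset latency
#'
#' Sleep onset time (SOT) is the clock time of falling asleep: bedtime plus
#' sleep onset latency (SOL), with SOL converted from minutes to hours.
#'
#' @param bedtime Bedtime in decimal hours on the continuous clock scale.
#' @param sol Sleep onset latency in minutes, `>= 0`.
#' @return SOT in decimal hours on the continuous clock scale.
#' @export
#' @examples
#' format_clock(sleep_onset_time(parse_clock("22:00"), 25.7))
sleep_onset_time <- function(bedtime, sol) {
  assert_clock(bedtime)
  if (any(sol < 0, na.rm = TRUE)) {
    abort_user("sleep onset latency must be >= 0 minutes")
  }
  assert_clock(bedtime + sol / 60)
}
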