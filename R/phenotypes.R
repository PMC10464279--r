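#' Load and derive the nine sleep-initiation measures
#'
#' Reads a per-subject phenotype/covariate table and returns a tibble with
#' all nine sleep measures populated (see [sleep_measures()]) plus the
#' adjustment covariates. Two input layouts are accepted, and may be mixed
#' per method:
#'
#' * raw fields: `bedtime_weekday` and `bedtime_weekend` (self-report
#'   questionnaire items) plus `sol_sr`; `bedtime_act` + `sol_act`;
#'   `bedtime_psg` + `sol_psg`. Self-report bedtime is derived with
#'   [weighted_bedtime()] and every SOT with [sleep_onset_time()].
#' * precomputed measures: the nine `bedtime_*`, `sol_*`, `sot_*` columns.
#'   Supplied SOT columns are kept verbatim but checked against
#'   `bedtime + sol/60` to within one minute; a larger discrepancy is an
#'   error, since SOT is defined by that identity.
#'
#' Clock columns may be `"hh:mm"` text (hours past 23 allowed, hours below
#' 12 mapped forward past midnight; see [parse_clock()]) or numeric decimal
#' hours. Covariates are `age` (years), `sex` (1 = male), `race`
#' (1 = non-minority), `bmi_percentile` (0-100) and `batch` (categorical
#' label). Rows with any missing covariate are flagged in
#' `covariates_complete`, not dropped: per-site regressions are
#' complete-case and handle them downstream.
#'
#' @param x Path to a CSV file, or a data frame already in memory.
#' @return A tibble with `subject_id`, the nine measure columns, the five
#'   covariate columns, and a logical `covariates_complete` flag.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   subject_id = "s1", bedtime_weekday = "23:00", bedtime_weekend = "24:45",
#'   sol_sr = 20, bedtime_act = "23:59", sol_act = 7.5,
#'   bedtime_psg = "22:00", sol_psg = 25.7,
#'   age = 17, sex = 1, race = 1, bmi_percentile = 60, batch = "b1"
#' )
#' load_phenotypes(df)[, c("bedtime_sr", "sot_sr", "sot_psg")]
load_phenotypes <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    # read everything as text so "hh:mm" columns are never mangled into
    # time-of-day types, then restore purely numeric columns
    df <- readr::read_csv(x, col_types = readr::cols(.default = "c"),
                          show_col_types = FALSE, progress = FALSE)
    for (nm in names(df)) {
      v <- suppressWarnings(as.numeric(df[[nm]]))
      if (!any(is.na(v) & !is.na(df[[nm]]))) df[[nm]] <- v
    }
  } else if (is.data.frame(x)) {
    df <- tibble::as_tibble(x)
  } else {
    abort_user("`x` must be a CSV path or a data frame")
  }
  if (nrow(df) == 0L) abort_user("phenotype table is empty")

  covars <- c("age", "sex", "race", "bmi_percentile", "batch")
  missing_cols <- setdiff(c("subject_id", covars), names(df))
  if (length(missing_cols)) {
    abort_user(paste0("missing mandatory columns: ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$subject_id)) abort_user("duplicate subject_id values")

  clock_col <- function(nm) {
    if (!nm %in% names(df)) return(NULL)
    parse_clock(df[[nm]])
  }

  # self-report bedtime: weighted weekday/weekend average unless given directly
  if (!"bedtime_sr" %in% names(df)) {
    wd <- clock_col("bedtime_weekday")
    we <- clock_col("bedtime_weekend")
    if (is.null(wd) || is.null(we)) {
      abort_user(paste0("need either bedtime_sr or both bedtime_weekday ",
                        "and bedtime_weekend"))
    }
    df$bedtime_sr <- weighted_bedtime(wd, we)
  } else {
    df$bedtime_sr <- clock_col("bedtime_sr")
  }

  for (m in c("act", "psg")) {
    bt <- paste0("bedtime_", m)
    if (!bt %in% names(df)) abort_user(paste0("missing column ", bt))
    df[[bt]] <- clock_col(bt)
  }
  for (m in c("sr", "act", "psg")) {
    solc <- paste0("sol_", m)
    if (!solc %in% names(df)) abort_user(paste0("missing column ", solc))
    sol <- as.numeric(df[[solc]])
    if (any(sol < 0 | sol >= 600, na.rm = TRUE)) {
      abort_user(paste0(solc, " outside plausible bounds [0, 600) minutes"))
    }
    df[[solc]] <- sol
    sotc <- paste0("sot_", m)
    derived <- sleep_onset_time(df[[paste0("bedtime_", m)]], sol)
    if (sotc %in% names(df)) {
      df[[sotc]] <- clock_col(sotc)
      off <- abs(df[[sotc]] - derived)
      if (any(off > 1 / 60 + 1e-9, na.rm = TRUE)) {
        abort_user(paste0(sotc, " violates sot = bedtime + sol/60 by more ",
                          "than one minute"))
      }
    } else {
      df[[sotc]] <- derived
    }
  }

  df$covariates_complete <- stats::complete.cases(df[covars])
  dplyr::select(df, "subject_id", dplyr::all_of(sleep_measures()),
                dplyr::all_of(covars), "covariates_complete",
                dplyr::everything())
}
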