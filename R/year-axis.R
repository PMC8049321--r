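#' Species-year axis helpers
#'
#' The analyses run on one of two year conventions. `"calendar"` years
#' start January 1. `"adjusted"` years start June 1, so that a winter
#' migration peak (the gray-whale south-bound run) is not split across
#' calendar years; an adjusted year is labelled by the calendar year in
#' which it starts (adjusted year 1993 spans 1993-06-01 to 1994-05-31).
#'
#' @param date A `Date` vector.
#' @param convention `"calendar"` or `"adjusted"`.
#' @return `species_year()` returns the integer year label;
#'   `species_day()` the 1-based day within the species year;
#'   `species_week()` the 7-day block index with the 1-2 leftover days of
#'   the year merged into week 52.
#' @export
#' @examples
#' species_day(as.Date("1994-06-01"), "adjusted")   # 1
#' species_day(as.Date("1994-05-31"), "adjusted")   # 365
species_year <- function(date, convention = c("calendar", "adjusted")) {
  convention <- match.arg(convention)
  y <- lubridate::year(date)
  if (convention == "calendar") return(as.integer(y))
  as.integer(ifelse(lubridate::month(date) >= 6, y, y - 1))
}

#' @rdname species_year
#' @export
species_day <- function(date, convention = c("calendar", "adjusted")) {
  convention <- match.arg(convention)
  if (convention == "calendar") return(lubridate::yday(date))
  start <- as.Date(paste0(species_year(date, "adjusted"), "-06-01"))
  as.integer(date - start) + 1L
}

#' @rdname species_year
#' @export
species_week <- function(date, convention = c("calendar", "adjusted")) {
  day <- species_day(date, convention)
  pmin(ceiling(day / 7), 52L)
}

# season of a calendar month under the Dec-Feb / Mar-May / Jun-Aug /
# Sep-Nov convention
month_season <- function(month) {
  dplyr::case_when(
    month %in% c(12, 1, 2) ~ "winter",
    month %in% 3:5 ~ "spring",
    month %in% 6:8 ~ "summer",
    TRUE ~ "fall")
}

# season-year: the year a season is attributed to. Winter belongs to the
# year in which it ends (Dec 1993 counts toward winter 1994).
season_year <- function(year, month) {
  as.integer(ifelse(month == 12, year + 1, year))
}
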