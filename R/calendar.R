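# 365-day working calendar shared by all modules (leap day folded into day 365)

MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_END  <- cumsum(MONTH_DAYS)           # last day-of-year of each month
MONTH_START <- c(1L, MONTH_END[-12] + 1L)  # first day-of-year of each month

# month (1..12) containing a day-of-year in 1..365
month_of_doy <- function(doy) {
  findInterval(doy, MONTH_START)
}

# mid-month day of year, used to evaluate monthly covariates
mid_month_doy <- function(month) {
  as.integer(round((MONTH_START[month] + MONTH_END[month]) / 2))
}

# day-of-year anchors of the 8-day compositing cadence: 1, 9, ..., 361
COMPOSITE_DOY <- seq(1L, 361L, by = 8L)
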