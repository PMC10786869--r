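# Internal helpers shared across modules.

# Fractional years at mid-month: 1993-01 -> 1993 + 0.5/12.
frac_year <- function(times) {
  y <- as.integer(format(times, "%Y"))
  m <- as.integer(format(times, "%m"))
  y + (m - 0.5) / 12
}

month_of <- function(times) as.integer(format(times, "%m"))
year_of <- function(times) as.integer(format(times, "%Y"))

#' First-of-month Date sequence
#'
#' Convenience constructor for the monthly time axes used throughout.
#' @param start_year,end_year calendar years (inclusive).
#' @param start_month,end_month calendar months of the endpoints.
#' @return a Date vector, first of each month.
#' @export
monthly_times <- function(start_year, end_year, start_month = 1L, end_month = 12L) {
  seq(as.Date(sprintf("%04d-%02d-01", start_year, start_month)),
      as.Date(sprintf("%04d-%02d-01", end_year, end_month)), by = "month")
}

# period: numeric c(first_year, last_year), inclusive on calendar years.
in_period <- function(times, period) {
  if (is.null(period)) return(rep(TRUE, length(times)))
  y <- year_of(times)
  y >= period[1] & y <= period[2]
}

stop_domain <- function(...) stop(errorCondition(paste0(...), class = c("md_domain_error", "error")))
stop_validation <- function(...) stop(errorCondition(paste0(...), class = c("md_validation_error", "error")))

# Equally spaced quantile probabilities in (0, 1): (i - 0.5)/n.
dqm_probs <- function(n_quantiles) (seq_len(n_quantiles) - 0.5) / n_quantiles

# Empirical quantiles, linear interpolation between order statistics.
equantile <- function(x, probs) unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a
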