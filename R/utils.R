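# shared validators; all user-facing errors drop the internal call stack

abort_input <- function(...) stop(sprintf(...), call. = FALSE)

check_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  if (anyNA(sex) || !all(sex %in% c("female", "male"))) {
    abort_input("`sex` must be \"female\" or \"male\"")
  }
  sex
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) abort_input("%s must be a data frame", what)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort_input("%s is missing required column(s): %s", what,
                paste(miss, collapse = ", "))
  }
  invisible(df)
}

check_date <- function(x, what) {
  if (!inherits(x, "Date")) abort_input("%s must be a Date", what)
  invisible(x)
}

# elapsed time on an actual/365.25 calendar basis
years_between <- function(from, to) as.numeric(to - from) / 365.25

# truncated normal draws via inverse-CDF; exact, no rejection loop
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) abort_input("`sd` must be non-negative")
  if (all(sd == 0)) {
    if (any(mean < lower | mean > upper)) {
      abort_input("degenerate (sd = 0) draw outside [lower, upper]")
    }
    return(rep_len(mean, n))
  }
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  if (any(p_hi - p_lo < 1e-12)) {
    abort_input("truncation interval carries essentially no probability mass")
  }
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}
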