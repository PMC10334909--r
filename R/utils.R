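#' Round half away from zero
#'
#' Integer rounding where ties at .5 move away from zero (11/13 -> 84.6 -> 85,
#' 8/13 -> 61.5 -> 62), matching how spontaneous-report case series are
#' conventionally tabulated.  `base::round()` rounds half to even and would
#' print 62% as 61% on some denominators.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5, 61.5))
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# integer percent of count/total under the round-half-away rule
pct_of <- function(count, total) round_half_away(100 * count / total)

`%||%` <- function(a, b) if (is.null(a)) b else a

# collapse internal whitespace and trim
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

# FAERS dates are YYYYMMDD strings; tolerate "", NA and Date input
parse_faers_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & !grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

format_faers_date <- function(x) {
  out <- format(x, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}

# quarter label ("2020Q1") for a Date vector
quarter_label <- function(date) {
  q <- (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L
  ifelse(is.na(date), NA_character_, paste0(format(date, "%Y"), "Q", q))
}
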