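#' Number of cell divisions over a culture period
#'
#' Simple doubling-time arithmetic used to express how long an engineered
#' epigenetic state persisted in units of mitotic divisions: a 50-day
#' culture at a ~21-hour doubling time corresponds to about 57 divisions.
#'
#' @param days Length of the culture period in days.
#' @param doubling_time_hours Population doubling time in hours (default 21).
#' @return Estimated number of divisions (not rounded).
#' @examples
#' cell_divisions(50, 21) # ~57
#' @export
cell_divisions <- function(days, doubling_time_hours = 21) {
  if (any(days < 0) || any(doubling_time_hours <= 0))
    stop("days must be >= 0 and doubling_time_hours > 0")
  days * 24 / doubling_time_hours
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")))
  invisible(df)
}
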