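# Internal helpers shared across modules.

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL means "use the current stream" (no isolation).
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying < 2^31.
#' @noRd
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483640L) + 1L
}

#' @noRd
fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' @noRd
parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# Day-of-week with the package-wide Monday = 0 convention.
#' @noRd
dow_index <- function(t) (as.POSIXlt(t, tz = "UTC")$wday + 6L) %% 7L

#' @noRd
month_index <- function(t) as.POSIXlt(t, tz = "UTC")$mon + 1L

#' @noRd
hour_real <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' @noRd
day_of_month <- function(t) as.POSIXlt(t, tz = "UTC")$mday

# Calendar quarter Q1..Q4 of a timestamp.
#' @noRd
quarter_of <- function(t) (month_index(t) - 1L) %/% 3L + 1L
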