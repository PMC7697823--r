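#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so that seeded package
#' functions do not clobber user randomness.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Parse EHR timestamps
#'
#' Accepts POSIXct, Date, or character in ISO-8601 (`2189-12-24T07:15:00`) or
#' `"YYYY-MM-DD HH:MM:SS"` / `"YYYY-MM-DD"` form. All times are treated as
#' timezone-naive local hospital time and represented in UTC.
#'
#' @param x Vector of timestamps.
#' @return POSIXct vector (UTC).
#' @keywords internal
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  x <- as.character(x)
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) {
    bad <- x[is.na(out)][1]
    stop("unparseable timestamp: ", bad, call. = FALSE)
  }
  out
}

# calendar day index of `ts` relative to `origin` (day 1 = admission date)
day_index <- function(ts, origin) {
  as.integer(as.Date(ts, tz = "UTC") - as.Date(origin, tz = "UTC")) + 1L
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
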