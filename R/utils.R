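# shared helpers: duration tokens, code normalization, deterministic RNG streams

#' Parse a duration token into whole days
#'
#' Durations on the command line and in run configurations are written in the
#' compact token forms used throughout the tool: `"5Y"`, `"6M"`, `"183D"`, or a
#' bare integer number of days. All gap arithmetic is done in whole days to
#' avoid calendar ambiguity; one month counts as 30.5 days and one year as
#' 365.25 days, truncated to a whole day after scaling (so `"6M"` = 183 days
#' and `"5Y"` = 1826 days).
#'
#' @param x a single duration token (character) or a non-negative number of
#'   days.
#' @return integer number of days.
#' @examples
#' parse_duration("6M")   # 183
#' parse_duration("5Y")   # 1826
#' parse_duration("1D")   # 1
#' parse_duration(90)     # 90
#' @export
parse_duration <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 1L || is.na(x) || x < 0) stop("duration must be a single non-negative number")
    return(as.integer(x))
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) stop("invalid duration: ", deparse(x))
  tok <- toupper(trimws(x))
  m <- regmatches(tok, regexec("^([0-9]+(?:\\.[0-9]+)?)([DMY]?)$", tok))[[1]]
  if (length(m) == 0L) stop("cannot parse duration token: '", x, "'")
  n <- as.numeric(m[2])
  unit <- m[3]
  days <- switch(ifelse(unit == "", "D", unit),
    D = n,
    M = n * 30.5,
    Y = n * 365.25
  )
  as.integer(floor(days))
}

# Deterministic 31-bit hash of a string (polynomial rolling hash).
# Used to derive independent per-pair RNG streams from (seed, a, b) so that
# pair results do not depend on the order pairs are processed in or on how the
# pair iteration space is split into work units.
.hash31 <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# Seed for the RNG stream of ordered pair (a, b) under a base seed.
.pair_seed <- function(seed, a, b) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + .hash31(paste0(a, "\r", b))) %% 2147483647)
}

# run `expr` under a local RNG state seeded with `seed`, restoring the global
# state afterwards
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stop() with a message assembled from parts, no call
.fail <- function(...) stop(paste0(...), call. = FALSE)

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}
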