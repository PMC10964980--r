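# Internal helpers: validation, seeded substreams, small numerics.

stop_ilam <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_ilam("'%s' must be a single number", name)
  }
  if (finite && !is.finite(x)) stop_ilam("'%s' must be finite", name)
  if (positive && x <= 0) stop_ilam("'%s' must be > 0", name)
  invisible(x)
}

#' Evaluate code under a named, derived random substream
#'
#' All stochastic draws in the generator derive from one root seed plus a
#' stream name, so adding a new source of randomness never perturbs existing
#' ones. The caller's RNG state is restored on exit.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_substream <- function(seed, name, code) {
  # fold the stream name into a 31-bit offset (R integers are 32-bit)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  sub <- (as.double(seed) * 48271 + h * 9973) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(sub))
  force(code)
}

# squared euclidean rows of matrix `a` (n x 3) to single point p (length 3)
.dist_to_point <- function(a, p) {
  sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2 + (a[, 3] - p[3])^2)
}

# min distance between two point sets (brute force, vectorised by chunks)
.min_set_distance <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- .dist_to_point(b, a[i, ])
    m <- min(d)
    if (m < best) best <- m
  }
  best
}

#' Used-point rate as printed by the mapping stage
#'
#' @param used number of points retained for the map.
#' @param acquired number of points acquired.
#' @return percentage rounded to one decimal.
#' @examples
#' used_point_rate(2149, 19060) # 11.3
#' @export
used_point_rate <- function(used, acquired) {
  check_number(used, "used")
  check_number(acquired, "acquired", positive = TRUE)
  round(100 * used / acquired, 1)
}
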