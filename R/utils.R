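#' Study window
#'
#' The fixed 365-day follow-up window used throughout the model
#' (1 June 2017 to 31 May 2018).
#'
#' @return A list with `start` and `end` Dates and `days = 365`.
#' @export
af_study_window <- function() {
  list(start = as.Date("2017-06-01"), end = as.Date("2018-05-31"), days = 365L)
}

## Named child RNG streams: every generator draws from a stream derived from
## (seed, stream name), so adding a generator never perturbs the others.
child_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000000007
  as.integer((abs(seed) * 7919 + h) %% 2147483629 + 1)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(seed, name))
  code
}

stop_af <- function(msg, class) {
  stop(structure(class = c(class, "af_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, min = -Inf, max = Inf, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_af(sprintf("field '%s' must be numeric and non-missing", name),
            "af_validation_error")
  }
  if (!is.null(len) && length(x) != len) {
    stop_af(sprintf("field '%s' must have length %d", name, len),
            "af_validation_error")
  }
  if (any(x < min) || any(x > max)) {
    stop_af(sprintf("field '%s' must lie in [%s, %s]", name,
                    format(min), format(max)), "af_validation_error")
  }
  invisible(x)
}

## negative-binomial size parameter from a (mean, sd) pair; Poisson limit when
## the pair is under-dispersed.
nb_size <- function(mu, sigma) {
  v <- sigma^2
  ifelse(v > mu & mu > 0, mu^2 / (v - mu), Inf)
}

rcount <- function(n, mu, sigma) {
  if (n == 0L) return(integer(0))
  if (mu <= 0) return(integer(n))
  size <- nb_size(mu, sigma)
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, size = size, mu = mu)
}

## lognormal (meanlog, sdlog) matching a target mean and sd on the raw scale
lnorm_pars <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
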