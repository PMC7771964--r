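#' Derive a child seed from a run seed and labels
#'
#' Deterministically fans a run-level seed out into independent per-stage
#' (or per-replicate) seeds. Adding a new stage label does not perturb the
#' streams of existing stages, so pipeline randomness is stable under
#' extension. All derived seeds stay below 2^31 - 1.
#'
#' @param seed Integer run seed.
#' @param ... Labels (character or integer) identifying the stream, e.g.
#'   `child_seed(1, "cohort", 12)`.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, "moran", 3)
child_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (lab in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(lab), "|"))) {
      h <- (h * 131 + ch) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# clip a numeric vector into [lo, hi]
clip <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

# draw from a Beta distribution parameterized by mean and concentration;
# concentration = Inf gives a point mass at the mean
rbeta_mc <- function(n, mean, concentration) {
  stopifnot(mean >= 0, mean <= 1, concentration > 0)
  if (!is.finite(concentration)) return(rep(mean, n))
  if (mean == 0 || mean == 1) return(rep(mean, n))
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

# stop with a classed configuration error
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("admixdyn_config_error", "error")))
}

# stop with a classed structural error (malformed/inconsistent inputs)
structural_error <- function(msg) {
  stop(errorCondition(msg, class = c("admixdyn_structural_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decade bin of a birth year
#'
#' Decade `d` covers birth years `[d, d + 10)`, so the 1940s are 1940-1949.
#'
#' @param birth_year Numeric vector of birth years.
#' @return Integer vector of decade start years.
#' @export
#' @examples
#' decade_of(c(1949, 1950, 1993))
decade_of <- function(birth_year) as.integer(floor(birth_year / 10) * 10)
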