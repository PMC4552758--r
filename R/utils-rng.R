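# Seeded-randomness helpers. Every stochastic operation in the package draws
# from its own substream derived from one user-facing seed, so stages can be
# re-run independently yet reproducibly.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, then restores the caller's RNG state, so
#' seeded package operations never disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fixed offsets give each pipeline stage its own reproducible substream.
.substream_offsets <- c(
  tracts = 1L, trees = 2L, species = 3L, mortality = 4L,
  replant = 5L, pairs = 6L
)

#' Derive a per-purpose substream seed from a global seed
#'
#' @param seed Integer master seed.
#' @param purpose One of `"tracts"`, `"trees"`, `"species"`, `"mortality"`,
#'   `"replant"`, `"pairs"`.
#' @return An integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, purpose) {
  purpose <- match.arg(purpose, names(.substream_offsets))
  off <- .substream_offsets[[purpose]]
  as.integer((abs(as.numeric(seed)) * 101 + off) %% 2147483629)
}

# Mean and SD of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  pa <- stats::dnorm(al)
  pb <- stats::dnorm(be)
  m <- mu + sigma * (pa - pb) / z
  v <- sigma^2 * (1 + (al * pa - be * pb) / z - ((pa - pb) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Solve for truncated-normal parameters that match target moments
#'
#' Finds the underlying `(mu, sigma)` of a normal distribution such that,
#' after truncation to `[a, b]`, the distribution has the requested mean and
#' standard deviation. Used so that generated tree attributes reproduce the
#' summary statistics the inventory is calibrated to, despite truncation.
#'
#' @param mean,sd Target post-truncation mean and SD (`sd = 0` is allowed and
#'   yields a point mass at `mean`).
#' @param a,b Truncation bounds with `a < mean < b`.
#' @return Named vector `c(mu, sigma)`.
#' @keywords internal
truncnorm_match <- function(mean, sd, a, b) {
  if (sd == 0) return(c(mu = mean, sigma = 0))
  stopifnot(a < mean, mean < b, sd > 0)
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), a, b)
    ((mo[["mean"]] - mean) / sd)^2 + ((mo[["sd"]] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 10000))
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  mo <- truncnorm_moments(out[["mu"]], out[["sigma"]], a, b)
  if (abs(mo[["mean"]] - mean) > 1e-6 * sd || abs(mo[["sd"]] - sd) > 1e-6 * sd) {
    stop("truncnorm_match: no truncated normal attains the requested moments ",
         "within [", a, ", ", b, "]")
  }
  out
}

# Inverse-CDF sampler for the truncated normal; deterministic given the
# RNG state, no rejection loop.
rtrunc_norm <- function(n, mu, sigma, a, b) {
  if (sigma == 0) return(rep(mu, n))
  lo <- stats::pnorm(a, mu, sigma)
  hi <- stats::pnorm(b, mu, sigma)
  stats::qnorm(stats::runif(n, lo, hi), mu, sigma)
}
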