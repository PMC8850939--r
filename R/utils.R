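`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))

## Truncated-normal sampler via inverse CDF so that draw count is fixed
## (one uniform per value), keeping streams reproducible under set.seed().
rtnorm <- function(n, mean, sd, lower = 0) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lower, mean = mean, sd = sd)
  u <- stats::runif(n, min = plo, max = 1)
  stats::qnorm(u, mean = mean, sd = sd)
}

## Moments of a normal(mu, sigma) truncated below at `lower`.
truncnorm_moments <- function(mu, sigma, lower) {
  a <- (lower - mu) / sigma
  lambda <- exp(stats::dnorm(a, log = TRUE) -
                  stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + a * lambda - lambda^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

## Underlying (mu, sigma) such that the lower-truncated normal has the
## requested mean and SD. At a truncation point several SDs below the mean
## the bias is nil and (m, s) is returned directly; otherwise the pair is
## found by Nelder-Mead on the closed-form truncated moments. Truncation
## bias is material here: a stay of 10.47 +/- 7.47 days truncated at zero
## would otherwise generate with a mean more than a day too high.
solve_truncnorm <- function(m, s, lower) {
  if ((lower - m) / s < -6) return(c(mu = m, sigma = s))
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), lower)
    (mm["mean"] - m)^2 / s^2 + (mm["sd"] - s)^2 / s^2
  }
  fit <- stats::optim(c(m, log(s)), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

## 32-bit FNV-1a over a character scalar; used for config hashes in run
## manifests. Returned as an 8-hex-digit string.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte (b < 256); keep h as a double since
    ## it exceeds R's signed 32-bit integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    ## 32-bit modular multiply by the FNV prime 16777619; split into
    ## 16-bit halves so intermediate products stay exact in doubles
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' = %g violates the required range [%g, %g]",
                 name, x, lower, upper), call. = FALSE)
  }
  invisible(x)
}

## Weighted draw of factor levels with a fixed single-uniform-per-record
## stream (sample.int with prob would consume a varying number of draws).
rcategory <- function(n, levels, prob) {
  stopifnot(length(levels) == length(prob))
  cp <- cumsum(prob) / sum(prob)
  idx <- findInterval(stats::runif(n), cp) + 1L
  levels[idx]
}
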