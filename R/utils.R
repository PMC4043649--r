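# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# log-normal parameterized by arithmetic mean and CV
lnorm_pars_mean <- function(mean, cv) {
  s2 <- log1p(cv^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# log-normal parameterized by median and CV (median = exp(meanlog))
lnorm_pars_median <- function(median, cv) {
  list(meanlog = log(median), sdlog = sqrt(log1p(cv^2)))
}

# vectorized over mean and cv; cv = 0 returns the mean exactly
rlnorm_mean <- function(n, mean, cv) {
  if (any(cv < 0)) stopf("negative CV")
  s2 <- log1p(cv^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

# multiplicative mean-1 noise
rnoise <- function(n, cv) rlnorm_mean(n, 1, cv)

# FNV-1a 32-bit hash of a deparsed R object (manifest config fingerprint)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)  # xor with a byte touches low 8 bits only
    # 32-bit multiply without double-precision overflow: split h into 16-bit halves
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  sprintf("%08x", h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
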