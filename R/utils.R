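# Internal helpers shared across modules.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

gcd_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(1L)
  Reduce(gcd2, x)
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) stop("lcm of zero is undefined")
  abs(a / gcd2(a, b) * b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

# Deterministic child seeds derived from a master seed; kept well below
# .Machine$integer.max so downstream set.seed() always receives a valid int.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 9973) %% 2147483563)
}
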