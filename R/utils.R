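# Shared helpers: rounding convention, big-integer powers, input checks.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Deterministic decimal rounding used for all reported percentages:
#' ties are rounded away from zero (so 77.075 -> 77.1 at one decimal),
#' unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

warn_ <- function(...) warning(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_(sprintf("`%s` must be a single finite number", name))
  }
}

# ---- exact big-integer power -------------------------------------------------
# Unsigned big integers as vectors of base-1e4 limbs, least-significant first.
# Only what sequence_space_size() needs: multiply and power.

big_from_int <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return(0L)
  limbs <- integer(0)
  while (n > 0) {
    limbs <- c(limbs, as.integer(n %% 10000))
    n <- n %/% 10000
  }
  limbs
}

big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
  }
  # carry propagation (values stay < 2^53 throughout: limbs < 1e4, so each
  # partial sum is < 1e8 * min(len(a), len(b)) + carry)
  carry <- 0
  for (i in seq_along(res)) {
    v <- res[i] + carry
    res[i] <- v %% 10000
    carry <- v %/% 10000
  }
  while (carry > 0) {
    res <- c(res, carry %% 10000)
    carry <- carry %/% 10000
  }
  while (length(res) > 1L && res[length(res)] == 0) res <- res[-length(res)]
  as.integer(res)
}

big_pow <- function(base, exp) {
  result <- big_from_int(1)
  b <- big_from_int(base)
  while (exp > 0) {
    if (exp %% 2 == 1) result <- big_mul(result, b)
    b <- big_mul(b, b)
    exp <- exp %/% 2
  }
  result
}

big_to_string <- function(limbs) {
  n <- length(limbs)
  parts <- sprintf("%04d", rev(limbs))
  parts[1] <- as.character(limbs[n])
  paste(parts, collapse = "")
}
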