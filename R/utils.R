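# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi) {
    stopf("'%s' must be a number in [%g, %g]", name, lo, hi)
  }
  as.numeric(x)
}

## Minimal arbitrary-precision non-negative integers, stored as little-endian
## digit vectors in base 1e7.  Only what MCC scoring needs: factorials, sums,
## comparison and decimal printing.  Clique sizes routinely push (|C|-1)!
## past 2^53, where doubles silently lose exactness.

BIG_BASE <- 1e7

big_from_int <- function(n) {
  n <- as.numeric(n)
  if (n < BIG_BASE) return(n)
  d <- numeric(0)
  while (n > 0) {
    d <- c(d, n %% BIG_BASE)
    n <- (n - n %% BIG_BASE) / BIG_BASE
  }
  d
}

big_norm <- function(a) {
  carry <- 0
  for (i in seq_along(a)) {
    v <- a[i] + carry
    a[i] <- v %% BIG_BASE
    carry <- (v - a[i]) / BIG_BASE
  }
  while (carry > 0) {
    a <- c(a, carry %% BIG_BASE)
    carry <- (carry - carry %% BIG_BASE) / BIG_BASE
  }
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  a
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# multiply by a small ordinary integer k (k * digit must stay < 2^53)
big_mul_small <- function(a, k) big_norm(a * k)

big_factorial <- function(n) {
  out <- 1
  if (n <= 1) return(out)
  for (k in 2:n) out <- big_mul_small(out, k)
  out
}

big_to_string <- function(a) {
  a <- rev(a)
  paste0(a[1], paste(sprintf("%07.0f", a[-1]), collapse = ""))
}

big_to_num <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

# zero-pad decimal strings to a common width so lexicographic order equals
# numeric order
pad_decimal <- function(s) {
  w <- max(nchar(s))
  vapply(s, function(x) paste0(strrep("0", w - nchar(x)), x), "", USE.NAMES = FALSE)
}

# fixed 6-significant-digit formatting for reproducible CSV digests
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

write_table_6sig <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
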