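#' Exact binomial coefficient as a big integer
#'
#' The number of distinct k-gene subsets of n candidates overflows
#' doubles long before panel-sized inputs (choose(770, 10) is about
#' 1.9e22, past the 2^53 integer range of a double), so the product
#' \eqn{\prod_{i=1}^{k} (n-k+i)/i} is evaluated in exact arbitrary-
#' precision integer arithmetic (the division at every step is exact).
#'
#' @param n,k non-negative integers, k <= n.
#' @return The exact value as a decimal string of class `gmr_bigint`;
#'   `as.numeric()` converts (with the usual double rounding).
#' @export
choose_exact <- function(n, k) {
  if (n < 0 || k < 0 || k > n || n != floor(n) || k != floor(k))
    stop("choose_exact: need integers 0 <= k <= n")
  base <- 1e9
  ## little-endian base-1e9 digit vector
  acc <- 1
  mul_small <- function(v, m) {
    carry <- 0
    for (i in seq_along(v)) {
      x <- v[i] * m + carry
      v[i] <- x %% base
      carry <- x %/% base
    }
    while (carry > 0) {
      v <- c(v, carry %% base)
      carry <- carry %/% base
    }
    v
  }
  div_small <- function(v, d) {
    rem <- 0
    for (i in rev(seq_along(v))) {
      x <- rem * base + v[i]
      v[i] <- x %/% d
      rem <- x %% d
    }
    if (rem != 0) stop("choose_exact: internal non-exact division")
    while (length(v) > 1 && v[length(v)] == 0) v <- v[-length(v)]
    v
  }
  for (i in seq_len(k)) {
    acc <- mul_small(acc, n - k + i)
    acc <- div_small(acc, i)
  }
  acc_rev <- rev(acc)
  rest <- if (length(acc_rev) > 1)
    paste0(formatC(acc_rev[-1], width = 9, flag = "0", format = "d"),
           collapse = "")
  else ""
  structure(paste0(formatC(acc_rev[1], format = "d"), rest),
            class = "gmr_bigint")
}

#' @export
print.gmr_bigint <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}

#' @export
as.numeric.gmr_bigint <- function(x, ...) as.numeric(unclass(x))

#' @export
as.character.gmr_bigint <- function(x, ...) unclass(x)
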