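# Bell numbers B_n: exact big-integer values via the Peirce (Bell) triangle,
# and a log-scale path for use inside probability computations where B_n
# overflows double precision (near n ~ 250).

# ---- arbitrary-precision non-negative integers ------------------------------
# Little-endian limb vectors in base 1e9, stored as doubles.  The triangle
# needs only addition, so this stays tiny and exact.

.BIG_BASE <- 1e9

.big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  s <- a + b
  while (any(s >= .BIG_BASE)) {
    carry <- s %/% .BIG_BASE
    s <- s %% .BIG_BASE
    top <- carry[length(carry)]
    s <- s + c(0, carry[-length(carry)])
    if (top > 0) s <- c(s, top)
  }
  s
}

.big_to_string <- function(a) {
  a <- a[seq_len(max(which(a > 0), 1))]      # strip leading zero limbs
  digits <- vapply(rev(a), function(d) sprintf("%09.0f", d), character(1))
  out <- paste0(digits, collapse = "")
  sub("^0+(?=.)", "", out, perl = TRUE)
}

.big_to_double <- function(a) {
  a <- a[seq_len(max(which(a > 0), 1))]
  L <- length(a)
  lo <- max(1L, L - 7L)
  v <- 0
  for (i in L:lo) v <- v * .BIG_BASE + a[i]
  v * .BIG_BASE^(lo - 1)
}

.big_log <- function(a) {
  a <- a[seq_len(max(which(a > 0), 1))]
  L <- length(a)
  if (L == 1) return(log(a))
  m <- a[L] * .BIG_BASE + a[L - 1]
  if (L >= 3) m <- m + a[L - 2] / .BIG_BASE
  log(m) + (L - 2) * log(.BIG_BASE)
}

# ---- caches -----------------------------------------------------------------
# .bell_env$exact : list of limb vectors, B_0 .. B_{n}
# .bell_env$row   : last Peirce-triangle row (limb vectors), to grow from
# .bell_env$logB  : log(B_0) .. log(B_m), by log-sum-exp binomial recurrence
.bell_env <- new.env(parent = emptyenv())

.bell_exact_extend <- function(n_max) {
  if (is.null(.bell_env$exact)) {
    .bell_env$exact <- list(1)       # B_0
    .bell_env$row <- list(1)         # triangle row 1
  }
  while (length(.bell_env$exact) - 1L < n_max) {
    row <- .bell_env$row
    r <- length(row)
    new_row <- vector("list", r + 1L)
    new_row[[1L]] <- row[[r]]
    for (k in seq_len(r)) new_row[[k + 1L]] <- .big_add(new_row[[k]], row[[k]])
    .bell_env$row <- new_row
    .bell_env$exact[[r + 1L]] <- new_row[[1L]]   # B_r = a(r+1, 1)
  }
  invisible(NULL)
}

.log_bell_extend <- function(n_max) {
  logB <- .bell_env$logB
  if (is.null(logB)) logB <- c(0, 0)             # log B_0, log B_1
  m <- length(logB) - 1L
  while (m < n_max) {
    # B_{m+1} = sum_{k=0}^{m} choose(m, k) B_k ; all terms positive
    terms <- lchoose(m, 0:m) + logB
    mx <- max(terms)
    logB <- c(logB, mx + log(sum(exp(terms - mx))))
    m <- m + 1L
  }
  .bell_env$logB <- logB
  invisible(NULL)
}

#' Bell numbers
#'
#' `bell_number()` computes the Bell numbers \eqn{B_n} (the number of
#' partitions of an \eqn{n}-set; equivalently the \eqn{n}-th moment of a
#' Poisson(1) variable) exactly, by the addition-only Peirce triangle in
#' big-integer arithmetic.  Values are returned as doubles: these are exact
#' for \eqn{n \le 22} (the last \eqn{B_n} below \eqn{2^{53}}) and correctly
#' rounded from the exact integer beyond that; use [bell_number_string()] for
#' the exact decimal representation at any order.
#'
#' @param n vector of non-negative integer orders.
#' @return `bell_number()`: numeric vector of \eqn{B_n} (`Inf` once the value
#'   exceeds double range); `bell_number_string()`: character vector of exact
#'   decimal integers; `log_bell_number()`: numeric vector of \eqn{\ln B_n}.
#' @examples
#' bell_number(0:6)          # 1 1 2 5 15 52 203
#' bell_number_string(13)    # "27644437"
#' log_bell_number(200)
#' @export
bell_number <- function(n) {
  n <- .check_order(n)
  if (length(n) == 0) return(numeric(0))
  .bell_exact_extend(max(n))
  vapply(n, function(k) .big_to_double(.bell_env$exact[[k + 1L]]), numeric(1))
}

#' @rdname bell_number
#' @export
bell_number_string <- function(n) {
  n <- .check_order(n)
  if (length(n) == 0) return(character(0))
  .bell_exact_extend(max(n))
  vapply(n, function(k) .big_to_string(.bell_env$exact[[k + 1L]]), character(1))
}

#' @rdname bell_number
#'
#' @details `log_bell_number()` uses a log-sum-exp form of the binomial
#'   recurrence \eqn{B_{n+1} = \sum_k \binom{n}{k} B_k}; all terms are
#'   positive, so no cancellation occurs and the relative error stays below
#'   about \eqn{10^{-12}} over the first several hundred orders.  This is the
#'   path the probability functions use, so pmf evaluation never forms
#'   \eqn{B_z/z!} directly.
#' @export
log_bell_number <- function(n) {
  n <- .check_order(n)
  if (length(n) == 0) return(numeric(0))
  .log_bell_extend(max(n))
  .bell_env$logB[n + 1L]
}

# log B_n straight from the exact big integer (slower; used for cross-checks)
.log_bell_exact <- function(n) {
  n <- .check_order(n)
  .bell_exact_extend(max(n))
  vapply(n, function(k) .big_log(.bell_env$exact[[k + 1L]]), numeric(1))
}

#' Table of Bell numbers with log values
#'
#' Convenience constructor bundling exact values (as decimal strings and
#' doubles) with their logarithms for orders \eqn{0, \dots, n_{max}}.
#'
#' @param n_max largest order, a non-negative integer.
#' @return list of class `bell_number_table` with fields `n_max`, `values`,
#'   `strings`, `log_values`.
#' @export
bell_number_table <- function(n_max) {
  n_max <- .check_order(n_max)
  stopifnot(length(n_max) == 1)
  n <- 0:n_max
  structure(
    list(n_max = n_max, values = bell_number(n),
         strings = bell_number_string(n), log_values = log_bell_number(n)),
    class = "bell_number_table")
}

.check_order <- function(n) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 0) || any(n != floor(n)))
    stop("'n' must contain non-negative integers", call. = FALSE)
  as.integer(n)
}
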