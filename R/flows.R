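#' Keep/drop affix flow grids
#'
#' For a composition multiset M, `b[l, w]` counts the length-l, weight-w
#' affixes whose weight stays w when the length drops to l - 1, and
#' `c[l, w]` those whose weight drops to w - 1. Both are determined by M
#' alone, via the row suffix sums `s[l, w] = sum_{v >= w} a[l, v]`:
#'
#'   b(l, w) = s(l - 1, w) - s(l, w + 1),
#'   c(l, w) = s(l, w) - s(l - 1, w),
#'
#' and every valid M yields b, c >= 0 with a(l,w) = b(l,w) + c(l,w) and
#' a(l,w) = b(l+1,w) + c(l+1,w+1).
#'
#' @param M a `composition_multiset`.
#' @param check validate M first (default TRUE).
#' @return An object of class `affix_flows`: a list with integer matrices
#'   `b`, `c` (n x (n+1), indexed `b[l, w + 1]` for l in 1..n) and
#'   `s` ((n+1) x (n+2), indexed `s[l + 1, w + 1]` for l in 0..n, w in
#'   0..n+1), plus `n`, `h`.
#' @examples
#' M <- composition_multiset(c("110101", "110101", "101110"))
#' fl <- affix_flow_grids(M)
#' fl$c[3, 2 + 1]  # affixes of length 3, weight 2 whose weight drops
#' @export
affix_flow_grids <- function(M, check = TRUE) {
  stopifnot(inherits(M, "composition_multiset"))
  if (check) assert_valid(M)
  a <- M$a; n <- M$n
  # s[l + 1, w + 1] = sum_{v = w}^{n} a[l, v], with an extra w = n + 1 column
  # of zeros so that s(l, w + 1) is always addressable.
  s <- matrix(0L, n + 1L, n + 2L)
  for (l in 0:n) {
    s[l + 1L, 1:(n + 1L)] <- rev(cumsum(rev(a[l + 1L, ])))
  }
  b <- matrix(0L, n, n + 1L)
  cc <- matrix(0L, n, n + 1L)
  for (l in 1:n) {
    for (w in 0:l) {
      b[l, w + 1L] <- s[l, w + 1L] - s[l + 1L, w + 2L]
      cc[l, w + 1L] <- s[l + 1L, w + 1L] - s[l, w + 1L]
    }
  }
  structure(list(b = b, c = cc, s = s, n = n, h = M$h), class = "affix_flows")
}

#' @export
print.affix_flows <- function(x, ...) {
  cat(sprintf("Affix flow grids (n = %d, h = %d): b (weight keeps), c (weight drops)\n",
              x$n, x$h))
  invisible(x)
}

#' @rdname affix_flow_grids
#' @param x an `affix_flows` object.
#' @param ... unused.
#' @method tidy affix_flows
#' @export
tidy.affix_flows <- function(x, ...) {
  n <- x$n
  grid <- expand.grid(l = 1:n, w = 0:n)
  out <- tibble::tibble(l = as.integer(grid$l), w = as.integer(grid$w),
                        b = x$b[cbind(grid$l, grid$w + 1L)],
                        c = x$c[cbind(grid$l, grid$w + 1L)])
  out <- out[out$w <= out$l & (out$b > 0L | out$c > 0L), , drop = FALSE]
  out[order(out$l, out$w), , drop = FALSE]
}

#' Branching and merging points of a composition grid
#'
#' A grid point (l, w) is branching when affixes of length l and weight w
#' both keep and drop weight as the length decreases (b(l,w) > 0 and
#' c(l,w) > 0), and merging when, read in the direction of increasing length,
#' paths join there (b(l+1,w) > 0 and c(l+1,w+1) > 0). These points are
#' properties of M shared by all of its solutions.
#'
#' @param M a `composition_multiset`.
#' @return A list with tibbles `branching` (points in \[1,n\]^2) and `merging`
#'   (points with l in 0..n-1).
#' @export
classify_points <- function(M) {
  fl <- affix_flow_grids(M)
  n <- fl$n
  br <- NULL; mg <- NULL
  for (l in 1:n) for (w in 0:l) {
    if (fl$b[l, w + 1L] > 0L && fl$c[l, w + 1L] > 0L) br <- rbind(br, c(l, w))
  }
  for (l in 0:(n - 1L)) for (w in 0:l) {
    if (fl$b[l + 1L, w + 1L] > 0L && fl$c[l + 1L, w + 2L] > 0L) {
      mg <- rbind(mg, c(l, w))
    }
  }
  as_pts <- function(m) {
    if (is.null(m)) tibble::tibble(l = integer(), w = integer())
    else tibble::tibble(l = as.integer(m[, 1L]), w = as.integer(m[, 2L]))
  }
  list(branching = as_pts(br), merging = as_pts(mg))
}
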