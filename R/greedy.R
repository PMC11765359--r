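#' Greedy reconstruction of one compatible multiset
#'
#' Builds a single CWF solution to a validated constant-weight composition
#' multiset in O(nh) time, and extracts its string multiset. At every interior
#' length l and string index k, the odd (prefix) label receives the unique
#' weight w for which the running row suffix sums satisfy
#' s(l, w + 1) < k <= s(l, w) - larger weights go to smaller k, the greedy
#' rule - and the even (suffix) labels are filled by the constant-weight
#' mirror f(l, 2k) = w_bar - f(n - l, 2k - 1). The result is always a
#' solution to M (asserted), so its multiset is compatible with M.
#'
#' @param M a `composition_multiset` of constant-weight strings.
#' @return An object of class `psr_reconstruction`: a list with `strings`
#'   (character vector of h strings), `cwf` (the constructed solution), and
#'   `M` (the input).
#' @examples
#' M <- composition_multiset(c("110101", "110101", "101110"))
#' reconstruct_one(M)$strings
#' @export
reconstruct_one <- function(M) {
  stopifnot(inherits(M, "composition_multiset"))
  assert_valid(M)
  if (is.na(M$w_bar)) stop("reconstruction requires constant weight", call. = FALSE)
  n <- M$n; h <- M$h; wb <- M$w_bar
  fl <- affix_flow_grids(M, check = FALSE)
  s <- fl$s  # s[l + 1, w + 1], suffix row sums with a zero guard column
  v <- matrix(0L, n + 1L, 2L * h)
  # boundary: f(n, m) = w_bar for every label
  v[n + 1L, ] <- wb
  if (n > 1L) {
    for (l in seq_len(n - 1L)) {
      # unique w with s(l, w+1) < k <= s(l, w): walk w downward as k grows
      w <- min(l, n)
      for (k in seq_len(h)) {
        while (w > 0L && s[l + 1L, w + 1L] < k) w <- w - 1L
        v[l + 1L, 2L * k - 1L] <- w
      }
    }
    # suffix labels by the rotational mirror
    for (l in seq_len(n - 1L)) {
      for (k in seq_len(h)) {
        v[l + 1L, 2L * k] <- wb - v[n - l + 1L, 2L * k - 1L]
      }
    }
  }
  f <- new_cwf(v, n, h, wb)
  validate_cwf(f)
  if (!is_solution(f, M)) {
    stop("internal error: greedy construction is not a solution to M",
         call. = FALSE)
  }
  structure(list(strings = strings_of_cwf(f), cwf = f, M = M),
            class = "psr_reconstruction")
}

#' @export
print.psr_reconstruction <- function(x, ...) {
  cat(sprintf("One multiset compatible with M (n = %d, h = %d, w_bar = %d):\n",
              x$M$n, x$M$h, x$M$w_bar))
  cat(paste0("  ", x$strings, collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname reconstruct_one
#' @param x a `psr_reconstruction`.
#' @param ... unused.
#' @method tidy psr_reconstruction
#' @export
tidy.psr_reconstruction <- function(x, ...) {
  r <- reverse_string(x$strings)
  tibble::tibble(string = x$strings,
                 canonical = ifelse(x$strings <= r, x$strings, r))
}

#' @rdname reconstruct_one
#' @method glance psr_reconstruction
#' @export
glance.psr_reconstruction <- function(x, ...) {
  tibble::tibble(n = x$M$n, h = x$M$h, w_bar = x$M$w_bar,
                 compatible = is_solution(x$cwf, x$M))
}
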