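#' Test for unique reconstructibility up to reversal
#'
#' A constant-weight composition multiset M determines its string multiset
#' uniquely up to reversal exactly when any one CWF solution f satisfies:
#' between each component function and its partner (m2 = m1*) there are at
#' most two maximal intervals of the discrepancy, and between any two
#' non-partner component functions at most one. The verdict does not depend
#' on which solution is inspected.
#'
#' `check_theorem1()` applies the criterion to a given solution CWF;
#' `is_unique()` first obtains a solution with [reconstruct_one()].
#'
#' @param f a constant-weight `cwf` that solves some composition multiset.
#' @return For `check_theorem1()`: a list with `unique` (logical) and
#'   `witnesses`, a tibble of all violating pairs with columns `m1`, `m2`,
#'   `partner`, `n_intervals`, `intervals` (list-column of tibbles).
#' @examples
#' g <- induce_cwf(c("1000111", "1110001", "1100011", "1010011"))
#' check_theorem1(g)$unique
#' @export
check_theorem1 <- function(f) {
  stopifnot(inherits(f, "cwf"))
  if (is.na(f$w_bar)) {
    stop("the uniqueness criterion applies to constant-weight CWFs",
         call. = FALSE)
  }
  labels <- seq_len(2L * f$h)
  wit <- list()
  for (m1 in labels) {
    for (m2 in labels[labels > m1]) {
      ivs <- maximal_intervals(f, m1, m2)
      partner <- star(m1) == m2
      limit <- if (partner) 2L else 1L
      if (nrow(ivs) > limit) {
        wit[[length(wit) + 1L]] <- tibble::tibble(
          m1 = m1, m2 = m2, partner = partner,
          n_intervals = nrow(ivs), intervals = list(ivs))
      }
    }
  }
  witnesses <- if (length(wit)) do.call(rbind, wit) else
    tibble::tibble(m1 = integer(), m2 = integer(), partner = logical(),
                   n_intervals = integer(), intervals = list())
  list(unique = nrow(witnesses) == 0L, witnesses = witnesses)
}

#' @rdname check_theorem1
#' @param M a validated constant-weight `composition_multiset`.
#' @return For `is_unique()`: a list with `unique`, `witnesses`, and `cwf`
#'   (the solution used).
#' @examples
#' M <- composition_multiset(c("110101", "110101", "101110"))
#' is_unique(M)$unique
#' @export
is_unique <- function(M) {
  sol <- reconstruct_one(M)
  res <- check_theorem1(sol$cwf)
  res$cwf <- sol$cwf
  res
}
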