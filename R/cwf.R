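#' Cumulative weight functions
#'
#' A cumulative weight function (CWF) records the running weights of h
#' strings read from both ends: a grid f(l, m) for affix lengths l in 0..n
#' and labels m in 1..2h, where odd label 2j - 1 tracks the prefixes of the
#' j-th string and even label 2j its suffixes. A CWF satisfies
#' (i) f(0, m) = 0, (ii) unit steps f(l, m) - f(l - 1, m) in \{0, 1\}, and
#' (iii) the rotational pairing f(l, 2j - 1) + f(n - l, 2j) = w_j. When all
#' strings share weight w_bar the CWF is constant weight, and each component
#' function f_m is the 180-degree rotation of its partner f_{m*} about
#' (n/2, w_bar/2).
#'
#' @name cwf
NULL

# Internal constructor; values is an (n+1) x (2h) integer matrix,
# values[l + 1, m] = f(l, m).
new_cwf <- function(values, n, h, w_bar = NA_integer_) {
  storage.mode(values) <- "integer"
  structure(list(values = values, n = as.integer(n), h = as.integer(h),
                 w_bar = as.integer(w_bar)), class = "cwf")
}

# Internal: check the three defining conditions; returns TRUE/character.
cwf_violations <- function(f) {
  v <- f$values; n <- f$n; h <- f$h
  msgs <- character()
  if (any(v[1L, ] != 0L)) msgs <- c(msgs, "f(0, m) != 0 for some m")
  if (n >= 1L) {
    st <- v[-1L, , drop = FALSE] - v[-(n + 1L), , drop = FALSE]
    if (any(st != 0L & st != 1L)) msgs <- c(msgs, "non-unit step")
  }
  for (j in seq_len(h)) {
    su <- v[1L + 0:n, 2L * j - 1L] + v[1L + n:0, 2L * j]
    if (length(unique(su)) != 1L) {
      msgs <- c(msgs, sprintf("pair (%d, %d) violates the rotational pairing",
                              2L * j - 1L, 2L * j))
    }
  }
  if (length(msgs)) msgs else TRUE
}

#' Validate a CWF object
#'
#' @param f a `cwf`.
#' @return TRUE invisibly; errors with the violated condition otherwise.
#' @export
validate_cwf <- function(f) {
  stopifnot(inherits(f, "cwf"))
  ok <- cwf_violations(f)
  if (!isTRUE(ok)) stop("invalid CWF: ", paste(ok, collapse = "; "),
                        call. = FALSE)
  invisible(TRUE)
}

#' Partner label of a component function
#'
#' Labels 2j - 1 and 2j refer to the two ends of the same string; `star`
#' maps each label to its partner (an involution).
#'
#' @param m integer label(s) in 1..2h.
#' @param h number of strings (only used for range checking; optional).
#' @return The partner label(s).
#' @examples
#' star(1); star(6)
#' @export
star <- function(m, h = NULL) {
  m <- as.integer(m)
  if (any(m < 1L) || (!is.null(h) && any(m > 2L * h))) {
    stop("label out of range", call. = FALSE)
  }
  ifelse(m %% 2L == 0L, m - 1L, m + 1L)
}

#' Induce the CWF of a string multiset
#'
#' f(l, 2j - 1) is the weight of the length-l prefix of the j-th string and
#' f(l, 2j) the weight of its length-l suffix. The result is a solution to
#' the multiset's prefix-suffix compositions by construction.
#'
#' @param u character vector of 0/1 strings of common length and weight.
#' @return A `cwf`.
#' @examples
#' f <- induce_cwf(c("110101", "110101", "101110"))
#' cwf_value(f, l = 4, m = 5)
#' @export
induce_cwf <- function(u) {
  d <- multiset_dims(u, constant_weight = TRUE)
  n <- d$n; h <- d$h
  v <- matrix(0L, n + 1L, 2L * h)
  for (j in seq_len(h)) {
    bits <- bits_of(u[j])
    v[, 2L * j - 1L] <- c(0L, cumsum(bits))
    v[, 2L * j] <- c(0L, cumsum(rev(bits)))
  }
  f <- new_cwf(v, n, h, d$w_bar)
  validate_cwf(f)
  f
}

#' Value of a component function
#'
#' @param f a `cwf`.
#' @param l affix length in 0..n.
#' @param m label in 1..2h.
#' @return f(l, m).
#' @export
cwf_value <- function(f, l, m) {
  stopifnot(inherits(f, "cwf"))
  f$values[l + 1L, m]
}

#' Extract the string multiset of a CWF
#'
#' The j-th string has bit t_l = f(l, 2j - 1) - f(l - 1, 2j - 1); inducing a
#' CWF from the result reproduces f up to reordering of label pairs.
#'
#' @param f a `cwf`.
#' @return Character vector of h strings.
#' @export
strings_of_cwf <- function(f) {
  stopifnot(inherits(f, "cwf"))
  vapply(seq_len(f$h), function(j) {
    string_of(diff(f$values[, 2L * j - 1L]))
  }, character(1L))
}

#' Maximal intervals of the discrepancy between two component functions
#'
#' The discrepancy D(m1, m2) is the set of lengths l in 1..n where
#' f_{m1}(l) != f_{m2}(l); its maximal runs \[k1, k2\] are the maximal
#' intervals. For m1 = m2 the result is empty.
#'
#' @param f a `cwf`.
#' @param m1,m2 labels in 1..2h.
#' @return A tibble with columns `k1`, `k2`, one row per interval, in
#'   increasing order.
#' @examples
#' f <- induce_cwf(c("110101", "110101", "101110"))
#' maximal_intervals(f, 1, 6)
#' @export
maximal_intervals <- function(f, m1, m2) {
  stopifnot(inherits(f, "cwf"))
  if (any(c(m1, m2) < 1L) || any(c(m1, m2) > 2L * f$h)) {
    stop("labels must lie in 1..2h", call. = FALSE)
  }
  empty <- tibble::tibble(k1 = integer(), k2 = integer())
  if (m1 == m2) return(empty)
  d <- which(f$values[-1L, m1] != f$values[-1L, m2])  # subset of 1..n
  if (!length(d)) return(empty)
  breaks <- which(diff(d) > 1L)
  starts <- d[c(1L, breaks + 1L)]
  ends <- d[c(breaks, length(d))]
  tibble::tibble(k1 = as.integer(starts), k2 = as.integer(ends))
}

#' Swap two component functions on a maximal interval
#'
#' Exchanges f_{m1} and f_{m2} on a maximal interval I of their discrepancy,
#' together with the mirrored exchange of the partner labels on
#' \{n - l : l in I\}, so that the result is again a CWF. When m2 = m1* the
#' exchange is applied once over I and its mirror image. If f is a solution
#' to a composition multiset, so is the swapped CWF.
#'
#' @param f a constant-weight `cwf`.
#' @param interval integer vector `c(k1, k2)` (a single length-1 or longer
#'   closed interval), which must be a maximal interval between f_{m1} and
#'   f_{m2}.
#' @param m1,m2 labels in 1..2h, m1 != m2.
#' @return The swapped `cwf`.
#' @examples
#' f <- induce_cwf(c("110101", "110101", "101110"))
#' g <- cwf_swap(f, c(1, 2), 1, 6)
#' strings_of_cwf(g)
#' @export
cwf_swap <- function(f, interval, m1, m2) {
  stopifnot(inherits(f, "cwf"))
  if (is.na(f$w_bar)) stop("swap requires a constant-weight CWF", call. = FALSE)
  k1 <- as.integer(interval[1L]); k2 <- as.integer(interval[length(interval)])
  ivs <- maximal_intervals(f, m1, m2)
  if (!any(ivs$k1 == k1 & ivs$k2 == k2)) {
    stop(sprintf("[%d, %d] is not a maximal interval between f_%d and f_%d",
                 k1, k2, m1, m2), call. = FALSE)
  }
  n <- f$n
  v <- f$values
  I <- k1:k2
  if (star(m1) == m2) {
    pos <- union(I, n - I)  # I and its mirror, applied once when they meet
    tmp <- v[pos + 1L, m1]
    v[pos + 1L, m1] <- v[pos + 1L, m2]
    v[pos + 1L, m2] <- tmp
  } else {
    tmp <- v[I + 1L, m1]
    v[I + 1L, m1] <- v[I + 1L, m2]
    v[I + 1L, m2] <- tmp
    Im <- n - I
    tmp <- v[Im + 1L, star(m1)]
    v[Im + 1L, star(m1)] <- v[Im + 1L, star(m2)]
    v[Im + 1L, star(m2)] <- tmp
  }
  g <- new_cwf(v, n, f$h, f$w_bar)
  validate_cwf(g)
  g
}

#' Is a CWF a solution to a composition multiset?
#'
#' A CWF f solves M exactly when, for every cell (l, w), the number of
#' component functions passing through (l, w) equals the multiplicity
#' a(l, w).
#'
#' @param f a `cwf`.
#' @param M a `composition_multiset` with matching n and h.
#' @return TRUE or FALSE.
#' @export
is_solution <- function(f, M) {
  stopifnot(inherits(f, "cwf"), inherits(M, "composition_multiset"))
  if (f$n != M$n || f$h != M$h) {
    stop("dimension mismatch between CWF and composition multiset",
         call. = FALSE)
  }
  n <- f$n
  counts <- matrix(0L, n + 1L, n + 1L)
  for (l in 0:n) {
    tab <- tabulate(f$values[l + 1L, ] + 1L, nbins = n + 1L)
    counts[l + 1L, ] <- tab
  }
  identical(counts, M$a)
}

#' Median weights and their label groups
#'
#' The median weight of a component function is
#' (f(floor(n/2), m) + f(ceil(n/2), m)) / 2, stored here as the doubled
#' integer to avoid fractional comparisons. Half strings can only pair into
#' full strings when their median weights sum to w_bar; the labels with
#' median w_bar / 2 form a group of even size in any constant-weight CWF.
#'
#' @param f a `cwf`.
#' @return A list with `doubled_median` (integer vector indexed by label) and
#'   `groups` (named list mapping doubled median value to the integer vector
#'   of labels).
#' @examples
#' g <- induce_cwf(c("1000111", "1110001", "1100011", "1010011"))
#' median_groups(g)$groups[["4"]]  # labels with median weight 2
#' @export
median_groups <- function(f) {
  stopifnot(inherits(f, "cwf"))
  n <- f$n
  med2 <- f$values[n %/% 2L + 1L, ] + f$values[(n + 1L) %/% 2L + 1L, ]
  groups <- split(seq_len(2L * f$h), med2)
  list(doubled_median = as.integer(med2), groups = groups)
}

#' @export
print.cwf <- function(x, ...) {
  cat(sprintf("Cumulative weight function: n = %d, h = %d (%d component functions)%s\n",
              x$n, x$h, 2L * x$h,
              if (!is.na(x$w_bar)) sprintf(", constant weight %d", x$w_bar) else ""))
  m <- t(x$values)
  dimnames(m) <- list(paste0("m=", seq_len(2L * x$h)), paste0("l=", 0:x$n))
  print(m)
  invisible(x)
}

#' @rdname cwf
#' @param x a `cwf`.
#' @param ... unused.
#' @method tidy cwf
#' @export
tidy.cwf <- function(x, ...) {
  grid <- expand.grid(l = 0:x$n, m = seq_len(2L * x$h))
  tibble::tibble(l = as.integer(grid$l), m = as.integer(grid$m),
                 value = x$values[cbind(grid$l + 1L, grid$m)],
                 end = ifelse(grid$m %% 2L == 1L, "prefix", "suffix"),
                 string = as.integer((grid$m + 1L) %/% 2L))
}

#' @rdname cwf
#' @method glance cwf
#' @export
glance.cwf <- function(x, ...) {
  tibble::tibble(n = x$n, h = x$h, w_bar = x$w_bar,
                 constant_weight = !is.na(x$w_bar))
}

#' Plot the component functions of a CWF
#'
#' @param object a `cwf`.
#' @param ... unused.
#' @return A ggplot object with one step line per component function.
#' @method autoplot cwf
#' @export
autoplot.cwf <- function(object, ...) {
  td <- tidy(object)
  td$label <- factor(td$m)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$l, y = .data$value,
                                   colour = .data$label,
                                   linetype = .data$end)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "affix length l", y = "running weight f(l, m)",
                  colour = "label m", linetype = NULL) +
    ggplot2::theme_minimal()
}
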