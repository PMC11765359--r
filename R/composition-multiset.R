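#' Prefix-suffix composition multiset
#'
#' The composition multiset M of a string multiset U collects, with
#' multiplicity, the compositions of all prefixes and all suffixes of every
#' member of U. It is stored densely as the grid `a` where `a(l, w)` (0-based
#' indices l in 0..n, w in 0..n) counts affixes of length l and weight w; the
#' conventional corner cell a(0, 0) = 2h is synthesized on construction. For
#' h strings of length n there are 2nh observed compositions in M.
#'
#' @param u character vector of 0/1 strings, all of the same length. For
#'   reconstruction the strings must also share a common weight.
#' @param constant_weight require a common weight (default TRUE); the
#'   reconstruction machinery only handles the constant-weight case.
#' @return An object of class `composition_multiset` with fields `a`
#'   ((n+1) x (n+1) integer matrix, 1-based as `a[l + 1, w + 1]`), `n`, `h`,
#'   and `w_bar` (NA when not constant weight).
#' @examples
#' M <- composition_multiset(c("110101", "110101", "101110"))
#' composition_count(M, zeros = 1, ones = 2)
#' @export
composition_multiset <- function(u, constant_weight = TRUE) {
  d <- multiset_dims(u, constant_weight = constant_weight)
  n <- d$n
  a <- matrix(0L, n + 1L, n + 1L)
  for (t in u) {
    wp <- cumsum(bits_of(t))
    ws <- cumsum(rev(bits_of(t)))
    for (j in seq_len(n)) {
      a[j + 1L, wp[j] + 1L] <- a[j + 1L, wp[j] + 1L] + 1L
      a[j + 1L, ws[j] + 1L] <- a[j + 1L, ws[j] + 1L] + 1L
    }
  }
  a[1L, 1L] <- 2L * d$h
  new_composition_multiset(a, n = n, h = d$h)
}

#' Construct a composition multiset from a count grid
#'
#' Low-level constructor used by the file readers and by tests that build
#' grids directly. The corner convention a(0,0) = 2h is imposed here; callers
#' supply counts for affix lengths l in 1..n only.
#'
#' @param a (n+1) x (n+1) integer matrix of counts, indexed `a[l + 1, w + 1]`,
#'   or a data frame / tibble with columns `l`, `w`, `count` (omitted cells
#'   are zero), in which case `n` must be given.
#' @param n string length.
#' @param h number of strings.
#' @return A `composition_multiset`.
#' @export
new_composition_multiset <- function(a, n, h) {
  n <- as.integer(n); h <- as.integer(h)
  if (is.data.frame(a)) {
    counts <- a
    a <- matrix(0L, n + 1L, n + 1L)
    if (nrow(counts)) {
      if (any(counts$l < 1L | counts$l > n | counts$w < 0L | counts$w > n)) {
        stop("count rows must have l in 1..n and w in 0..n", call. = FALSE)
      }
      for (i in seq_len(nrow(counts))) {
        a[counts$l[i] + 1L, counts$w[i] + 1L] <-
          a[counts$l[i] + 1L, counts$w[i] + 1L] + as.integer(counts$count[i])
      }
    }
  }
  if (!is.matrix(a) || any(dim(a) != n + 1L)) {
    stop("`a` must be an (n+1) x (n+1) matrix", call. = FALSE)
  }
  storage.mode(a) <- "integer"
  a[1L, 1L] <- 2L * h
  w_bar <- infer_weight(a, n, h)
  structure(list(a = a, n = n, h = h, w_bar = w_bar),
            class = "composition_multiset")
}

# Internal: the common weight is the unique w with a[n, w] = 2h (all 2h
# full-length affixes share it). NA when no such w exists.
infer_weight <- function(a, n, h) {
  hits <- which(a[n + 1L, ] == 2L * h) - 1L
  if (length(hits) == 1L) as.integer(hits) else NA_integer_
}

#' Look up the multiplicity of one composition
#'
#' @param M a `composition_multiset`.
#' @param zeros,ones the composition (number of zeros, number of ones).
#' @return Integer count of affixes with that composition.
#' @export
composition_count <- function(M, zeros, ones) {
  stopifnot(inherits(M, "composition_multiset"))
  l <- zeros + ones
  if (l < 0L || l > M$n || ones < 0L) return(0L)
  M$a[l + 1L, ones + 1L]
}

#' Validate a composition multiset
#'
#' Checks every structural invariant a grid must satisfy to be the
#' prefix-suffix composition multiset of h constant-weight strings of length
#' n: nonnegative counts, no weight exceeding length, row sums of 2h at every
#' affix length, a unique common weight at full length, the central symmetry
#' a(l, w) = a(n - l, w_bar - w), and nonnegativity of the derived keep/drop
#' flow grids b and c.
#'
#' @param M a `composition_multiset`.
#' @return A tibble with columns `check`, `ok`, `detail`; the attribute
#'   `"ok"` (and [is_valid_composition_multiset()]) gives the overall verdict.
#' @export
validate_composition_multiset <- function(M) {
  stopifnot(inherits(M, "composition_multiset"))
  a <- M$a; n <- M$n; h <- M$h
  rows <- list()
  add <- function(check, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(check = check, ok = ok,
                                                 detail = detail)
  }
  witness <- function(idx) {
    # idx: matrix of 1-based (row, col) positions in a
    paste(sprintf("(l=%d,w=%d)", idx[, 1L] - 1L, idx[, 2L] - 1L),
          collapse = " ")
  }

  neg <- which(a < 0L, arr.ind = TRUE)
  add("counts are nonnegative", nrow(neg) == 0L,
      if (nrow(neg)) witness(neg) else "")

  over <- which(upper.tri(a) & a > 0L, arr.ind = TRUE)  # w > l cells
  add("no composition has weight exceeding length", nrow(over) == 0L,
      if (nrow(over)) witness(over) else "")

  add("corner cell a(0,0) equals 2h", a[1L, 1L] == 2L * h,
      sprintf("a(0,0)=%d, 2h=%d", a[1L, 1L], 2L * h))

  rs <- rowSums(a)[-1L]
  bad_l <- which(rs != 2L * h)
  add("each affix length accounts for 2h compositions", length(bad_l) == 0L,
      if (length(bad_l)) paste0("l=", paste(bad_l, collapse = ",")) else "")

  add("a unique common weight w_bar exists", !is.na(M$w_bar),
      if (is.na(M$w_bar)) "row l=n has no unique w with a(n,w)=2h" else
        sprintf("w_bar=%d", M$w_bar))

  if (!is.na(M$w_bar)) {
    wb <- M$w_bar
    bad <- NULL
    for (l in 0:n) for (w in 0:wb) {
      if (a[l + 1L, w + 1L] != a[n - l + 1L, wb - w + 1L]) {
        bad <- rbind(bad, c(l + 1L, w + 1L))
      }
    }
    add("constant-weight symmetry a(l,w) = a(n-l, w_bar-w)", is.null(bad),
        if (!is.null(bad)) witness(bad) else "")
  } else {
    add("constant-weight symmetry a(l,w) = a(n-l, w_bar-w)", FALSE,
        "not checkable without w_bar")
  }

  fl <- tryCatch(affix_flow_grids(M, check = FALSE), error = function(e) NULL)
  if (is.null(fl)) {
    add("keep/drop flow grids b, c are nonnegative", FALSE,
        "flow grids not computable")
  } else {
    negb <- which(fl$b < 0L, arr.ind = TRUE)
    negc <- which(fl$c < 0L, arr.ind = TRUE)
    okf <- nrow(negb) == 0L && nrow(negc) == 0L
    det <- c(
      if (nrow(negb)) paste0("b: ", paste(sprintf("(l=%d,w=%d)", negb[, 1L],
                                                  negb[, 2L] - 1L), collapse = " ")),
      if (nrow(negc)) paste0("c: ", paste(sprintf("(l=%d,w=%d)", negc[, 1L],
                                                  negc[, 2L] - 1L), collapse = " ")))
    add("keep/drop flow grids b, c are nonnegative", okf,
        paste(det, collapse = "; "))
  }

  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$ok)
  out
}

#' @rdname validate_composition_multiset
#' @export
is_valid_composition_multiset <- function(M) {
  isTRUE(attr(validate_composition_multiset(M), "ok"))
}

# Internal: fail fast with the validation report.
assert_valid <- function(M) {
  rep <- validate_composition_multiset(M)
  if (!isTRUE(attr(rep, "ok"))) {
    bad <- rep[!rep$ok, , drop = FALSE]
    stop("invalid composition multiset:\n",
         paste(sprintf("  - %s %s", bad$check,
                       ifelse(nzchar(bad$detail), paste0("[", bad$detail, "]"), "")),
               collapse = "\n"),
         call. = FALSE)
  }
  invisible(M)
}

# Internal: grids equal?
same_multiset <- function(M1, M2) {
  M1$n == M2$n && M1$h == M2$h && identical(M1$a, M2$a)
}

#' @export
print.composition_multiset <- function(x, ...) {
  cat(sprintf("Prefix-suffix composition multiset: n = %d, h = %d, w_bar = %s\n",
              x$n, x$h, ifelse(is.na(x$w_bar), "NA", x$w_bar)))
  cat(sprintf("%d compositions over %d non-zero grid cells\n",
              2L * x$n * x$h, sum(x$a[-1L, ] > 0L)))
  invisible(x)
}

#' @rdname composition_multiset
#' @param x a `composition_multiset`.
#' @param ... unused.
#' @method tidy composition_multiset
#' @export
tidy.composition_multiset <- function(x, ...) {
  idx <- which(x$a > 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  out <- tibble::tibble(l = as.integer(idx[, 1L] - 1L),
                        w = as.integer(idx[, 2L] - 1L),
                        count = x$a[idx])
  out[out$l > 0L, , drop = FALSE]
}

#' @rdname composition_multiset
#' @method glance composition_multiset
#' @export
glance.composition_multiset <- function(x, ...) {
  tibble::tibble(n = x$n, h = x$h, w_bar = x$w_bar,
                 n_compositions = 2L * x$n * x$h,
                 valid = is_valid_composition_multiset(x))
}

#' Plot a composition grid
#'
#' Draws the non-zero cells of the a-grid with their counts, marking
#' branching and merging points, mirroring the usual grid picture used to
#' reason about running-weight paths.
#'
#' @param object a `composition_multiset`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot composition_multiset
#' @export
autoplot.composition_multiset <- function(object, ...) {
  td <- tidy(object)
  pts <- classify_points(object)
  td$role <- "plain"
  key <- paste(td$l, td$w)
  td$role[key %in% paste(pts$merging$l, pts$merging$w)] <- "merging"
  td$role[key %in% paste(pts$branching$l, pts$branching$w)] <- "branching"
  ggplot2::ggplot(td, ggplot2::aes(x = .data$l, y = .data$w)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$role), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -1) +
    ggplot2::scale_shape_manual(values = c(branching = 1, merging = 5,
                                           plain = 16)) +
    ggplot2::labs(x = "affix length l", y = "affix weight w",
                  shape = NULL) +
    ggplot2::theme_minimal()
}
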