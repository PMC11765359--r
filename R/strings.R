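#' Binary strings and their affix compositions
#'
#' A binary string is represented as a plain character scalar over the
#' alphabet \{0, 1\}; a multiset of strings is a character vector (duplicates
#' are meaningful). These helpers compute reversals, weights, and the
#' compositions (number of zeros, number of ones) of every prefix and suffix.
#'
#' @name binary-strings
NULL

# Internal: validate one or more 0/1 strings; returns invisibly.
check_bits <- function(x, arg = "x") {
  if (!is.character(x) || length(x) < 1L) {
    stop(sprintf("`%s` must be a non-empty character vector of 0/1 strings", arg),
         call. = FALSE)
  }
  bad <- !grepl("^[01]+$", x)
  if (any(bad)) {
    stop(sprintf("`%s` contains non-binary strings at positions: %s",
                 arg, paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Internal: 0/1 integer vector of a string.
bits_of <- function(t) as.integer(strsplit(t, "", fixed = TRUE)[[1]])

# Internal: string from 0/1 integer vector.
string_of <- function(bits) paste(bits, collapse = "")

#' Weight (number of ones) of binary strings
#'
#' @param x character vector of 0/1 strings.
#' @return Integer vector of weights.
#' @examples
#' string_weight(c("110101", "0000"))
#' @export
string_weight <- function(x) {
  check_bits(x)
  nchar(x) - nchar(gsub("1", "", x, fixed = TRUE))
}

#' Reverse binary strings
#'
#' Maps position i to n + 1 - i. Length and weight are preserved and the
#' operation is an involution.
#'
#' @param x character vector of 0/1 strings.
#' @return Character vector of reversed strings.
#' @examples
#' reverse_string("011101")
#' @export
reverse_string <- function(x) {
  check_bits(x)
  vapply(x, function(t) string_of(rev(bits_of(t))), character(1L),
         USE.NAMES = FALSE)
}

#' Prefix and suffix compositions of a binary string
#'
#' For each affix length j in 1..n, the composition of the length-j prefix
#' (resp. suffix) is the ordered pair (j - w, w) where w is the affix weight.
#'
#' @param t a single 0/1 string.
#' @return A tibble with one row per affix length and columns `length`,
#'   `zeros`, `ones`.
#' @examples
#' prefix_compositions("110101")
#' suffix_compositions("110101")
#' @export
prefix_compositions <- function(t) {
  check_bits(t, "t")
  if (length(t) != 1L) stop("`t` must be a single string", call. = FALSE)
  w <- cumsum(bits_of(t))
  j <- seq_along(w)
  tibble::tibble(length = j, zeros = j - w, ones = w)
}

#' @rdname prefix_compositions
#' @export
suffix_compositions <- function(t) {
  check_bits(t, "t")
  if (length(t) != 1L) stop("`t` must be a single string", call. = FALSE)
  w <- cumsum(rev(bits_of(t)))
  j <- seq_along(w)
  tibble::tibble(length = j, zeros = j - w, ones = w)
}

#' Canonical reversal-equivalence class of a string multiset
#'
#' Two multisets are reversals of each other when, for every string, the
#' summed multiplicities of the string and its reversal agree. The canonical
#' form replaces each member by the lexicographically smaller of itself and
#' its reversal and sorts the result; two multisets are reversal-equivalent
#' exactly when their canonical forms are identical.
#'
#' @param u character vector of 0/1 strings (a multiset; duplicates count).
#' @return Sorted character vector of canonical members.
#' @examples
#' canonical_class(c("110101", "110101", "101110"))
#' @export
canonical_class <- function(u) {
  check_bits(u, "u")
  r <- reverse_string(u)
  canon <- ifelse(u <= r, u, r)
  sort(canon, method = "radix")
}

# Internal: serialize a class for set comparisons.
class_key <- function(cls) paste(cls, collapse = ",")

# Internal: require all strings same length (and optionally same weight);
# returns list(n, h, w_bar or NA).
multiset_dims <- function(u, constant_weight = TRUE) {
  check_bits(u, "u")
  n <- unique(nchar(u))
  if (length(n) != 1L) {
    stop("all strings in the multiset must have the same length", call. = FALSE)
  }
  w <- unique(string_weight(u))
  if (constant_weight && length(w) != 1L) {
    stop("all strings in the multiset must have the same weight", call. = FALSE)
  }
  list(n = as.integer(n), h = length(u),
       w_bar = if (length(w) == 1L) as.integer(w) else NA_integer_)
}
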