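#' Enumerate all binary strings of given length and weight
#'
#' @param n string length.
#' @param w weight (number of ones), 0 <= w <= n.
#' @return Character vector of all choose(n, w) strings, in lexicographic
#'   order.
#' @examples
#' enumerate_weight_strings(4, 2)
#' @export
enumerate_weight_strings <- function(n, w) {
  n <- as.integer(n); w <- as.integer(w)
  if (n < 1L || w < 0L || w > n) stop("need n >= 1 and 0 <= w <= n",
                                      call. = FALSE)
  if (w == 0L) return(strrep("0", n))
  pos <- combn(n, w)
  out <- apply(pos, 2L, function(p) {
    bits <- integer(n); bits[p] <- 1L; string_of(bits)
  })
  sort(out, method = "radix")
}

#' Enumerate all constant-weight string multisets
#'
#' All multisets of size h over the weight-w strings of length n
#' (combinations with repetition, lexicographic). Intended for exhaustive
#' ground-truth sweeps on small instances.
#'
#' @param n string length.
#' @param h multiset size.
#' @param w common weight.
#' @param max_multisets safety cap on the number of multisets.
#' @return A list of character vectors, each one multiset.
#' @export
enumerate_constant_weight_multisets <- function(n, h, w, max_multisets = 2e6) {
  base <- enumerate_weight_strings(n, w)
  k <- length(base)
  total <- choose(k + h - 1L, h)
  if (total > max_multisets) {
    stop(sprintf("%.0f multisets exceed the cap of %g", total, max_multisets),
         call. = FALSE)
  }
  out <- vector("list", total)
  cnt <- 0L
  rec <- function(start, acc) {
    if (length(acc) == h) {
      cnt <<- cnt + 1L
      out[[cnt]] <<- base[acc]
      return(invisible())
    }
    for (i in start:k) rec(i, c(acc, i))
  }
  rec(1L, integer(0L))
  out
}

#' Brute-force enumeration of all compatible classes
#'
#' Independent ground truth for [reconstruct_all()] and [is_unique()]: it
#' never touches the cumulative-weight-function machinery. All candidate
#' multisets of h weight-w_bar strings are enumerated and those whose
#' prefix-suffix composition grid equals M are collected as canonical
#' reversal classes.
#'
#' With `prune = TRUE` (default) two sound reductions are applied that
#' preserve completeness: candidate strings are restricted to those whose own
#' prefix and suffix compositions stay within the support of M's grid (any
#' member of a compatible multiset must satisfy this), and partial multisets
#' whose accumulated counts already exceed a cell of the grid are abandoned.
#' With `prune = FALSE` the full combinations-with-repetition space over all
#' choose(n, w_bar) strings is walked.
#'
#' @param M a validated constant-weight `composition_multiset`.
#' @param prune apply the sound search reductions (default TRUE).
#' @param max_candidates safety cap on the candidate-string count.
#' @return An object of class `psr_classes` (see [reconstruct_all()]), with
#'   an additional attribute `n_universe`, the number of candidate multisets
#'   in the (unpruned) search universe choose(K + h - 1, h).
#' @examples
#' M <- composition_multiset(c("110101", "110101", "101110"))
#' length(oracle_reconstruct_all(M))
#' @export
oracle_reconstruct_all <- function(M, prune = TRUE, max_candidates = 1e4) {
  stopifnot(inherits(M, "composition_multiset"))
  assert_valid(M)
  if (is.na(M$w_bar)) stop("constant weight required", call. = FALSE)
  n <- M$n; h <- M$h; wb <- M$w_bar
  cand <- enumerate_weight_strings(n, wb)
  # per-candidate contribution to the a-grid, flattened column-major
  contrib <- t(vapply(cand, function(t) {
    g <- composition_multiset(t)$a
    g[1L, 1L] <- 0L
    as.integer(g)
  }, integer((n + 1L)^2L)))
  target <- as.integer(M$a)
  target[1L] <- 0L  # drop the synthetic corner; it carries no data
  if (prune) {
    keep <- vapply(seq_along(cand), function(i) {
      all(contrib[i, ] <= target)
    }, logical(1L))
    cand <- cand[keep]
    contrib <- contrib[keep, , drop = FALSE]
  }
  k <- length(cand)
  if (k > max_candidates) {
    stop(sprintf("%d candidate strings exceed the cap of %g", k,
                 max_candidates), call. = FALSE)
  }
  # hash of full-grid keys for the last level
  key_of <- function(v) paste(v, collapse = ",")
  last_keys <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(k)) {
    kk <- key_of(contrib[i, ])
    last_keys[[kk]] <- c(last_keys[[kk]], i)
  }
  hits <- list()
  rec <- function(start, depth, acc, idx) {
    if (depth == h - 1L) {
      need <- target - acc
      kk <- key_of(need)
      js <- last_keys[[kk]]
      for (j in js[js >= start]) {
        hits[[length(hits) + 1L]] <<- cand[c(idx, j)]
      }
      return(invisible())
    }
    for (i in start:k) {
      acc2 <- acc + contrib[i, ]
      if (prune && any(acc2 > target)) next
      rec(i, depth + 1L, acc2, c(idx, i))
    }
  }
  if (k > 0L) {
    if (h == 1L) {
      kk <- key_of(target)
      js <- last_keys[[kk]]
      for (j in js) hits[[length(hits) + 1L]] <- cand[j]
    } else {
      rec(1L, 0L, integer(length(target)), integer(0L))
    }
  }
  classes <- unique(lapply(hits, canonical_class))
  keys <- vapply(classes, class_key, character(1L))
  ord <- order(keys, method = "radix")
  structure(classes[ord], class = "psr_classes",
            n = n, h = h, w_bar = wb, n_leaves = NA_integer_,
            n_universe = choose(choose(n, wb) + h - 1, h))
}

#' Seeded random constant-weight multiset
#'
#' Draws h independent uniformly random weight-w strings of length n (one
#' position sample per string). When `seed` is given, the RNG state is set
#' locally and restored, so identical seeds reproduce identical multisets
#' without disturbing the caller's stream.
#'
#' @param n string length.
#' @param h number of strings.
#' @param w common weight.
#' @param seed optional integer seed.
#' @return Character vector of h strings.
#' @export
random_instance <- function(n, h, w, seed = NULL) {
  n <- as.integer(n); h <- as.integer(h); w <- as.integer(w)
  if (n < 1L || h < 1L || w < 0L || w > n) {
    stop("need n >= 1, h >= 1 and 0 <= w <= n", call. = FALSE)
  }
  draw <- function() {
    vapply(seq_len(h), function(j) {
      bits <- integer(n)
      if (w > 0L) bits[sample.int(n, w)] <- 1L
      string_of(bits)
    }, character(1L))
  }
  if (is.null(seed)) return(draw())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  draw()
}
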