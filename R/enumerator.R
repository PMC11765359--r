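#' Enumerate all bounded integer compositions
#'
#' All nonnegative integer vectors x with sum(x) = total and 0 <= x(i) <=
#' bounds(i), in ascending lexicographic order. This is the elementary step
#' both of the scan stage (splitting label groups between "weight keeps" and
#' "weight drops") and of the pairing stage.
#'
#' @param total nonnegative integer.
#' @param bounds integer vector of upper bounds (possibly empty).
#' @return A list of integer vectors; empty when infeasible.
#' @examples
#' bounded_compositions(5, c(3, 2))
#' @export
bounded_compositions <- function(total, bounds) {
  total <- as.integer(total)
  bounds <- as.integer(bounds)
  if (total < 0L || any(bounds < 0L)) {
    stop("`total` and `bounds` must be nonnegative", call. = FALSE)
  }
  q <- length(bounds)
  if (q == 0L) return(if (total == 0L) list(integer(0L)) else list())
  out <- vector("list", 0L)
  tails <- rev(cumsum(rev(bounds)))  # tails[i] = sum(bounds[i:q])
  rec <- function(i, rem, acc) {
    if (i == q) {
      if (rem <= bounds[q]) out[[length(out) + 1L]] <<- c(acc, rem)
      return(invisible())
    }
    lo <- max(0L, rem - (tails[i] - bounds[i]))
    hi <- min(bounds[i], rem)
    if (lo > hi) return(invisible())
    for (x in lo:hi) rec(i + 1L, rem - x, c(acc, x))
  }
  rec(1L, total, integer(0L))
  out
}

#' Initial label partition at the string midpoint
#'
#' The scan stage starts by partitioning the 2h component-function labels by
#' median weight. For even n the part of (doubled) median 2w has size
#' a(n/2, w); for odd n the part of doubled median 2w has size b(ceil(n/2), w)
#' and the part of doubled median 2w + 1 has size c(ceil(n/2), w + 1). The
#' part sizes must be symmetric under w -> w_bar - w for pairing to be
#' feasible.
#'
#' @param M a validated constant-weight `composition_multiset`.
#' @return A tibble with columns `doubled_median`, `size` (non-zero parts
#'   only), ordered by decreasing doubled median.
#' @examples
#' M <- composition_multiset(c("110101", "110101", "101110"))
#' initial_partition(M)
#' @export
initial_partition <- function(M) {
  stopifnot(inherits(M, "composition_multiset"))
  assert_valid(M)
  if (is.na(M$w_bar)) stop("constant weight required", call. = FALSE)
  parts <- initial_groups(M)
  out <- tibble::tibble(
    doubled_median = vapply(parts, `[[`, integer(1L), "med2"),
    size = vapply(parts, `[[`, integer(1L), "size"))
  sizes <- setNames(rep(0L, 2L * M$w_bar + 1L), 0:(2L * M$w_bar))
  sizes[as.character(out$doubled_median)] <- out$size
  if (any(sizes != rev(sizes))) {
    stop("infeasible midpoint partition: part sizes are not symmetric under ",
         "w -> w_bar - w", call. = FALSE)
  }
  if (sum(out$size) != 2L * M$h) {
    stop("midpoint partition does not account for all 2h labels", call. = FALSE)
  }
  out
}

# Internal: the midpoint groups as the scan state uses them. A group is
# list(size, med2, vals) where vals[k] is the component value at length
# k - 1; at the midpoint vals has one entry, the value at floor(n/2).
# Order: value at floor(n/2) descending, and within a value the even doubled
# median (weight keeps across the midpoint) before the odd one.
initial_groups <- function(M) {
  n <- M$n; wb <- M$w_bar; half <- n %/% 2L
  groups <- list()
  if (n %% 2L == 0L) {
    for (w in wb:0) {
      sz <- M$a[half + 1L, w + 1L]
      if (sz > 0L) groups[[length(groups) + 1L]] <-
          list(size = sz, med2 = 2L * w, vals = w)
    }
  } else {
    fl <- affix_flow_grids(M, check = FALSE)
    ceilh <- half + 1L
    for (w in wb:0) {
      sz <- fl$b[ceilh, w + 1L]
      if (sz > 0L) groups[[length(groups) + 1L]] <-
          list(size = sz, med2 = 2L * w, vals = w)
      if (w < wb) {
        sz <- fl$c[ceilh, w + 2L]  # c(ceil(n/2), w + 1): drops onto value w
        if (sz > 0L) groups[[length(groups) + 1L]] <-
            list(size = sz, med2 = 2L * w + 1L, vals = w)
      }
    }
  }
  groups
}

#' Scan stage: enumerate all half-string bookkeeping functions
#'
#' Sweeps the composition grid from the string midpoint down to length 0,
#' maintaining groups of component-function labels that share a running
#' weight profile. At every cell (l, w) each group splits between labels
#' whose weight drops to w - 1 at length l - 1 and labels whose weight keeps
#' w; the admissible split sizes are exactly the bounded compositions of
#' c(l, w) with the group sizes as bounds, and every solution spawns a
#' distinct branch. Each resulting leaf determines a distinct multiset of
#' "half strings" (weight profiles over 0..floor(n/2) with a doubled median
#' weight).
#'
#' @param M a validated constant-weight `composition_multiset`.
#' @param max_states cap on the number of simultaneously tracked branches
#'   (the search is exponential in the worst case); exceeded caps raise an
#'   error.
#' @return A list of leaves of class `psr_bookkeeping`; each leaf has
#'   `groups` (list of list(size, med2, vals) with vals the profile over
#'   0..floor(n/2)), `splits` (tibble log of every split decision with
#'   columns `l`, `w`, `sizes`, `x` - the latter two list-columns), and
#'   `n`, `h`, `w_bar`.
#' @examples
#' M <- composition_multiset(c("110101", "110101", "101110"))
#' length(scan_compositions(M))
#' @export
scan_compositions <- function(M, max_states = 1e6) {
  stopifnot(inherits(M, "composition_multiset"))
  assert_valid(M)
  if (is.na(M$w_bar)) stop("constant weight required", call. = FALSE)
  n <- M$n; h <- M$h; wb <- M$w_bar; half <- n %/% 2L
  fl <- affix_flow_grids(M, check = FALSE)
  states <- list(list(groups = initial_groups(M), splits = list()))
  if (half >= 1L) {
    for (l in half:1L) {
      nxt <- list()
      for (st in states) {
        nxt <- c(nxt, split_level(st, l, fl, wb))
        if (length(nxt) > max_states) {
          stop(sprintf("scan stage exceeded max_states = %g branches",
                       max_states), call. = FALSE)
        }
      }
      states <- nxt
    }
  }
  leaves <- lapply(states, function(st) {
    stopifnot(all(vapply(st$groups, function(g) g$vals[1L] == 0L, logical(1L))))
    splits <- if (length(st$splits)) {
      tibble::tibble(
        l = vapply(st$splits, `[[`, integer(1L), "l"),
        w = vapply(st$splits, `[[`, integer(1L), "w"),
        sizes = lapply(st$splits, `[[`, "sizes"),
        x = lapply(st$splits, `[[`, "x"))
    } else {
      tibble::tibble(l = integer(), w = integer(), sizes = list(), x = list())
    }
    structure(list(groups = st$groups, splits = splits,
                   n = n, h = h, w_bar = wb),
              class = "psr_bookkeeping")
  })
  # distinct leaves are guaranteed; a duplicate would be a logic error
  keys <- vapply(leaves, leaf_key, character(1L))
  if (anyDuplicated(keys)) {
    stop("internal error: duplicate bookkeeping leaves in the scan stage",
         call. = FALSE)
  }
  leaves
}

# Internal: serialize a leaf's multiset of (profile, median, size) groups.
leaf_key <- function(leaf) {
  gk <- vapply(leaf$groups, function(g) {
    paste(g$med2, paste(g$vals, collapse = ""), g$size, sep = ":")
  }, character(1L))
  paste(sort(gk), collapse = "|")
}

# Internal: expand one state across level l; returns the list of successor
# states at level l - 1. Cells (l, w) are processed with w descending; the
# admissible splits at distinct cells are independent, so the successors are
# their Cartesian product. Children at level l - 1, value w' are ordered:
# drops from cell (l, w' + 1) first, then keeps from cell (l, w').
split_level <- function(st, l, fl, wb) {
  buckets <- vector("list", wb + 1L)  # buckets[[w + 1]]: groups with value w
  for (g in st$groups) {
    w <- g$vals[1L]
    buckets[[w + 1L]] <- c(buckets[[w + 1L]], list(g))
  }
  # partial expansions: each carries keeps/drops per value and the split log
  partials <- list(list(keeps = vector("list", wb + 1L),
                        drops = vector("list", wb + 2L),
                        splits = st$splits))
  for (w in wb:0) {
    cell <- buckets[[w + 1L]]
    clw <- fl$c[l, w + 1L]
    if (length(cell) == 0L) {
      if (clw > 0L) stop("invalid composition multiset: no labels available ",
                         sprintf("to drop at (l=%d, w=%d)", l, w), call. = FALSE)
      next
    }
    sizes <- vapply(cell, `[[`, integer(1L), "size")
    sols <- bounded_compositions(clw, sizes)
    if (length(sols) == 0L) {
      stop(sprintf("invalid composition multiset: no admissible split at (l=%d, w=%d)",
                   l, w), call. = FALSE)
    }
    nxt <- vector("list", length(partials) * length(sols))
    k <- 0L
    for (p in partials) {
      for (x in sols) {
        keeps <- p$keeps; drops <- p$drops
        kg <- list(); dg <- list()
        for (i in seq_along(cell)) {
          g <- cell[[i]]
          if (x[i] < g$size) {
            kg[[length(kg) + 1L]] <- list(size = g$size - x[i], med2 = g$med2,
                                          vals = c(w, g$vals))
          }
          if (x[i] > 0L) {
            dg[[length(dg) + 1L]] <- list(size = x[i], med2 = g$med2,
                                          vals = c(w - 1L, g$vals))
          }
        }
        keeps[[w + 1L]] <- kg
        drops[[w + 1L]] <- dg
        splits <- p$splits
        splits[[length(splits) + 1L]] <- list(l = l, w = w, sizes = sizes,
                                              x = x)
        k <- k + 1L
        nxt[[k]] <- list(keeps = keeps, drops = drops, splits = splits)
      }
    }
    partials <- nxt
  }
  lapply(partials, function(p) {
    groups <- list()
    for (w in wb:0) {
      groups <- c(groups, p$drops[[w + 2L]], p$keeps[[w + 1L]])
    }
    list(groups = groups, splits = p$splits)
  })
}

#' @export
print.psr_bookkeeping <- function(x, ...) {
  cat(sprintf("Half-string bookkeeping leaf (n = %d, h = %d, w_bar = %d):\n",
              x$n, x$h, x$w_bar))
  for (g in x$groups) {
    cat(sprintf("  %d label(s), half profile %s, doubled median %d\n",
                g$size, paste(g$vals, collapse = ""), g$med2))
  }
  invisible(x)
}

#' Group the half strings of a bookkeeping leaf by median weight
#'
#' For each doubled median weight t the groups R_t collect the distinct half
#' profiles whose component functions have median t/2, with their label
#' multiplicities. Half strings pair into full strings only across
#' complementary medians t and 2 w_bar - t.
#'
#' @param leaf a `psr_bookkeeping` from [scan_compositions()].
#' @return An object of class `psr_half_groups`: list with `R` (list indexed
#'   by doubled median + 1; each element a list of groups), `n`, `h`,
#'   `w_bar`.
#' @export
half_profile_groups <- function(leaf) {
  stopifnot(inherits(leaf, "psr_bookkeeping"))
  R <- vector("list", 2L * leaf$w_bar + 1L)
  for (g in leaf$groups) {
    R[[g$med2 + 1L]] <- c(R[[g$med2 + 1L]], list(g))
  }
  structure(list(R = R, n = leaf$n, h = leaf$h, w_bar = leaf$w_bar),
            class = "psr_half_groups")
}

#' @rdname half_profile_groups
#' @param x a `psr_half_groups` object.
#' @param ... unused.
#' @method tidy psr_half_groups
#' @export
tidy.psr_half_groups <- function(x, ...) {
  rows <- list()
  for (t in seq_along(x$R)) {
    for (i in seq_along(x$R[[t]])) {
      g <- x$R[[t]][[i]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        doubled_median = t - 1L, group = i,
        half_profile = paste(g$vals, collapse = ""),
        half_string = string_of(diff(g$vals)),
        multiplicity = g$size)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(doubled_median = integer(), group = integer(),
                   half_profile = character(), half_string = character(),
                   multiplicity = integer())
}

# Internal: all nonnegative integer matrices with the given row and column
# sums (a transportation polytope), rows enumerated lexicographically.
transportation_matrices <- function(rowsums, colsums) {
  if (sum(rowsums) != sum(colsums)) return(list())
  r <- length(rowsums); s <- length(colsums)
  out <- list()
  rec <- function(i, rem, acc) {
    if (i > r) {
      out[[length(out) + 1L]] <<- matrix(unlist(acc), nrow = r, ncol = s,
                                         byrow = TRUE)
      return(invisible())
    }
    for (x in bounded_compositions(rowsums[i], rem)) {
      rec(i + 1L, rem - x, c(acc, list(x)))
    }
  }
  rec(1L, as.integer(colsums), list())
  out
}

# Internal: all symmetric nonnegative integer matrices with even diagonal and
# the given row sums (the self-pairing system at median weight w_bar / 2).
symmetric_even_matrices <- function(sizes) {
  r <- length(sizes)
  out <- list()
  rec <- function(i, rem, acc) {
    # rem[j]: remaining row capacity of row j given entries fixed so far
    if (i > r) {
      if (any(rem != 0L)) return(invisible())
      m <- matrix(0L, r, r)
      for (k in seq_len(r)) {
        row <- acc[[k]]  # entries (k, k), (k, k+1), ..., (k, r)
        m[k, k:r] <- row
        m[k:r, k] <- row
      }
      out[[length(out) + 1L]] <<- m
      return(invisible())
    }
    di <- seq.int(0L, rem[i], by = 2L)
    for (d in di) {
      need <- rem[i] - d
      ub <- if (i < r) rem[(i + 1L):r] else integer(0L)
      for (x in bounded_compositions(need, ub)) {
        rem2 <- rem
        rem2[i] <- 0L
        if (i < r) rem2[(i + 1L):r] <- rem2[(i + 1L):r] - x
        rec(i + 1L, rem2, c(acc, list(c(d, x))))
      }
    }
  }
  rec(1L, as.integer(sizes), list())
  out
}

#' Enumerate all pairings of half strings into full strings
#'
#' For each median weight w < w_bar / 2 the admissible pairings of the groups
#' of median w with the groups of median w_bar - w are the integer matrices
#' with row sums the sizes of the former and column sums the sizes of the
#' latter; at w = w_bar / 2 they are the symmetric matrices with even
#' diagonal and row sums the group sizes. The full solution set is the
#' Cartesian product over all medians, in deterministic lexicographic order.
#'
#' @param hg a `psr_half_groups` object.
#' @param max_solutions cap on the number of pairing combinations.
#' @return A list of pairing solutions; each is a named list mapping the
#'   doubled median weight t (as character, t in 0..w_bar) to its matrix.
#' @export
pairing_solutions <- function(hg, max_solutions = 1e6) {
  stopifnot(inherits(hg, "psr_half_groups"))
  wb <- hg$w_bar
  per_t <- list()
  for (t in 0:wb) {
    A <- hg$R[[t + 1L]]
    B <- hg$R[[2L * wb - t + 1L]]
    if (t < wb) {
      if (length(A) == 0L && length(B) == 0L) next
      if (length(A) == 0L || length(B) == 0L) {
        stop(sprintf("no pairing possible: medians %g and %g carry unequal mass",
                     t / 2, wb - t / 2), call. = FALSE)
      }
      mats <- transportation_matrices(
        vapply(A, `[[`, integer(1L), "size"),
        vapply(B, `[[`, integer(1L), "size"))
    } else {
      if (length(A) == 0L) next
      mats <- symmetric_even_matrices(vapply(A, `[[`, integer(1L), "size"))
    }
    if (length(mats) == 0L) {
      stop(sprintf("no pairing solution at doubled median %d", t),
           call. = FALSE)
    }
    per_t[[as.character(t)]] <- mats
  }
  if (length(per_t) == 0L) return(list())
  counts <- vapply(per_t, length, integer(1L))
  if (prod(counts) > max_solutions) {
    stop(sprintf("pairing stage exceeded max_solutions = %g", max_solutions),
         call. = FALSE)
  }
  idx <- expand.grid(lapply(rev(counts), seq_len))  # first key varies slowest
  idx <- idx[, rev(seq_along(counts)), drop = FALSE]
  colnames(idx) <- names(per_t)
  lapply(seq_len(nrow(idx)), function(i) {
    setNames(lapply(names(per_t), function(t) per_t[[t]][[idx[i, t]]]),
             names(per_t))
  })
}

# Internal: full running-weight profile from a prefix half u and a suffix
# half v with complementary doubled medians; returns the string.
stitch_halves <- function(u, v, n, wb) {
  if (u$med2 + v$med2 != 2L * wb) {
    stop("internal error: paired halves have non-complementary medians",
         call. = FALSE)
  }
  half <- n %/% 2L
  f <- integer(n + 1L)
  f[1:(half + 1L)] <- u$vals
  for (l in (n - half):n) {
    f[l + 1L] <- wb - v$vals[n - l + 1L]
  }
  bits <- diff(f)
  if (any(bits != 0L & bits != 1L)) {
    stop("internal error: stitched profile is not unit-step", call. = FALSE)
  }
  string_of(bits)
}

#' Assemble a full string multiset from a bookkeeping leaf and a pairing
#'
#' Each paired couple of half profiles (u with median w, v with median
#' w_bar - w) forms one string: the running prefix weight follows u up to
#' floor(n/2) and equals w_bar - v(n - l) beyond; bits are the first
#' differences. Matrix entry y(i, j) contributes that many copies (y(i, i) / 2
#' on the self-pairing diagonal).
#'
#' @param leaf a `psr_bookkeeping`.
#' @param pairing one element of [pairing_solutions()].
#' @return Character vector of h strings.
#' @export
assemble_pairing <- function(leaf, pairing) {
  stopifnot(inherits(leaf, "psr_bookkeeping"))
  hg <- half_profile_groups(leaf)
  n <- hg$n; wb <- hg$w_bar
  strings <- character(0L)
  for (t_chr in names(pairing)) {
    t <- as.integer(t_chr)
    y <- pairing[[t_chr]]
    A <- hg$R[[t + 1L]]
    B <- hg$R[[2L * wb - t + 1L]]
    if (t < wb) {
      for (i in seq_along(A)) for (j in seq_along(B)) {
        if (y[i, j] > 0L) {
          strings <- c(strings,
                       rep(stitch_halves(A[[i]], B[[j]], n, wb), y[i, j]))
        }
      }
    } else {
      for (i in seq_along(A)) for (j in seq.int(i, length(A))) {
        cnt <- if (i == j) y[i, i] %/% 2L else y[i, j]
        if (cnt > 0L) {
          strings <- c(strings,
                       rep(stitch_halves(A[[i]], A[[j]], n, wb), cnt))
        }
      }
    }
  }
  if (length(strings) != leaf$h) {
    stop("internal error: assembled multiset has wrong size", call. = FALSE)
  }
  strings
}

#' Enumerate all multisets compatible with a composition multiset
#'
#' Runs the scan stage over all bookkeeping branches and the assembly stage
#' over all admissible half-string pairings, returning every
#' reversal-equivalence class of string multisets whose prefix-suffix
#' compositions equal M. Every assembled multiset is verified against M and
#' the classes are guaranteed (and asserted) pairwise distinct. The search is
#' exponential in the worst case; `max_states` bounds it.
#'
#' @param M a validated constant-weight `composition_multiset`.
#' @param max_states cap on scan branches and pairing combinations.
#' @return An object of class `psr_classes`: a list of canonical classes
#'   (sorted character vectors), sorted lexicographically, with attributes
#'   `n`, `h`, `w_bar`, `n_leaves`.
#' @examples
#' M <- composition_multiset(c("110101", "110101", "101110"))
#' reconstruct_all(M)
#' @export
reconstruct_all <- function(M, max_states = 1e6) {
  stopifnot(inherits(M, "composition_multiset"))
  leaves <- scan_compositions(M, max_states = max_states)
  classes <- list()
  keys <- character(0L)
  for (leaf in leaves) {
    hg <- half_profile_groups(leaf)
    for (pairing in pairing_solutions(hg, max_solutions = max_states)) {
      strs <- assemble_pairing(leaf, pairing)
      if (!same_multiset(composition_multiset(strs), M)) {
        stop("internal error: assembled multiset is incompatible with M",
             call. = FALSE)
      }
      cls <- canonical_class(strs)
      key <- class_key(cls)
      if (key %in% keys) {
        stop("internal error: duplicate equivalence class assembled",
             call. = FALSE)
      }
      keys <- c(keys, key)
      classes[[length(classes) + 1L]] <- cls
    }
  }
  ord <- order(keys, method = "radix")
  structure(classes[ord], class = "psr_classes",
            n = M$n, h = M$h, w_bar = M$w_bar, n_leaves = length(leaves))
}

#' @export
print.psr_classes <- function(x, ...) {
  cat(sprintf("%d compatible multiset class(es) (n = %d, h = %d, w_bar = %d):\n",
              length(x), attr(x, "n"), attr(x, "h"), attr(x, "w_bar")))
  for (i in seq_along(x)) {
    cat(sprintf("  [%d] {%s}\n", i, paste(x[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' @rdname reconstruct_all
#' @param x a `psr_classes` object.
#' @param ... unused.
#' @method tidy psr_classes
#' @export
tidy.psr_classes <- function(x, ...) {
  if (!length(x)) {
    return(tibble::tibble(class = integer(), string = character(),
                          multiplicity = integer()))
  }
  do.call(rbind, lapply(seq_along(x), function(i) {
    tab <- table(x[[i]])
    tibble::tibble(class = i, string = names(tab),
                   multiplicity = as.integer(tab))
  }))
}

#' @rdname reconstruct_all
#' @method glance psr_classes
#' @export
glance.psr_classes <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), h = attr(x, "h"),
                 w_bar = attr(x, "w_bar"), n_classes = length(x),
                 n_scan_leaves = attr(x, "n_leaves"),
                 unique = length(x) == 1L)
}
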