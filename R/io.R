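#' Read and write string multisets as plain text
#'
#' One 0/1 string per line; `#` comment lines and blank lines are ignored.
#' Duplicates are meaningful (the file encodes a multiset).
#'
#' @param path file path.
#' @return For `read_strings()`: character vector of strings.
#' @export
read_strings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  strs <- trimws(lines[keep])
  bad <- !grepl("^[01]+$", strs)
  if (any(bad)) {
    ln <- which(keep)[bad][1L]
    stop(sprintf("non-binary string on line %d of %s: '%s'",
                 ln, path, lines[ln]), call. = FALSE)
  }
  if (!length(strs)) stop("no strings found in ", path, call. = FALSE)
  if (length(unique(nchar(strs))) != 1L) {
    stop("mixed string lengths in ", path, call. = FALSE)
  }
  strs
}

#' @rdname read_strings
#' @param u character vector of 0/1 strings.
#' @export
write_strings <- function(u, path) {
  check_bits(u, "u")
  writeLines(u, path)
  invisible(path)
}

#' Read and write composition multisets
#'
#' Two interchangeable dialects: a TSV with header comment lines `#n=<int>`
#' and `#h=<int>` followed by rows `l<TAB>w<TAB>count` (any order; omitted
#' cells are zero), and a JSON equivalent carrying `n`, `h`, and a `counts`
#' array of (l, w, count) triples. The corner cell
#' a(0,0) = 2h is never stored; it is synthesized on read. The reader
#' validates the grid and fails with the validation report.
#'
#' @param path file path; a `.json` extension (or a leading `{`) selects the
#'   JSON dialect.
#' @return For `read_compositions()`: a `composition_multiset`.
#' @export
read_compositions <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE) || grepl("^\\s*\\{", first)) {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.null(obj$n) || is.null(obj$h)) {
      stop("JSON composition table must carry n and h", call. = FALSE)
    }
    counts <- obj$counts
    df <- if (is.null(counts) || length(counts) == 0L) {
      data.frame(l = integer(), w = integer(), count = integer())
    } else {
      counts <- matrix(as.integer(counts), ncol = 3L)
      data.frame(l = counts[, 1L], w = counts[, 2L], count = counts[, 3L])
    }
    n <- as.integer(obj$n); h <- as.integer(obj$h)
  } else {
    lines <- readLines(path, warn = FALSE)
    get_header <- function(key) {
      m <- grep(sprintf("^#%s=", key), lines, value = TRUE)
      if (length(m) != 1L) {
        stop(sprintf("composition table %s must carry exactly one '#%s=' header",
                     path, key), call. = FALSE)
      }
      as.integer(sub(sprintf("^#%s=", key), "", m))
    }
    n <- get_header("n")
    h <- get_header("h")
    body <- lines[!grepl("^\\s*(#|$)", lines)]
    df <- if (length(body)) {
      parts <- strsplit(body, "\t", fixed = TRUE)
      if (any(lengths(parts) != 3L)) {
        stop("composition rows must be 'l<TAB>w<TAB>count'", call. = FALSE)
      }
      m <- matrix(as.integer(unlist(parts)), ncol = 3L, byrow = TRUE)
      data.frame(l = m[, 1L], w = m[, 2L], count = m[, 3L])
    } else {
      data.frame(l = integer(), w = integer(), count = integer())
    }
  }
  if (any(df$count < 0L)) stop("negative composition counts", call. = FALSE)
  M <- new_composition_multiset(df, n = n, h = h)
  assert_valid(M)
  M
}

#' @rdname read_compositions
#' @param M a `composition_multiset`.
#' @param format `"tsv"` (default) or `"json"`.
#' @export
write_compositions <- function(M, path, format = c("tsv", "json")) {
  stopifnot(inherits(M, "composition_multiset"))
  format <- match.arg(format)
  td <- tidy(M)  # non-zero cells with l >= 1
  if (format == "json") {
    obj <- list(n = M$n, h = M$h,
                counts = unname(as.matrix(td[, c("l", "w", "count")])))
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("#n=%d", M$n), sprintf("#h=%d", M$h)), con)
    writeLines(sprintf("%d\t%d\t%d", td$l, td$w, td$count), con)
  }
  invisible(path)
}

#' Read and write CWF tables
#'
#' TSV dump mirroring the tabular presentation of a CWF: `#n=` and `#h=`
#' headers, then one row per label m with the values f(0, m) .. f(n, m).
#'
#' @param f a `cwf`.
#' @param path file path.
#' @export
write_cwf <- function(f, path) {
  stopifnot(inherits(f, "cwf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#n=%d", f$n), sprintf("#h=%d", f$h)), con)
  for (m in seq_len(2L * f$h)) {
    writeLines(paste(c(m, f$values[, m]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_cwf
#' @export
read_cwf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(sub("^#n=", "", grep("^#n=", lines, value = TRUE)[1L]))
  h <- as.integer(sub("^#h=", "", grep("^#h=", lines, value = TRUE)[1L]))
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  v <- matrix(0L, n + 1L, 2L * h)
  for (row in strsplit(body, "\t", fixed = TRUE)) {
    vals <- as.integer(row)
    v[, vals[1L]] <- vals[-1L]
  }
  wb <- unique(v[n + 1L, ])
  f <- new_cwf(v, n, h, if (length(wb) == 1L) wb else NA_integer_)
  validate_cwf(f)
  f
}

#' Write equivalence classes as JSON Lines
#'
#' One line per class: the sorted JSON array of canonical member strings.
#'
#' @param classes a `psr_classes` object (or list of character vectors).
#' @param path file path.
#' @export
write_classes <- function(classes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cls in classes) {
    writeLines(as.character(jsonlite::toJSON(cls)), con)
  }
  invisible(path)
}

#' @rdname write_classes
#' @export
read_classes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(x) as.character(jsonlite::fromJSON(x)))
}
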