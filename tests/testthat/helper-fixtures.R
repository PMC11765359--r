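# Worked examples used throughout the suite: a three-string multiset whose
# compositions admit three compatible classes, and a four-string multiset
# that is uniquely reconstructible up to reversal.
U3 <- c("110101", "110101", "101110")
V4 <- c("1000111", "1110001", "1100011", "1010011")

# Induced CWF of U3, one row per label (prefix/suffix alternating).
# The published table misprints the cell (l = 5, m = 5); the value below is
# the one computed from the string 101110 and consistent with the rotational
# pairing constraint.
table_u3 <- rbind(
  c(0, 1, 2, 2, 3, 3, 4),
  c(0, 1, 1, 2, 2, 3, 4),
  c(0, 1, 2, 2, 3, 3, 4),
  c(0, 1, 1, 2, 2, 3, 4),
  c(0, 1, 1, 2, 3, 4, 4),
  c(0, 0, 1, 2, 3, 3, 4))

# Induced CWF of V4.
table_v4 <- rbind(
  c(0, 1, 1, 1, 1, 2, 3, 4),
  c(0, 1, 2, 3, 3, 3, 3, 4),
  c(0, 1, 2, 3, 3, 3, 3, 4),
  c(0, 1, 1, 1, 1, 2, 3, 4),
  c(0, 1, 2, 2, 2, 2, 3, 4),
  c(0, 1, 2, 2, 2, 2, 3, 4),
  c(0, 1, 1, 2, 2, 2, 3, 4),
  c(0, 1, 2, 2, 2, 3, 3, 4))

storage.mode(table_u3) <- "integer"
storage.mode(table_v4) <- "integer"

# The three multisets compatible with the compositions of U3.
H1 <- c("011101", "110011", "101101")
H2 <- c("011011", "110101", "101101")
H3 <- c("011101", "110101", "110101")

# Expected composition multiplicities of U3 as (zeros, ones, count).
u3_multiplicities <- data.frame(
  zeros = c(0, 1, 0, 1, 1, 1, 2, 1, 2, 2),
  ones  = c(1, 0, 2, 1, 2, 3, 2, 4, 3, 4),
  count = c(5, 1, 2, 4, 6, 4, 2, 1, 5, 6))

class_keys <- function(classes) {
  sort(vapply(classes, function(cls) paste(cls, collapse = ","), character(1L)))
}

expect_same_classes <- function(a, b) {
  expect_identical(class_keys(a), class_keys(b))
}

cwf_matrix <- function(f) unname(t(f$values))
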