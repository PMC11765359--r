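test_that("reversal maps positions i -> n + 1 - i and is an involution", {
  expect_identical(reverse_string("011101"), "101110")
  expect_identical(reverse_string("101"), "101")
  expect_identical(reverse_string(reverse_string("110101")), "110101")
  set.seed(101)
  for (i in 1:25) {
    n <- sample(1:12, 1)
    t <- random_instance(n, 1, sample(0:n, 1))
    expect_identical(string_weight(reverse_string(t)), string_weight(t))
    expect_identical(reverse_string(reverse_string(t)), t)
  }
})

test_that("prefix and suffix compositions follow the running affix weights", {
  p <- prefix_compositions("110101")
  expect_equal(p$zeros, c(0, 0, 1, 1, 2, 2))
  expect_equal(p$ones, c(1, 2, 2, 3, 3, 4))
  s <- suffix_compositions("110101")
  expect_equal(s$zeros, c(0, 1, 1, 2, 2, 2))
  expect_equal(s$ones, c(1, 1, 2, 2, 3, 4))

  expect_equal(prefix_compositions("1")$ones, 1)
  expect_equal(prefix_compositions("0000")$zeros, c(1, 2, 3, 4))
  expect_equal(prefix_compositions("0000")$ones, rep(0, 4))

  pal <- "0110"
  expect_identical(prefix_compositions(pal), suffix_compositions(pal))

  # length-5 affixes of 101110 differ across ends
  expect_equal(prefix_compositions("101110")$ones[5], 4)
  expect_equal(suffix_compositions("101110")$ones[5], 3)

  expect_error(prefix_compositions(""), "non-binary")
  expect_error(suffix_compositions("11a1"), "non-binary")
})

test_that("the composition multiset collects all 2nh affix compositions", {
  M <- composition_multiset(U3)
  for (i in seq_len(nrow(u3_multiplicities))) {
    expect_identical(
      composition_count(M, u3_multiplicities$zeros[i], u3_multiplicities$ones[i]),
      as.integer(u3_multiplicities$count[i]))
  }
  expect_equal(sum(tidy(M)$count), 2L * 6L * 3L)
  expect_identical(M$w_bar, 4L)

  M1 <- composition_multiset("1")
  expect_identical(M1$a[1, 1], 2L)
  expect_identical(composition_count(M1, 0, 1), 2L)

  expect_error(composition_multiset(c("10", "110")), "same length")
  expect_error(composition_multiset(c("10", "11")), "same weight")
})

test_that("row sums and central symmetry hold on random constant-weight multisets", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(2:10, 1); w <- sample(0:n, 1); h <- sample(1:4, 1)
    u <- random_instance(n, h, w)
    M <- composition_multiset(u)
    expect_equal(unname(rowSums(M$a)), rep(2 * h, n + 1))
    for (l in 0:n) for (v in 0:w) {
      expect_identical(M$a[l + 1, v + 1], M$a[n - l + 1, w - v + 1])
    }
    expect_true(is_valid_composition_multiset(M))
  }
})

test_that("validation reports the violated invariant with witnesses", {
  M <- composition_multiset(U3)
  rep0 <- validate_composition_multiset(M)
  expect_true(attr(rep0, "ok"))
  expect_identical(composition_count(M, 0, 1), composition_count(M, 2, 3))

  bad <- M
  bad$a[4, 3] <- bad$a[4, 3] + 1L  # one extra count breaks the row sum
  rep1 <- validate_composition_multiset(bad)
  expect_false(attr(rep1, "ok"))
  expect_true(any(!rep1$ok & grepl("2h compositions", rep1$check)))

  bad2 <- M
  bad2$a[2, 4] <- 1L  # weight 3 on a length-1 affix is impossible
  rep2 <- validate_composition_multiset(bad2)
  expect_false(attr(rep2, "ok"))
  expect_true(any(!rep2$ok & grepl("weight exceeding length", rep2$check)))
  expect_error(scan_compositions(bad2), "invalid composition multiset")
})

test_that("canonical classes are invariant under member reversal", {
  expect_identical(canonical_class(U3), canonical_class(H3))
  pal <- c("0110", "1001")
  expect_identical(canonical_class(pal), sort(pal))
  expect_identical(canonical_class(c("01", "10")), canonical_class(c("10", "10")))
  set.seed(303)
  for (i in 1:20) {
    u <- random_instance(7, 3, 3)
    j <- sample(3, 1)
    u2 <- u; u2[j] <- reverse_string(u2[j])
    expect_identical(canonical_class(u), canonical_class(u2))
  }
})
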