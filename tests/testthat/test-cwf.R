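test_that("induced CWFs reproduce the published running-weight tables", {
  f <- induce_cwf(U3)
  expect_identical(cwf_matrix(f), table_u3)
  expect_identical(cwf_value(f, 4, 5), 3L)
  expect_identical(cwf_value(f, 1, 6), 0L)
  # the cell whose printed value contradicts the pairing constraint
  expect_identical(cwf_value(f, 5, 5), 4L)
  expect_identical(cwf_value(f, 5, 5) + cwf_value(f, 1, 6), f$w_bar)

  g <- induce_cwf(V4)
  expect_identical(cwf_matrix(g), table_v4)
  expect_identical(cwf_value(g, 3, 2), 3L)

  flat <- induce_cwf("0000")
  expect_true(all(flat$values == 0L))

  expect_error(induce_cwf(c("10", "11")), "same weight")
})

test_that("strings_of_cwf inverts induce_cwf", {
  f <- induce_cwf(U3)
  expect_identical(strings_of_cwf(f)[1], "110101")
  expect_identical(strings_of_cwf(f), U3)
  set.seed(505)
  for (i in 1:20) {
    n <- sample(2:10, 1); w <- sample(0:n, 1); h <- sample(1:3, 1)
    u <- random_instance(n, h, w)
    expect_identical(strings_of_cwf(induce_cwf(u)), u)
  }
})

test_that("star pairs each label with its partner", {
  expect_identical(star(1), 2L)
  expect_identical(star(6), 5L)
  expect_identical(star(star(1:8)), 1:8)
  expect_error(star(0), "out of range")
  expect_error(star(7, h = 3), "out of range")
})

test_that("maximal intervals are the runs of the discrepancy", {
  f <- induce_cwf(U3)
  iv <- maximal_intervals(f, 1, 6)
  expect_equal(unname(as.matrix(iv)), matrix(c(1L, 2L), 1))
  iv2 <- maximal_intervals(f, 2, 6)
  expect_equal(iv2$k1, c(1L, 4L))
  expect_equal(iv2$k2, c(1L, 4L))
  expect_identical(nrow(maximal_intervals(f, 3, 1)), 0L)  # identical strings
  expect_identical(nrow(maximal_intervals(f, 2, 2)), 0L)
})

test_that("partner-pair intervals are mirror symmetric", {
  # intervals between f_m and f_{m*} map onto themselves under
  # [k1, k2] -> [n - k2, n - k1]
  set.seed(606)
  for (i in 1:20) {
    n <- sample(2:10, 1); w <- sample(1:(n - 1), 1); h <- sample(1:3, 1)
    f <- induce_cwf(random_instance(n, h, w))
    for (m in seq_len(2 * h)) {
      iv <- maximal_intervals(f, m, star(m))
      mirrored <- data.frame(k1 = n - rev(iv$k2), k2 = n - rev(iv$k1))
      expect_equal(iv$k1, mirrored$k1)
      expect_equal(iv$k2, mirrored$k2)
    }
  }
})

test_that("intervals between two labels mirror onto their partners", {
  f <- induce_cwf(U3)
  n <- f$n
  # observed on the worked example ...
  expect_true(nrow(maximal_intervals(f, 1, 6)) > 0)
  expect_equal(as.list(maximal_intervals(f, 2, 5)[1, ]), list(k1 = 4L, k2 = 5L))
  # ... and as a property on random instances: an interval strictly inside
  # [1, n-1] between m1, m2 has its mirror between the partner labels
  set.seed(707)
  for (i in 1:15) {
    nn <- sample(3:10, 1); w <- sample(1:(nn - 1), 1); h <- sample(1:3, 1)
    g <- induce_cwf(random_instance(nn, h, w))
    for (m1 in seq_len(2 * h - 1)) for (m2 in (m1 + 1):(2 * h)) {
      iv <- maximal_intervals(g, m1, m2)
      ivp <- maximal_intervals(g, star(m1), star(m2))
      inner <- iv[iv$k1 >= 1 & iv$k2 <= nn - 1, , drop = FALSE]
      for (r in seq_len(nrow(inner))) {
        expect_true(any(ivp$k1 == nn - inner$k2[r] & ivp$k2 == nn - inner$k1[r]))
      }
    }
  }
})

test_that("swapping on a maximal interval yields another solution", {
  f <- induce_cwf(U3)
  M <- composition_multiset(U3)

  g <- cwf_swap(f, c(1, 2), 1, 6)
  # the swapped component equals its old counterpart everywhere
  expect_identical(g$values[, 1], f$values[, 6])
  expect_same_classes(list(canonical_class(strings_of_cwf(g))),
                      list(canonical_class(H3)))
  expect_true(is_solution(g, M))

  g2 <- cwf_swap(f, c(1, 1), 2, 6)
  expect_identical(sort(strings_of_cwf(g2)),
                   sort(c("110110", "110101", "101101")))
  # third string is a palindrome: its two component functions coincide
  expect_identical(g2$values[, 5], g2$values[, 6])
  expect_true(is_solution(g2, M))

  # swapping twice with the same arguments restores the original
  iv <- maximal_intervals(g, 1, 6)
  back <- cwf_swap(g, c(iv$k1[1], iv$k2[1]), 1, 6)
  expect_identical(back$values, f$values)

  expect_error(cwf_swap(f, c(2, 3), 1, 6), "not a maximal interval")
})

test_that("swap preserves solutions on random maximal intervals", {
  set.seed(808)
  tried <- 0
  for (i in 1:30) {
    n <- sample(3:9, 1); w <- sample(1:(n - 1), 1); h <- sample(1:3, 1)
    u <- random_instance(n, h, w)
    f <- induce_cwf(u)
    M <- composition_multiset(u)
    labs <- sample(2 * h, 2)
    iv <- maximal_intervals(f, labs[1], labs[2])
    if (!nrow(iv)) next
    r <- sample(nrow(iv), 1)
    g <- cwf_swap(f, c(iv$k1[r], iv$k2[r]), labs[1], labs[2])
    expect_true(is_solution(g, M))
    tried <- tried + 1
  }
  expect_gt(tried, 5)
})

test_that("is_solution counts component visits against the grid", {
  M <- composition_multiset(U3)
  f <- induce_cwf(U3)
  expect_true(is_solution(f, M))
  # a step-valid perturbation of one interior cell breaks the counts
  v <- f$values
  v[2 + 1, 1] <- 1L  # f(2, 1): 2 -> 1 keeps unit steps but shifts a visit
  g <- psrecon:::new_cwf(v, f$n, f$h, f$w_bar)
  expect_true(all(diff(g$values[, 1]) %in% 0:1))
  expect_false(is_solution(g, M))
  expect_error(is_solution(induce_cwf("11"), M), "dimension mismatch")
})

test_that("median groups split the labels by doubled median weight", {
  g <- induce_cwf(V4)
  mg <- median_groups(g)
  expect_identical(mg$groups[["4"]], c(5L, 6L, 7L, 8L))
  f <- induce_cwf(U3)
  expect_identical(median_groups(f)$groups[["4"]], 1:6)
  one <- induce_cwf("11")
  expect_equal(median_groups(one)$doubled_median, c(2, 2))
  # the half-weight group always has even size and is closed under star
  set.seed(909)
  for (i in 1:20) {
    n <- sample(2:10, 1); w <- sample(0:n, 1); h <- sample(1:3, 1)
    mm <- median_groups(induce_cwf(random_instance(n, h, w)))
    half <- mm$groups[[as.character(w)]]
    if (!is.null(half)) {
      expect_identical(length(half) %% 2L, 0L)
      expect_setequal(star(half), half)
    }
  }
})

test_that("rotational pairing ties induced CWFs to the common weight", {
  set.seed(111)
  for (i in 1:15) {
    n <- sample(2:10, 1); w <- sample(0:n, 1); h <- sample(1:3, 1)
    u <- random_instance(n, h, w)
    f <- induce_cwf(u)
    expect_true(validate_cwf(f))
    for (j in seq_len(h)) for (l in 0:n) {
      expect_identical(cwf_value(f, l, 2 * j - 1) + cwf_value(f, n - l, 2 * j),
                       as.integer(w))
    }
  }
})
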