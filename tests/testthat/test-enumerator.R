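test_that("bounded compositions enumerate exactly the feasible vectors", {
  expect_identical(bounded_compositions(5, c(3, 2)), list(c(3L, 2L)))
  expect_identical(bounded_compositions(4, 6), list(4L))
  expect_identical(bounded_compositions(0, c(2, 3)), list(c(0L, 0L)))
  expect_identical(bounded_compositions(7, c(3, 2)), list())
  expect_identical(bounded_compositions(0, integer(0)), list(integer(0)))
  expect_identical(bounded_compositions(1, integer(0)), list())
  # lexicographic order and completeness against a grid filter
  got <- bounded_compositions(3, c(2, 2, 2))
  all_vecs <- expand.grid(x1 = 0:2, x2 = 0:2, x3 = 0:2)
  want <- all_vecs[rowSums(all_vecs) == 3, ]
  want <- want[order(want$x1, want$x2, want$x3), ]
  expect_identical(length(got), nrow(want))
  for (i in seq_along(got)) {
    expect_equal(got[[i]], unname(unlist(want[i, ])))
  }
})

test_that("the midpoint partition sizes follow the grid", {
  p <- initial_partition(composition_multiset(U3))
  expect_equal(as.data.frame(p), data.frame(doubled_median = 4L, size = 6L))

  pV <- initial_partition(composition_multiset(V4))
  sizes <- setNames(pV$size, pV$doubled_median)
  expect_equal(unname(sizes[c("2", "4", "6")]), c(2L, 4L, 2L))

  p1 <- initial_partition(composition_multiset("1111"))
  expect_equal(as.data.frame(p1), data.frame(doubled_median = 4L, size = 2L))
})

test_that("the scan stage finds the unique bookkeeping of the worked example", {
  M <- composition_multiset(U3)
  leaves <- scan_compositions(M)
  expect_identical(length(leaves), 1L)
  leaf <- leaves[[1]]
  halves <- tidy(half_profile_groups(leaf))
  expect_setequal(halves$half_string, c("011", "110", "101"))
  expect_identical(sort(halves$multiplicity), c(1L, 2L, 3L))
  # the split at the last interior cell admits exactly one solution
  sp <- leaf$splits[leaf$splits$l == 1 & leaf$splits$w == 1, ]
  expect_identical(nrow(sp), 1L)
  sizes <- sp$sizes[[1]]; x <- sp$x[[1]]
  expect_setequal(sizes, c(2L, 3L))
  expect_identical(x[sizes == 3L], 3L)
  expect_identical(x[sizes == 2L], 2L)
  expect_identical(length(bounded_compositions(5, sizes)), 1L)

  expect_identical(length(scan_compositions(composition_multiset("1111"))), 1L)
  expect_identical(length(scan_compositions(composition_multiset(V4))), 1L)
})

test_that("pairing solutions are the transportation/symmetric systems", {
  leaf <- scan_compositions(composition_multiset(U3))[[1]]
  hg <- half_profile_groups(leaf)
  ys <- pairing_solutions(hg)
  expect_identical(length(ys), 3L)
  sizes <- vapply(hg$R[[5]], `[[`, integer(1), "size")
  for (y in ys) {
    m <- y[["4"]]
    expect_identical(m, t(m))
    expect_true(all(diag(m) %% 2L == 0L))
    expect_equal(unname(rowSums(m)), sizes)
  }
  # self-pairing of a single repeated half
  leaf2 <- scan_compositions(composition_multiset(c("11", "11")))[[1]]
  ys2 <- pairing_solutions(half_profile_groups(leaf2))
  expect_identical(length(ys2), 1L)
  expect_identical(ys2[[1]][["2"]], matrix(4L, 1, 1))
})

test_that("assembly reproduces the three compatible multisets", {
  M <- composition_multiset(U3)
  leaf <- scan_compositions(M)[[1]]
  hg <- half_profile_groups(leaf)
  got <- lapply(pairing_solutions(hg), function(y) {
    strs <- assemble_pairing(leaf, y)
    expect_true(psrecon:::same_multiset(composition_multiset(strs), M))
    canonical_class(strs)
  })
  expect_same_classes(got, lapply(list(H1, H2, H3), canonical_class))
})

test_that("reconstruct_all returns exactly the compatible classes", {
  cls <- reconstruct_all(composition_multiset(U3))
  expect_same_classes(cls, lapply(list(H1, H2, H3), canonical_class))

  clsV <- reconstruct_all(composition_multiset(V4))
  expect_identical(length(clsV), 1L)
  expect_identical(clsV[[1]], canonical_class(V4))

  cls11 <- reconstruct_all(composition_multiset("11"))
  expect_identical(length(cls11), 1L)
  expect_identical(cls11[[1]], "11")
})

test_that("enumerator and brute force agree on random instances", {
  set.seed(1515)
  for (i in 1:40) {
    n <- sample(2:10, 1); w <- sample(0:n, 1); h <- sample(1:3, 1)
    u <- random_instance(n, h, w)
    M <- composition_multiset(u)
    cls <- reconstruct_all(M)
    expect_same_classes(cls, oracle_reconstruct_all(M))
    expect_true(psrecon:::class_key(canonical_class(u)) %in% class_keys(cls))
    expect_identical(length(cls) == 1L, is_unique(M)$unique)
    for (x in cls) {
      expect_true(psrecon:::same_multiset(composition_multiset(x), M))
      expect_identical(unique(string_weight(x)), as.integer(w))
    }
  }
})

test_that("state caps guard the exponential search", {
  M <- composition_multiset(random_instance(10, 3, 5, seed = 99))
  expect_error(scan_compositions(M, max_states = 1), "max_states")
})
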