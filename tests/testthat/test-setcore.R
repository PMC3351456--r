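test_that("canonicalization trims whitespace, drops blanks, collapses duplicates", {
  expect_equal(as.character(canonicalize_entries(c("GIT1", " GIT1", "", "PAK1"))),
               c("GIT1", "PAK1"))
  folded <- canonicalize_entries(c("git1", "GIT1"), case_sensitive = FALSE)
  expect_length(folded, 1L)
  expect_equal(as.character(folded), "git1") # first-seen spelling kept
  expect_equal(as.character(canonicalize_entries(c("  ", "", NA))), character(0))

  # a column of 100 generated labels with 10 planted duplicates -> 90 unique
  labels <- sprintf("L%03d", 1:90)
  set.seed(11)
  raw <- sample(c(labels, labels[1:10]))
  got <- canonicalize_entries(raw)
  expect_length(got, length(unique(raw)))
  expect_length(got, 90L)
  expect_equal(attr(got, "n_dropped"), 10L)
})

test_that("partition assigns every member to its matching region and keeps all keys", {
  # disjoint pair
  p2 <- disjoint_pair()
  expect_equal(region_members(p2, 1), "a")
  expect_equal(region_members(p2, 2), "b")
  expect_equal(region_members(p2, 3), character(0))
  expect_length(p2$regions, 3L)

  # three sets, hand-enumerated: {a,b}, {b,c}, {c}
  p3 <- compute_partition(set_collection(list(X = c("a", "b"),
                                              Y = c("b", "c"),
                                              Z = "c")))
  expect_equal(region_members(p3, 1), "a")   # X only
  expect_equal(region_members(p3, 3), "b")   # X and Y
  expect_equal(region_members(p3, 6), "c")   # Y and Z
  for (empty in c(2, 4, 5, 7)) {
    expect_equal(region_members(p3, empty), character(0))
  }

  # six identical sets: only the all-sets region is populated, 63 keys total
  p6 <- identical_six()
  expect_length(p6$regions, 63L)
  sizes <- region_sizes(p6)
  expect_equal(unname(sizes[63]), 8L)
  expect_equal(sum(sizes[-63]), 0L)
})

test_that("set counts outside 2..6 are hard errors", {
  expect_error(set_collection(list(A = "x")), class = "cogwheel_set_count")
  seven <- stats::setNames(rep(list("x"), 7), paste0("S", 1:7))
  expect_error(set_collection(seven), class = "cogwheel_set_count")
  expect_error(set_collection(list(A = "x", A = "y")), class = "cogwheel_format")
})

test_that("signature index is the mask-value bijection onto 1..2^n-1", {
  for (n in 2:6) {
    idx <- vapply(seq_len(2L^n - 1L), signature_index, integer(1), n = n)
    expect_equal(idx, seq_len(2L^n - 1L)) # bijection: identity on masks
  }
  expect_equal(signature_index(1L, 6), 1L)
  expect_equal(signature_index(63L, 6), 63L)
  expect_equal(signature_index(bitwOr(2L, 8L), 4), 10L) # sets {2,4}, 1010b
  expect_error(signature_index(0L, 4))
  expect_error(signature_index(16L, 4))
  expect_equal(signature_sets(10L, 4), c(2L, 4L))
})

test_that("classification follows the five-colour scheme and tiles the signature space", {
  expect_equal(classify_region(1L, 1L, 6L), "BLUE")   # reference only
  expect_equal(classify_region(4L, 1L, 6L), "RED")    # one dose (set 3) only
  expect_equal(classify_region(63L, 1L, 6L), "GREEN") # all sets
  expect_equal(classify_region(6L, 1L, 6L), "GREY")   # two doses, no reference
  expect_equal(classify_region(3L, 1L, 6L), "BLACK")  # reference + one dose

  # census for n = 6, reference 1: exhaustively enumerated
  census <- table(classify_region(1:63, 1L, 6L))
  expect_equal(as.integer(census[c("BLUE", "RED", "GREY", "BLACK", "GREEN")]),
               c(1L, 5L, 26L, 30L, 1L))

  # codes partition the signatures for every n and reference position
  for (n in 2:6) {
    for (ref in seq_len(n)) {
      codes <- classify_region(seq_len(2L^n - 1L), ref, n)
      expect_true(all(codes %in% category_codes()))
      expect_equal(sum(codes == "BLUE"), 1L)
      expect_equal(sum(codes == "RED"), n - 1L)
      expect_equal(sum(codes == "GREEN"), 1L)
    }
  }
  expect_error(classify_region(1L, 7L, 6L))
  expect_error(classify_region(1L, 0L, 6L))
})

test_that("dose-unique members are read off the singleton regions", {
  expect_true(all(lengths(dose_unique_members(identical_six())) == 0L))

  p3 <- compute_partition(set_collection(list(X = c("a", "b"),
                                              Y = c("b", "c"),
                                              Z = "c")))
  du <- dose_unique_members(p3, 1L)
  expect_equal(du, list(Y = character(0), Z = character(0)))

  # plan with exactly k singleton members per dose
  k <- 4L
  counts <- stats::setNames(rep(k, 5), 2^(1:5))
  fx <- generate_collection(partition_plan(6, counts, seed = 3))
  du6 <- dose_unique_members(compute_partition(fx$collection))
  expect_true(all(lengths(du6) == k))
})

test_that("random fixtures satisfy disjointness and conservation and match the brute-force oracle", {
  for (case in 1:60) {
    n <- 2L + case %% 5L
    fx <- generate_collection(random_plan(n, seed = 1000 + case))
    p <- compute_partition(fx$collection)
    members <- unlist(p$regions, use.names = FALSE)
    expect_equal(anyDuplicated(members), 0L)                # pairwise disjoint
    expect_length(members, length(unique(unlist(fx$collection$sets))))
    expect_length(p$regions, 2L^n - 1L)                     # key completeness
    expect_equal(p$regions, brute_partition(fx$collection)) # oracle equality
  }
})
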