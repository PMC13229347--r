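# Pair-table canonicalization, balancing, split-size arithmetic and the
# two-stage stratified split.

pt <- function(a, b, y) {
  PairTable(data.frame(protein_a = a, protein_b = b, label = y,
                       stringsAsFactors = FALSE))
}

test_that("canonicalization keeps one record per unordered pair", {
  out <- canonicalizeAndDedup(pt(c("A", "B"), c("B", "A"), c(1, 1)))
  expect_identical(pairRecords(out),
                   data.frame(protein_a = "A", protein_b = "B", label = 1L,
                              stringsAsFactors = FALSE))
  # idempotent on an already-canonical table
  canon <- pt(c("A", "A", "C"), c("B", "C", "C"), c(1, 0, 1))
  expect_identical(pairRecords(canonicalizeAndDedup(canon)),
                   pairRecords(canon))
  # self-pairs retained once
  selfp <- canonicalizeAndDedup(pt(c("A", "A"), c("A", "A"), c(1, 1)))
  expect_identical(nrow(pairRecords(selfp)), 1L)
})

test_that("conflicting duplicate labels are refused, naming the pair", {
  expect_error(canonicalizeAndDedup(pt(c("A", "B"), c("B", "A"), c(1, 0))),
               "A/B")
})

test_that("undersampling equalizes counts; oversampling retains originals", {
  tb <- pt(sprintf("P%02d", 1:14), sprintf("Q%02d", 1:14),
           c(rep(1, 10), rep(0, 4)))
  un <- balanceByUndersampling(tb, seed = 1)
  expect_identical(unname(classCounts(un)), c(4L, 4L))
  # already balanced input unchanged up to order
  bal <- balanceByUndersampling(un, seed = 2)
  expect_identical(sort(pairRecords(bal)$protein_a), sort(pairRecords(un)$protein_a))

  tb2 <- pt(sprintf("P%02d", 1:12), sprintf("Q%02d", 1:12),
            c(rep(1, 3), rep(0, 9)))
  ov <- balanceByOversampling(tb2, seed = 1)
  expect_identical(unname(classCounts(ov)), c(9L, 9L))
  # every original minority record still present
  pos <- pairRecords(ov)[pairRecords(ov)$label == 1L, ]
  expect_true(all(sprintf("P%02d", 1:3) %in% pos$protein_a))
  expect_identical(length(balanceByOversampling(un, seed = 1)), length(un))
  expect_error(balanceByUndersampling(pt("A", "B", 1), seed = 1), "nonempty")
})

test_that("balancing by undersampling yields 2 x min(n_pos, n_neg) records", {
  set.seed(8)
  n <- 500
  tb <- pt(sprintf("A%04d", 1:n), sprintf("B%04d", 1:n),
           rbinom(n, 1, 0.3))
  cc <- classCounts(tb)
  out <- balanceByUndersampling(tb, seed = 3)
  expect_identical(length(out), 2L * min(cc))
})

test_that("split sizes reproduce the documented arithmetic", {
  expect_identical(unlist(computeSplitSizes(100)[c("nTrain", "nVal", "nTest")]),
                   c(nTrain = 68L, nVal = 20L, nTest = 12L))
  # the 0.225-of-remainder variant rounds differently
  alt <- computeSplitSizes(249814, valFracRemainder = 0.225)
  expect_identical(alt$nVal, 49463L)
  expect_error(computeSplitSizes(10, testFrac = 0.5, valFracTotal = 0.5), "< 1")
  expect_error(computeSplitSizes(3, testFrac = 0.4, valFracTotal = 0.4),
               "training")
})

test_that("two-stage split partitions exactly and stratifies evenly", {
  set.seed(11)
  n <- 1000
  tb <- pt(sprintf("A%04d", 1:n), sprintf("B%04d", 1:n),
           rep(c(0, 1), each = n / 2))
  sizes <- computeSplitSizes(n)
  sp <- twoStageStratifiedSplit(tb, sizes, seed = 4)
  expect_identical(length(trainSet(sp)), sizes$nTrain)
  expect_identical(length(valSet(sp)), sizes$nVal)
  expect_identical(length(testSet(sp)), sizes$nTest)
  # balanced parent with even split sizes: each split exactly 50% positive
  for (part in list(trainSet(sp), valSet(sp), testSet(sp))) {
    cc <- classCounts(part)
    expect_identical(cc[["n_pos"]], cc[["n_neg"]])
  }
  # union of splits equals the input; keys pairwise disjoint
  allKeys <- c(pairRecords(trainSet(sp))$protein_a,
               pairRecords(valSet(sp))$protein_a,
               pairRecords(testSet(sp))$protein_a)
  expect_setequal(allKeys, pairRecords(tb)$protein_a)
  expect_identical(anyDuplicated(allKeys), 0L)
  expect_identical(auditLeakage(sp), 0L)
})

test_that("per-split positive fraction stays within 1 record of the parent", {
  set.seed(12)
  n <- 777
  tb <- pt(sprintf("A%04d", 1:n), sprintf("B%04d", 1:n), rbinom(n, 1, 0.37))
  parentFrac <- mean(pairRecords(tb)$label)
  sp <- twoStageStratifiedSplit(tb, computeSplitSizes(n), seed = 2)
  for (part in list(trainSet(sp), valSet(sp), testSet(sp))) {
    frac <- mean(pairRecords(part)$label)
    expect_lt(abs(frac - parentFrac), 1 / length(part))
  }
})

test_that("shuffling input rows changes membership but not sizes or balance", {
  set.seed(13)
  n <- 400
  tb <- pt(sprintf("A%04d", 1:n), sprintf("B%04d", 1:n), rbinom(n, 1, 0.5))
  sp1 <- twoStageStratifiedSplit(tb, computeSplitSizes(n), seed = 6)
  shuf <- PairTable(pairRecords(tb)[sample.int(n), ])
  sp2 <- twoStageStratifiedSplit(shuf, computeSplitSizes(n), seed = 6)
  expect_identical(length(trainSet(sp1)), length(trainSet(sp2)))
  expect_identical(classCounts(valSet(sp1)), classCounts(valSet(sp2)))
  expect_identical(classCounts(testSet(sp1)), classCounts(testSet(sp2)))
})

test_that("leakage audit flags oversample-before-split and clears after-split", {
  set.seed(14)
  n <- 300
  tb <- pt(sprintf("A%04d", 1:n), sprintf("B%04d", 1:n),
           c(rep(1, 40), rep(0, 260)))
  before <- balanceAndSplit(tb, balance = "oversample", seed = 3)
  expect_gt(before@provenance$leakage, 0L)
  after <- balanceAndSplit(tb, balance = "oversample",
                           balanceAfterSplit = TRUE, seed = 3)
  expect_identical(after@provenance$leakage, 0L)
})
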