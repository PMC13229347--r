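## Pair-dataset construction: canonicalization, class balancing, and the
## two-stage stratified train/validation/test split.

canonicalKeys <- function(df) {
  lo <- pmin(df$protein_a, df$protein_b)
  hi <- pmax(df$protein_a, df$protein_b)
  paste(lo, hi, sep = "\r")
}

#' Canonicalize and deduplicate a pair table
#'
#' Order-normalizes every record so protein_a <= protein_b
#' (lexicographically) and keeps the first occurrence of each unordered
#' pair, so that a pair recorded both as (A, B) and (B, A) appears once.
#' Self-pairs (A, A) are retained (once). If the same unordered pair occurs
#' with conflicting labels the function refuses rather than guessing.
#'
#' @param pairs a [PairTable-class].
#' @return A canonical, duplicate-free [PairTable-class].
#' @examples
#' pt <- PairTable(data.frame(protein_a = c("A", "B"), protein_b = c("B", "A"),
#'                            label = c(1, 1)))
#' pairRecords(canonicalizeAndDedup(pt))
#' @export
canonicalizeAndDedup <- function(pairs) {
  df <- pairRecords(pairs)
  swap <- df$protein_a > df$protein_b
  tmp <- df$protein_a[swap]
  df$protein_a[swap] <- df$protein_b[swap]
  df$protein_b[swap] <- tmp
  key <- paste(df$protein_a, df$protein_b, sep = "\r")
  lab <- split(df$label, key)
  bad <- names(lab)[vapply(lab, function(v) length(unique(v)) > 1L, logical(1))]
  if (length(bad)) {
    stopf("conflicting labels for unordered pair(s): %s",
          paste(gsub("\r", "/", utils::head(bad, 10L)), collapse = ", "))
  }
  PairTable(df[!duplicated(key), , drop = FALSE])
}

#' Balance classes by undersampling the majority class
#'
#' Subsamples the majority class without replacement down to the minority
#' count, yielding equal positive and negative counts.
#'
#' @param pairs a [PairTable-class] with both classes present.
#' @param seed RNG seed.
#' @return A balanced [PairTable-class].
#' @export
balanceByUndersampling <- function(pairs, seed = 1L) {
  df <- pairRecords(pairs)
  iPos <- which(df$label == 1L)
  iNeg <- which(df$label == 0L)
  if (!length(iPos) || !length(iNeg)) {
    stopf("both classes must be nonempty (found %d positive, %d negative)",
          length(iPos), length(iNeg))
  }
  set.seed(seed)
  k <- min(length(iPos), length(iNeg))
  keep <- sort(c(
    if (length(iPos) > k) sample(iPos, k) else iPos,
    if (length(iNeg) > k) sample(iNeg, k) else iNeg
  ))
  PairTable(df[keep, , drop = FALSE])
}

#' Balance classes by oversampling the minority class
#'
#' Resamples the minority class with replacement until its count matches
#' the majority class. All original records are retained; duplicates are
#' added on top. Note that oversampling *before* splitting lets duplicated
#' records fall on both sides of a split boundary; see [auditLeakage()].
#'
#' @inheritParams balanceByUndersampling
#' @return A balanced [PairTable-class].
#' @export
balanceByOversampling <- function(pairs, seed = 1L) {
  df <- pairRecords(pairs)
  iPos <- which(df$label == 1L)
  iNeg <- which(df$label == 0L)
  if (!length(iPos) || !length(iNeg)) {
    stopf("both classes must be nonempty (found %d positive, %d negative)",
          length(iPos), length(iNeg))
  }
  set.seed(seed)
  minority <- if (length(iPos) < length(iNeg)) iPos else iNeg
  deficit <- abs(length(iPos) - length(iNeg))
  extra <- if (deficit > 0) sample(minority, deficit, replace = TRUE) else integer(0)
  PairTable(df[c(seq_len(nrow(df)), extra), , drop = FALSE])
}

#' Split-size arithmetic for the two-stage partition
#'
#' Computes the train/validation/test sizes used by the two-stage split:
#' the test partition takes `ceiling(testFrac * n)` records, the validation
#' partition the half-up-rounded `valFracTotal * n` (a fraction of the
#' *total*, not of the stage-2 remainder), and training the rest. With the
#' defaults (12% test, 20% validation) this reproduces the published
#' partition counts for both the balanced (249,814) and oversampled
#' (1,082,662) pair datasets. Setting `valFracRemainder` instead expresses
#' validation as a fraction of the stage-1 remainder (e.g. 0.225 of the
#' remaining 88%), a variant that rounds differently.
#'
#' @param nTotal total number of records.
#' @param testFrac fraction for the isolated test set (default 0.12).
#' @param valFracTotal validation fraction of the total (default 0.20).
#' @param valFracRemainder optional; if given, overrides `valFracTotal` and
#'   sizes validation as `round(valFracRemainder * (n - nTest))`.
#' @return list with `nTrain`, `nVal`, `nTest`, and the fractions used.
#' @examples
#' computeSplitSizes(100)  # 68 / 20 / 12
#' @export
computeSplitSizes <- function(nTotal, testFrac = 0.12, valFracTotal = 0.20,
                              valFracRemainder = NULL) {
  nTotal <- assertCount(nTotal, "nTotal", min = 1L)
  assertFraction(testFrac, "testFrac")
  assertFraction(valFracTotal, "valFracTotal")
  if (testFrac + valFracTotal >= 1) stopf("testFrac + valFracTotal must be < 1")
  ## guard the ceiling against floating-point dust on exact products
  nTest <- as.integer(ceiling(testFrac * nTotal - 1e-9))
  nVal <- if (is.null(valFracRemainder)) {
    as.integer(roundHalfUp(valFracTotal * nTotal))
  } else {
    as.integer(roundHalfUp(valFracRemainder * (nTotal - nTest)))
  }
  nTrain <- nTotal - nTest - nVal
  if (nTrain <= 0L) stopf("no records left for training (nTrain = %d)", nTrain)
  list(nTrain = nTrain, nVal = nVal, nTest = nTest,
       testFrac = testFrac, valFracTotal = valFracTotal)
}

## Stratified per-class allocation of `size` records among class counts,
## largest-fractional-part remainder assignment (deterministic and
## order-independent; ties broken toward the larger class, then label order).
stratumQuota <- function(counts, size) {
  exact <- size * counts / sum(counts)
  base <- floor(exact)
  rem <- size - sum(base)
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, -counts, names(counts))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

drawStratified <- function(labels, size) {
  counts <- table(factor(labels, levels = sort(unique(labels))))
  quota <- stratumQuota(stats::setNames(as.integer(counts), names(counts)), size)
  idx <- integer(0)
  for (cl in names(quota)) {
    pool <- which(labels == as.integer(cl))
    if (quota[[cl]] > length(pool)) {
      stopf("class %s has too few records (%d) for the requested allocation (%d)",
            cl, length(pool), quota[[cl]])
    }
    take <- if (quota[[cl]] == length(pool)) pool else sample(pool, quota[[cl]])
    idx <- c(idx, take)
  }
  sort(idx)
}

#' Two-stage stratified train/validation/test split
#'
#' Stage 1 removes a stratified test partition; stage 2 separates a
#' stratified validation partition from the remainder. Each stage
#' stratifies on the binary label with per-class quotas allocated
#' proportionally (largest-fractional-part remainders), so every split's
#' positive fraction is within one record of the parent table's.
#' Deterministic given `seed`.
#'
#' @param pairs a [PairTable-class].
#' @param sizes output of [computeSplitSizes()] for `length(pairs)`.
#' @param seed RNG seed.
#' @return A [DatasetSplits-class].
#' @export
twoStageStratifiedSplit <- function(pairs, sizes, seed = 1L) {
  df <- pairRecords(pairs)
  n <- nrow(df)
  if (sizes$nTrain + sizes$nVal + sizes$nTest != n) {
    stopf("sizes (%d + %d + %d) do not sum to the table size (%d)",
          sizes$nTrain, sizes$nVal, sizes$nTest, n)
  }
  set.seed(seed)
  iTest <- drawStratified(df$label, sizes$nTest)
  rest <- setdiff(seq_len(n), iTest)
  iVal <- rest[drawStratified(df$label[rest], sizes$nVal)]
  iTrain <- setdiff(rest, iVal)
  splits <- new("DatasetSplits",
                train = PairTable(df[iTrain, , drop = FALSE]),
                val = PairTable(df[iVal, , drop = FALSE]),
                test = PairTable(df[iTest, , drop = FALSE]),
                provenance = list(seed = seed, sizes = sizes,
                                  nTotal = n))
  splits
}

#' Audit duplicated records crossing split boundaries
#'
#' Counts canonical unordered pair keys that occur in more than one of the
#' train/validation/test partitions. For a deduplicated input this is zero
#' by construction; when a table is oversampled *before* splitting,
#' duplicated minority records can land in different partitions and leak
#' training information into evaluation — this audit makes that visible.
#'
#' @param splits a [DatasetSplits-class].
#' @return integer: number of distinct canonical keys present in 2+ splits.
#' @export
auditLeakage <- function(splits) {
  ks <- lapply(list(trainSet(splits), valSet(splits), testSet(splits)),
               function(pt) unique(canonicalKeys(pairRecords(pt))))
  tab <- table(unlist(ks))
  sum(tab > 1L)
}

#' Balance and split a pair table in one call
#'
#' Replicates the published workflow by default: balance classes first
#' (undersampling or oversampling), then split. Because
#' balancing-by-oversampling before splitting can leak duplicated records
#' across partitions, `balanceAfterSplit = TRUE` instead splits the
#' deduplicated table first and oversamples only the training partition.
#' The leakage audit is always computed and stored in the provenance.
#'
#' @param pairs a [PairTable-class] (canonical; see
#'   [canonicalizeAndDedup()]).
#' @param balance `"undersample"`, `"oversample"` or `"none"`.
#' @param balanceAfterSplit if TRUE, split first and balance the training
#'   partition only.
#' @param testFrac,valFracTotal passed to [computeSplitSizes()].
#' @param seed RNG seed.
#' @return A [DatasetSplits-class]; `provenance$leakage` holds the audit.
#' @export
balanceAndSplit <- function(pairs, balance = c("undersample", "oversample", "none"),
                            balanceAfterSplit = FALSE,
                            testFrac = 0.12, valFracTotal = 0.20, seed = 1L) {
  balance <- match.arg(balance)
  doBalance <- function(pt) switch(balance,
    undersample = balanceByUndersampling(pt, seed = seed),
    oversample = balanceByOversampling(pt, seed = seed),
    none = pt)
  if (balanceAfterSplit) {
    sizes <- computeSplitSizes(length(pairs), testFrac, valFracTotal)
    splits <- twoStageStratifiedSplit(pairs, sizes, seed = seed)
    splits@train <- doBalance(splits@train)
  } else {
    balanced <- doBalance(pairs)
    sizes <- computeSplitSizes(length(balanced), testFrac, valFracTotal)
    splits <- twoStageStratifiedSplit(balanced, sizes, seed = seed)
  }
  splits@provenance$balance <- balance
  splits@provenance$balanceAfterSplit <- balanceAfterSplit
  splits@provenance$leakage <- auditLeakage(splits)
  splits
}
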