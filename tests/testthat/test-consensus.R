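test_that("merge criterion implements reciprocal overlap of the shortest segment", {
  a <- make_peaks(1000, 1500)          # 500 bp
  b <- make_peaks(1100, 1700)          # overlap 400 = 0.8 * 500
  expect_true(merge_criterion(a, b))
  expect_true(merge_criterion(b, a))   # symmetric
  expect_true(merge_criterion(a, a))   # identity
  c <- make_peaks(1400, 1900)          # overlap 100 = 0.2 * 500
  expect_false(merge_criterion(a, c))
  other <- make_peaks(1000, 1500, chrom = "chr9")
  expect_false(merge_criterion(a, other))   # different chromosome, no error
  expect_error(merge_criterion(a, b, min_frac = 0), "min_frac")
  expect_error(merge_criterion(a, b, min_frac = 1.5), "min_frac")
})

test_that("replicate peaks merge into union segments with replicate support", {
  pk <- c(make_peaks(1000, 1500, "R1"), make_peaks(1100, 1700, "R2"))
  cons <- merge_replicates(pk)
  expect_length(cons, 1L)
  expect_equal(start(cons), 1001L)     # union: min start
  expect_equal(end(cons), 1700L)       # union: max end
  expect_equal(cons$support, 2L)

  ## weak overlap -> two components, both below min_support
  pk2 <- c(make_peaks(1000, 1500, "R1"), make_peaks(1400, 1900, "R2"))
  expect_message(cons2 <- merge_replicates(pk2), "dropped 2")
  expect_length(cons2, 0L)

  ## identical peaks from four replicates
  pk4 <- do.call(c, lapply(paste0("R", 1:4), function(r)
    make_peaks(0, 100, r)))
  cons4 <- merge_replicates(pk4)
  expect_length(cons4, 1L)
  expect_equal(c(start(cons4), end(cons4)), c(1L, 100L))
  expect_equal(cons4$support, 4L)
})

test_that("identical duplicate peaks within a replicate are deduplicated", {
  pk <- c(make_peaks(1000, 1500, "R1"), make_peaks(1000, 1500, "R1"),
          make_peaks(1100, 1700, "R2"))
  expect_warning(cons <- merge_replicates(pk), "deduplicated 1")
  expect_equal(cons$support, 2L)
  expect_equal(cons$n_members, 2L)
})

test_that("two same-replicate peaks can share a component but count support once", {
  pk <- c(make_peaks(1000, 1500, "R1"), make_peaks(1050, 1550, "R1"),
          make_peaks(1040, 1540, "R2"))
  cons <- merge_replicates(pk)
  expect_length(cons, 1L)
  expect_equal(cons$n_members, 3L)
  expect_equal(cons$support, 2L)       # distinct replicates, not peaks
})

test_that("consensus output is invariant to input order and min_frac is monotone", {
  set.seed(7)
  for (rep in 1:20) {
    pk <- random_peak_set(30)
    cons <- merge_replicates(pk, min_support = 1)
    perm <- merge_replicates(pk[sample(length(pk))], min_support = 1)
    expect_identical(as.data.frame(cons), as.data.frame(perm))
    ## lowering min_frac never splits components: every strict-threshold
    ## component is contained in one loose-threshold component
    loose <- merge_replicates(pk, min_frac = 0.4, min_support = 1)
    strict_members <- strsplit(cons$member_ids, ",", fixed = TRUE)
    loose_members <- strsplit(loose$member_ids, ",", fixed = TRUE)
    for (sm in strict_members) {
      host <- vapply(loose_members, function(lm) all(sm %in% lm), logical(1))
      expect_equal(sum(host), 1L)
    }
  }
})

test_that("every consensus segment is at least as long as its longest member", {
  set.seed(11)
  for (rep in 1:50) {
    pk <- random_peak_set(25)
    cons <- merge_replicates(pk, min_support = 1)
    members <- strsplit(cons$member_ids, ",", fixed = TRUE)
    for (i in seq_along(cons)) {
      widths <- width(pk)[match(members[[i]], pk$peak_id)]
      expect_gte(width(cons)[i], max(widths))
    }
  }
})

test_that("components equal an O(n^2) brute-force evaluation", {
  set.seed(23)
  for (rep in 1:25) {
    pk <- random_peak_set(40)
    cons <- merge_replicates(pk, min_support = 1)
    comp <- oracle_components(pk)
    oracle_sets <- lapply(split(pk$peak_id, comp), sort)
    impl_sets <- lapply(strsplit(cons$member_ids, ",", fixed = TRUE), sort)
    expect_setequal(vapply(oracle_sets, paste, "", collapse = "|"),
                    vapply(impl_sets, paste, "", collapse = "|"))
  }
})

test_that("support summary counts each consensus peak once", {
  pk <- c(make_peaks(1000, 1500, "R1"), make_peaks(1010, 1510, "R2"),
          make_peaks(5000, 5400, "R1"), make_peaks(5010, 5410, "R2"),
          make_peaks(9000, 9300, "R1"), make_peaks(9005, 9305, "R2"),
          make_peaks(9010, 9310, "R3"), make_peaks(9015, 9315, "R4"))
  cons <- merge_replicates(pk)
  tab <- consensus_summary(cons)
  expect_equal(tab$n_peaks[tab$support == 2], 2L)
  expect_equal(tab$n_peaks[tab$support == 4], 1L)
  expect_equal(sum(tab$n_peaks), length(cons))
  expect_equal(nrow(consensus_summary(merge_replicates(pk[0]))), 0L)
})
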