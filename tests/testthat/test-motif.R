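test_that("degenerate scanning matches each IUPAC alternative", {
  s1 <- scan_motif("AAGTACTACAA", "GTACTRC")
  expect_length(s1, 1L)
  expect_equal(start(s1), 3L)           # 0-based offset 2
  expect_equal(s1$matched_text, "GTACTAC")
  expect_equal(as.character(strand(s1)), "+")
  s2 <- scan_motif("AAGTACTGCAA", "GTACTRC")
  expect_equal(s2$matched_text, "GTACTGC")
  ## reverse complement of a match-bearing sequence: same count, minus strand
  rc <- revcomp_str("AAGTACTACAA")
  s3 <- scan_motif(rc, "GTACTRC")
  expect_length(s3, 1L)
  expect_equal(as.character(strand(s3)), "-")
  expect_equal(s3$matched_text, "GTACTAC")
  expect_error(iupac_motif("GTACXRC"), "invalid IUPAC")
  expect_error(iupac_motif(paste(rep("A", 21), collapse = "")), "1..20")
})

test_that("sequence N never satisfies a non-N motif position", {
  expect_length(scan_motif("AAGTACTNCAA", "GTACTRC"), 0L)
  expect_length(scan_motif("AANNNNNNNAA", "GTACTRC"), 0L)
})

test_that("overlapping matches are all reported", {
  ## GTACGTAC contains GTAC at 1 and 5 on + and two minus-strand GTAC
  s <- scan_motif("GTACGTAC", "GTAC")
  expect_equal(sum(strand(s) == "+"), 2L)
  ## genomic offset shifts reported coordinates
  so <- scan_motif("AAGTACTACAA", "GTACTRC", chrom = "chr5", offset = 1000)
  expect_equal(start(so), 1003L)
  expect_equal(as.character(seqnames(so)), "chr5")
})

test_that("scanner agrees with the naive regex oracle on random sequences", {
  set.seed(101)
  for (rep in 1:60) {
    seq <- random_dna(400)
    for (motif in c("GTACTRC", "TCTTCTST", "GTAC")) {
      got <- scan_motif(seq, motif)
      want <- oracle_scan(seq, motif)
      expect_equal(start(got)[as.character(strand(got)) == "+"],
                   want$fwd)
      expect_equal(start(got)[as.character(strand(got)) == "-"],
                   want$rev)
    }
  }
})

test_that("per-peak copy counts use site midpoints and include the zero class", {
  ## two planted non-overlapping motifs inside the peak
  set.seed(77)
  left <- random_dna(100)
  genome <- Biostrings::DNAStringSet(
    paste0(left, "GTACTAC", random_dna(50), "GTACTGC", random_dna(100)))
  names(genome) <- "chr1"
  pk <- make_peaks(90, 220); pk$peak_id <- "pk1"
  res <- sites_per_peak(pk, genome, "GTACTRC")
  expect_equal(unname(res$counts), 2L)
  expect_equal(res$sites$peak_id, c("pk1", "pk1"))
  ## motif-free composition: pattern needs A, sequence is G/C only
  gc <- Biostrings::DNAStringSet(paste(rep("GC", 200), collapse = ""))
  names(gc) <- "chr1"
  res0 <- sites_per_peak(pk, gc, "GTACTRC")
  expect_equal(unname(res0$counts), 0L)
  expect_equal(res0$histogram$n_peaks[res0$histogram$copies == 0], 1L)
  expect_error(sites_per_peak(make_peaks(1000, 2000), gc, "GTACTRC"),
               "chromosome bounds")
})

test_that("a promoter with 8 GTAC cores of which 2 extend to GTACTRC", {
  ## synthetic fixture mirroring a tandem-core promoter architecture
  spacer <- "TTAAGGCCTTAAGG"
  flank <- strrep("CCTTAAGG", 5)               # GTAC-free by construction
  cores <- c("GTACAA", "GTACTT", "GTACTAC", "GTACGG", "GTACCA", "GTACTGC",
             "GTACAT", "GTACTA")
  seqstr <- paste0(flank,
                   paste0(vapply(cores, function(cc) paste0(cc, spacer), ""),
                          collapse = ""),
                   flank)
  genome <- Biostrings::DNAStringSet(seqstr); names(genome) <- "chr1"
  pk <- make_peaks(10, nchar(seqstr) - 10); pk$peak_id <- "fsd1like"
  n_core <- sites_per_peak(pk, genome, "GTAC", both_strands = FALSE)$counts
  n_full <- sites_per_peak(pk, genome, "GTACTRC",
                           both_strands = FALSE)$counts
  expect_equal(unname(n_core), 8L)
  expect_equal(unname(n_full), 2L)
})

test_that("center-distance density is centered, symmetric and sums to one", {
  mk <- function(offsets) {
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 7))
    gr <- rep(gr, length(offsets))
    gr$offset_from_peak_center <- offsets
    gr
  }
  d0 <- center_distance_density(mk(rep(0, 10)))
  expect_equal(nrow(d0), 1L)
  expect_equal(c(d0$bin_lo, d0$bin_hi, d0$density), c(-37.5, 37.5, 1))
  dsym <- center_distance_density(mk(c(-100, -100, 100, 100)))
  expect_equal(dsym$density[dsym$bin_lo == -112.5],
               dsym$density[dsym$bin_lo == 37.5])
  expect_equal(sum(dsym$density), 1)
  dabs <- center_distance_density(mk(c(-100, 100)), absolute = TRUE)
  expect_equal(sum(dabs$count), 2L)
  expect_equal(nrow(center_distance_density(mk(numeric(0)))), 0L)
})

test_that("normalized gene-body mapping is exact for the three zones", {
  genes <- make_genes(10000, 14000, "+")       # 4,000 bp gene
  mk_site <- function(bed_start, len = 8) {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(bed_start + 1,
                                                  bed_start + len))
    gr$gene_id <- "G001"
    gr
  }
  ## site whose midpoint is 1,000 bp into the gene: f = 0.25 -> 500
  s_in <- mk_site(11000 - 4)
  prof <- normalized_position_profile(s_in, genes)
  expect_equal(prof$coords, 500)
  expect_equal(prof$profile$count[prof$profile$bin_lo == 400], 1L)
  ## upstream site at TSS-110 stays in real bp
  s_up <- mk_site(10000 - 110 - 4)
  expect_equal(normalized_position_profile(s_up, genes)$coords, -110)
  ## site 50 bp past the TTS maps to body_norm + 50
  s_down <- mk_site(14000 + 50 - 4)
  expect_equal(normalized_position_profile(s_down, genes)$coords, 2050)
  ## minus-strand gene mirrors: site 1,000 bp downstream of its TSS
  genes_m <- make_genes(10000, 14000, "-")
  s_m <- mk_site(13000 - 4)
  expect_equal(normalized_position_profile(s_m, genes_m)$coords, 500)
  ## unknown gene id skipped with a message
  s_bad <- mk_site(11000); s_bad$gene_id <- "nope"
  expect_message(p <- normalized_position_profile(s_bad, genes), "skipped 1")
  expect_equal(sum(p$profile$count), 0L)
})
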