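test_that("BED and narrowPeak records map to peaks with verbatim fields", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr1\t1000\t1500",
               "Chr1\t2000\t2600\tpk2\t750\t.\t8.1\t12.2\t9.9\t250"), f)
  pk <- read_peaks(f, "R1", "low_cu", "tagged")
  expect_length(pk, 2L)
  expect_equal(start(pk), c(1001L, 2001L))   # 0-based half-open -> GRanges
  expect_equal(end(pk), c(1500L, 2600L))
  expect_equal(width(pk), c(500L, 600L))
  expect_equal(as.character(seqnames(pk)), c("Chr1", "Chr1"))
  expect_equal(pk$summit_offset, c(NA_integer_, 250L))
  expect_equal(pk$score, c(NA_real_, 750))
  expect_equal(pk$replicate_id, c("R1", "R1"))
})

test_that("invalid peak lines are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr1\t100\t200", "Chr1\t1500\t1000"), f)
  expect_error(read_peaks(f, "R1", "low_cu", "tagged"), "line 2.*end <= start")
  writeLines("Chr1\t100", f)
  expect_error(read_peaks(f, "R1", "low_cu", "tagged"), "line 1.*fewer than 3")
  writeLines(character(0), f)
  expect_warning(pk <- read_peaks(f, "R1", "low_cu", "tagged"), "no peak")
  expect_length(pk, 0L)
  expect_error(read_peaks(f, "R1", "lowcu", "tagged"), "condition")
})

test_that("GFF3 gene models convert coordinates and locate the TSS by strand", {
  genes <- make_genes(c(5000, 10000), c(7000, 12000), c("+", "-"))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t5001\t7000\t.\t+\t.\tID=G001",
               "chr1\tx\tmRNA\t5001\t7000\t.\t+\t.\tID=G001.1;Parent=G001",
               "chr1\tx\texon\t5001\t5600\t.\t+\t.\tParent=G001.1",
               "chr1\tx\tgene\t10001\t12000\t.\t-\t.\tID=G002"), f)
  expect_message(gm <- read_gff3_genes(f), "skipped 2 non-gene")
  expect_equal(gm$gene_id, c("G001", "G002"))
  expect_equal(start(gm), c(5001L, 10001L))
  expect_equal(end(gm), c(7000L, 12000L))
  ## + gene: first base; - gene: last base (both 1-based; 0-based 5000/11999)
  expect_equal(gene_tss(gm), c(5001, 12000))
  expect_equal(gene_tts(gm), c(7000, 10001))
})

test_that("GFF3 genes without ID or strand are an error", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t100\t200\t.\t.\t.\tID=G001"), f)
  expect_error(read_gff3_genes(f), "strand")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t100\t200\t.\t+\t.\tName=foo"), f)
  expect_error(read_gff3_genes(f), "ID")
})

test_that("DE tables preserve missing padj and reject duplicate rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcontrast\tbase_mean\tlog2fc\tpadj",
               sprintf("FSD1\twt_vs_mut_lowcu\t1800\t%.6f\t1e-30",
                       log2(4700)),
               "CITF1\twt_vs_mut_lowcu\t3\t8.607\t1e-10",
               "ZIP2\twt_vs_mut_controlcu\t0.9\t0.02\tNA"), f)
  de <- read_de_table(f)
  expect_equal(nrow(de), 3L)
  ## an RTL (WT/mutant) ratio of 4,700 corresponds to log2fc ~ 12.2
  expect_equal(de$log2fc[de$gene_id == "FSD1"], 12.2, tolerance = 0.01)
  expect_gt(de$log2fc[de$gene_id == "CITF1"], 0)
  expect_true(is.na(de$padj[de$gene_id == "ZIP2"]))
  writeLines(c("gene_id\tcontrast\tbase_mean\tlog2fc\tpadj",
               "A\twt_vs_mut_lowcu\t10\t1\t0.1",
               "A\twt_vs_mut_lowcu\t10\t2\t0.2"), f)
  expect_error(read_de_table(f), "duplicate")
})

test_that("write_bed round-trips intervals and sorts unsorted input", {
  set.seed(42)
  pk <- random_peak_set(100)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk, f)
  back <- read_peaks(f, "R1", "low_cu", "tagged")
  ## independent sort of the originals for comparison
  ord <- order(as.character(seqnames(pk)), start(pk), end(pk))
  expect_equal(as.character(seqnames(back)), as.character(seqnames(pk))[ord])
  expect_equal(start(back), start(pk)[ord])
  expect_equal(end(back), end(pk)[ord])
  ## empty set -> empty file
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(GRanges(), f2)
  expect_identical(readLines(f2), character(0))
})

test_that("interval centers are exact, including half-integers", {
  gr <- GRanges("c", IRanges(c(1001, 1001), c(1500, 1501)))
  expect_identical(interval_center(gr), c(1250, 1250.5))
})
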