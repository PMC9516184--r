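small_sim <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chrom = 1L, chrom_len_bp = 3.2e5,
               n_genes = 40L, n_true_sites = 30L,
               background_peaks_per_replicate = 10L,
               mock_peaks_per_condition = 5L, n_bound_activated = 5L,
               n_bound_repressed = 5L, n_unbound_de = 5L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("impossible geometries and inconsistent class counts are rejected", {
  expect_error(sim_config(n_genes = 500L, chrom_len_bp = 1e5), "too small")
  expect_error(sim_config(n_true_sites = 300L, n_genes = 250L),
               "must not exceed")
  expect_error(sim_config(n_bound_activated = 10L, n_bound_unchanged = 10L),
               "sum to n_true_sites")
  expect_error(sim_config(motif = "QQ"), "IUPAC")
})

test_that("identical seeds give byte-identical files; different seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_dataset(small_sim(seed = 9L), d1)
  simulate_dataset(small_sim(seed = 9L), d2)
  simulate_dataset(small_sim(seed = 10L), d3)
  files <- list.files(d1)
  expect_true(length(files) >= 13)   # genome, gff, de, truth, 8 peaks, 2 mock
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("emitted files re-parse and truth coordinates verify against them", {
  d <- withr::local_tempdir()
  out <- simulate_dataset(small_sim(), d)
  genes <- read_gff3_genes(file.path(d, "genes.gff3"))
  expect_length(genes, 30L + 10L)
  de <- read_de_table(file.path(d, "de_table.tsv"))
  expect_equal(nrow(de), 2L * 40L)
  pk <- read_peaks(file.path(d, "peaks_low_cu_R1.narrowPeak"), "R1",
                   "low_cu", "tagged")
  expect_true(all(width(pk) > 0))
  genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(Biostrings::width(genome), 3.2e5)
  ## truth sites sit in the promoter of their gene and contain the motif
  tr <- jsonlite::read_json(file.path(d, "truth.json"),
                            simplifyVector = TRUE)
  sites <- tr$sites
  gidx <- match(sites$gene_id, genes$gene_id)
  expect_false(anyNA(gidx))
  tss0 <- ifelse(as.character(strand(genes))[gidx] == "+",
                 start(genes)[gidx] - 1, end(genes)[gidx])
  expect_true(all(abs((sites$start0 + sites$end0) / 2 - tss0) <= 400))
  for (i in seq_len(3)) {
    found <- scan_motif(as.character(
      Biostrings::subseq(genome[[1]], sites$start0[i] + 1, sites$end0[i])),
      tr$config$motif)
    expect_gte(length(found), 2L)
  }
})

test_that("noise-free simulation is recovered perfectly at full support", {
  d <- withr::local_tempdir()
  cfg <- small_sim(seed = 4L, replicate_dropout_prob = 0, jitter_sd_bp = 0,
                   peak_width_sd_bp = 0, background_peaks_per_replicate = 0L)
  out <- simulate_dataset(cfg, d)
  pk <- do.call(c, lapply(1:4, function(k)
    read_peaks(file.path(d, sprintf("peaks_low_cu_R%d.narrowPeak", k)),
               paste0("R", k), "low_cu", "tagged")))
  cons <- merge_replicates(pk)
  expect_length(cons, cfg$n_true_sites)
  expect_true(all(cons$support == 4L))
  sc <- score_against_truth(list(low_cu = cons), out$truth)
  rec <- sc$site_recovery[sc$site_recovery$condition == "low_cu", ]
  expect_equal(rec$recall, 1)
  expect_equal(rec$precision, 1)
})

test_that("all-low-Cu-only sites yield zero shared peaks", {
  d <- withr::local_tempdir()
  cfg <- small_sim(seed = 5L, frac_sites_lowcu_only = 1)
  simulate_dataset(cfg, d)
  load_cons <- function(cond) {
    pk <- do.call(c, lapply(1:4, function(k)
      read_peaks(file.path(d, sprintf("peaks_%s_R%d.narrowPeak", cond, k)),
                 paste0("R", k), cond, "tagged")))
    merge_replicates(pk)
  }
  low <- load_cons("low_cu")
  ctrl <- load_cons("control_cu")
  res <- classify_presence(low, ctrl)
  expect_equal(unname(res$venn["shared_low"]), 0)
  ## control side holds only background-derived peaks, if any
  expect_lte(length(ctrl), 3L)
})

test_that("empty consensus scores as zero recall and missing precision", {
  d <- withr::local_tempdir()
  out <- simulate_dataset(small_sim(seed = 6L), d)
  sc <- score_against_truth(list(low_cu = GenomicRanges::GRanges()),
                            out$truth)
  rec <- sc$site_recovery[sc$site_recovery$condition == "low_cu", ]
  expect_equal(rec$recall, 0)
  expect_true(is.na(rec$precision))
})
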