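## Independent brute-force oracles and small fixture builders.
## Everything here recomputes from first principles in plain R loops so the
## package implementation is checked against a second, independent route.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## continuous (BED-style) bounds of a GRanges, recomputed locally
.o_lo <- function(gr) as.numeric(start(gr)) - 1
.o_hi <- function(gr) as.numeric(end(gr))

## O(n^2) reciprocal-overlap criterion matrix + transitive closure by BFS
oracle_components <- function(gr, min_frac = 0.8) {
  n <- length(gr)
  ch <- as.character(seqnames(gr))
  lo <- .o_lo(gr); hi <- .o_hi(gr)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || ch[i] != ch[j]) next
    ov <- min(hi[i], hi[j]) - max(lo[i], lo[j])
    shortest <- min(hi[i] - lo[i], hi[j] - lo[j])
    adj[i, j] <- ov >= min_frac * shortest
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

## all-pairs center-window presence classification
oracle_presence <- function(low, ctrl, frac = 0.3) {
  win <- function(gr) {
    c <- (.o_lo(gr) + .o_hi(gr)) / 2
    L <- .o_hi(gr) - .o_lo(gr)
    data.frame(ch = as.character(seqnames(gr)), lo = c - frac * L,
               hi = c + frac * L)
  }
  wl <- win(low); wc <- win(ctrl)
  shared_low <- vapply(seq_len(nrow(wl)), function(i)
    any(wl$ch[i] == wc$ch & wl$lo[i] < wc$hi & wc$lo < wl$hi[i]),
    logical(1))
  shared_ctrl <- vapply(seq_len(nrow(wc)), function(j)
    any(wc$ch[j] == wl$ch & wc$lo[j] < wl$hi & wl$lo < wc$hi[j]),
    logical(1))
  list(shared_low = shared_low, shared_ctrl = shared_ctrl)
}

## naive regex scanner: IUPAC expanded to character classes, overlapping
## matches found via zero-width lookahead; minus strand = reverse-complement
## pattern scanned on the forward sequence
iupac_to_regex <- function(pattern) {
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
             M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
             N = "[ACGT]")
  paste(codes[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}

revcomp_str <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

oracle_scan <- function(seq, pattern) {
  starts <- function(pat) {
    m <- gregexpr(paste0("(?=", iupac_to_regex(pat), ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  list(fwd = starts(pattern), rev = starts(revcomp_str(pattern)))
}

## quick builders ------------------------------------------------------------

make_peaks <- function(bed_starts, bed_ends, replicate_id = "R1",
                       chrom = "chr1", condition = "low_cu",
                       genotype = "tagged") {
  gr <- GRanges(chrom, IRanges(bed_starts + 1, bed_ends))
  gr$replicate_id <- replicate_id
  gr$condition <- condition
  gr$genotype <- genotype
  gr$score <- NA_real_
  gr$summit_offset <- NA_integer_
  gr$peak_id <- paste0(gr$replicate_id, ":", chrom, ":", bed_starts, "-",
                       bed_ends)
  gr
}

random_peak_set <- function(n, n_rep = 4, chroms = c("chr1", "chr2"),
                            span = 50000, wmin = 100, wmax = 800) {
  s <- floor(runif(n, 0, span))
  w <- floor(runif(n, wmin, wmax))
  gr <- GRanges(sample(chroms, n, replace = TRUE), IRanges(s + 1, s + w))
  gr$replicate_id <- sample(paste0("R", seq_len(n_rep)), n, replace = TRUE)
  gr$condition <- "low_cu"
  gr$genotype <- "tagged"
  gr$score <- NA_real_
  gr$summit_offset <- NA_integer_
  gr$peak_id <- paste0(gr$replicate_id, ":", as.character(seqnames(gr)), ":",
                       start(gr) - 1, "-", end(gr))
  gr[!duplicated(paste(gr$replicate_id, seqnames(gr), start(gr), end(gr)))]
}

make_genes <- function(bed_starts, bed_ends, strands, chrom = "chr1",
                       ids = NULL) {
  if (is.null(ids)) ids <- sprintf("G%03d", seq_along(bed_starts))
  gr <- GRanges(chrom, IRanges(bed_starts + 1, bed_ends), strand = strands)
  gr$gene_id <- ids
  names(gr) <- ids
  gr
}

write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     as.character(seqnames(genes)), start(genes), end(genes),
                     as.character(strand(genes)), genes$gene_id))
  writeLines(lines, path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
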