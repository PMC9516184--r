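## Degenerate (IUPAC) motif scanning and positional statistics.
##
## Matching is exact over IUPAC character classes (R = A/G, Y = C/T, S =
## C/G, W = A/T, K = G/T, M = A/C, B/D/H/V, N = any): no position-weight
## scoring and no p-values. An N in the *sequence* is an unknown base and
## never satisfies a non-N motif position. All distances use the site
## midpoint, which is symmetric for even and odd motif lengths.

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Validate an IUPAC motif pattern
#'
#' @param pattern Character string over IUPAC nucleotide codes, at most 20
#'   characters (e.g. `"GTACTRC"`).
#' @return The validated uppercase pattern, classed `"iupac_motif"`.
#' @export
iupac_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  if (length(chars) == 0L || length(chars) > 20L)
    stop("motif length must be in 1..20", call. = FALSE)
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad))
    stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(pattern, class = "iupac_motif")
}

#' Named motif presets
#'
#' The binding-site motifs tracked by the pipeline: the degenerate
#' `GTACTRC` consensus enriched in bound, factor-activated promoters, the
#' `TCTTCTST` secondary motif, the minimal `GTAC` core shared across the
#' SBP-domain family, and the extended high-affinity variant `AGTACA`
#' (whose reverse complement is `TGTACT`, so both arrangements are found by
#' a two-strand scan).
#'
#' @return Named character vector of IUPAC patterns.
#' @export
motif_presets <- function() {
  c(gtactrc = "GTACTRC", tcttctst = "TCTTCTST",
    gtac_core = "GTAC", agtaca = "AGTACA")
}

#' Scan a sequence for all degenerate-motif matches
#'
#' Reports every exact degenerate match on the forward strand and, when
#' `both_strands`, every match of the reverse-complement pattern (reported
#' in forward coordinates with strand `-`). Overlapping matches are all
#' reported. Output is ordered by position, then strand (`+` before `-`).
#'
#' @param seq Nucleotide sequence: a character string, `DNAString`, or
#'   `DNAStringSet` of length 1.
#' @param motif An [iupac_motif()] or pattern string.
#' @param both_strands Scan the minus strand too? Default `TRUE`.
#' @param chrom Sequence name used for the reported coordinates.
#' @param offset 0-based genomic offset of the first base of `seq`;
#'   reported coordinates are genomic when the scanned sequence is a slice.
#' @return A `GRanges` of motif sites (width = motif length) with strand
#'   and metadata column `matched_text`, the site sequence read 5'->3' on
#'   the reported strand (so it always satisfies the pattern).
#' @export
scan_motif <- function(seq, motif, both_strands = TRUE, chrom = "seq",
                       offset = 0L) {
  motif <- iupac_motif(as.character(motif))
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  if (!is(seq, "DNAString")) seq <- Biostrings::DNAString(toupper(seq))
  pat <- Biostrings::DNAString(unclass(motif))
  fwd <- Biostrings::matchPattern(pat, seq, fixed = "subject")
  sites <- data.frame(start = BiocGenerics::start(fwd),
                      end = BiocGenerics::end(fwd),
                      strand = rep("+", length(fwd)),
                      text = as.character(fwd))
  if (both_strands) {
    rcp <- Biostrings::reverseComplement(pat)
    rev <- Biostrings::matchPattern(rcp, seq, fixed = "subject")
    if (length(rev))
      sites <- rbind(sites, data.frame(
        start = BiocGenerics::start(rev), end = BiocGenerics::end(rev),
        strand = "-",
        text = as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(as.character(rev))))))
  }
  sites <- sites[order(sites$start, sites$strand), , drop = FALSE]
  gr <- GRanges(rep(chrom, nrow(sites)),
                IRanges(sites$start + as.integer(offset),
                        sites$end + as.integer(offset)),
                strand = sites$strand)
  gr$matched_text <- sites$text
  gr
}

.read_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"))
  ## FASTA headers may carry descriptions; keep the first token as the name
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Motif sites and copy counts within peaks
#'
#' Scans each peak (extended by motif length minus 1 on both sides so
#' edge-straddling matches are seen) and counts the sites whose midpoint
#' lies inside the peak. Overlapping matches all count, so tandem
#' arrangements contribute every copy.
#'
#' @param peaks Consensus peaks (`GRanges` with `peak_id`).
#' @param genome A `DNAStringSet` or path to a FASTA file covering every
#'   peak.
#' @param motif An [iupac_motif()] or pattern string.
#' @param both_strands Passed to [scan_motif()].
#' @return A list: `sites` (`GRanges` with `peak_id` and
#'   `offset_from_peak_center`, the signed bp from peak center to site
#'   midpoint), `counts` (integer vector, one per peak, named by peak id)
#'   and `histogram` (data.frame `copies` / `n_peaks`, zero class
#'   included).
#' @export
sites_per_peak <- function(peaks, genome, motif, both_strands = TRUE) {
  stopifnot(is(peaks, "GRanges"))
  genome <- .read_genome(genome)
  motif <- iupac_motif(as.character(motif))
  mlen <- nchar(unclass(motif))
  if (is.null(peaks$peak_id)) peaks$peak_id <- paste0("peak_", seq_along(peaks))
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  pk_chrom <- as.character(seqnames(peaks))
  if (!all(pk_chrom %in% names(genome)))
    stop("peak chromosome(s) absent from genome: ",
         paste(unique(setdiff(pk_chrom, names(genome))), collapse = ", "),
         call. = FALSE)
  if (any(end(peaks) > chrom_len[pk_chrom] | start(peaks) < 1L))
    stop("peak outside chromosome bounds", call. = FALSE)
  all_sites <- list()
  counts <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    s <- max(1L, start(peaks)[i] - (mlen - 1L))
    e <- min(chrom_len[[pk_chrom[i]]], end(peaks)[i] + (mlen - 1L))
    subseq <- Biostrings::subseq(genome[[pk_chrom[i]]], s, e)
    hits <- scan_motif(subseq, motif, both_strands = both_strands,
                       chrom = pk_chrom[i], offset = s - 1L)
    mid <- interval_center(hits)
    inside <- mid >= .bp_lo(peaks[i]) & mid < .bp_hi(peaks[i])
    hits <- hits[inside]
    counts[i] <- length(hits)
    if (length(hits)) {
      hits$peak_id <- peaks$peak_id[i]
      hits$offset_from_peak_center <-
        interval_center(hits) - interval_center(peaks[i])
      all_sites[[length(all_sites) + 1L]] <- hits
    }
  }
  ## peaks on different chromosomes yield GRanges with disjoint seqlevels;
  ## combining them is intended, so the seqinfo-merge warning is noise
  sites <- if (length(all_sites))
    suppressWarnings(do.call(c, all_sites)) else {
    gr <- GRanges()
    mcols(gr) <- DataFrame(matched_text = character(0),
                           peak_id = character(0),
                           offset_from_peak_center = numeric(0))
    gr
  }
  names(counts) <- peaks$peak_id
  hist <- data.frame(copies = 0:max(counts, 0L),
                     n_peaks = tabulate(counts + 1L,
                                        nbins = max(counts, 0L) + 1L))
  list(sites = sites, counts = counts, histogram = hist)
}

#' Binned density of motif-to-peak-center distances
#'
#' Bins signed offsets into half-open bins of width `bin_bp` centered on
#' zero (the central bin spans `[-bin_bp/2, bin_bp/2)`).
#'
#' @param sites `sites` element of [sites_per_peak()] (needs
#'   `offset_from_peak_center`).
#' @param bin_bp Bin width in bp; default 75.
#' @param absolute Use |offset| instead of the signed offset? Default
#'   `FALSE`.
#' @return A `data.frame` with `bin_lo`, `bin_hi`, `count`, `density`;
#'   densities sum to 1 when any site exists, and the frame is empty (zero
#'   rows) for empty input.
#' @export
center_distance_density <- function(sites, bin_bp = 75, absolute = FALSE) {
  if (bin_bp <= 0) stop("bin_bp must be positive", call. = FALSE)
  off <- sites$offset_from_peak_center
  if (is.null(off)) stop("sites lack 'offset_from_peak_center'", call. = FALSE)
  if (absolute) off <- abs(off)
  if (length(off) == 0L)
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0), density = numeric(0)))
  idx <- floor((off + bin_bp / 2) / bin_bp)   # bin k spans [(k-.5)b, (k+.5)b)
  rng <- range(idx)
  ks <- rng[1]:rng[2]
  counts <- tabulate(idx - rng[1] + 1L, nbins = length(ks))
  data.frame(bin_lo = (ks - 0.5) * bin_bp, bin_hi = (ks + 0.5) * bin_bp,
             count = counts, density = counts / sum(counts))
}

#' Motif frequency profile over length-normalized gene coordinates
#'
#' Maps each site to a gene-relative coordinate: real bp upstream of the
#' TSS (negative), the gene-body fraction times `body_norm` inside the gene
#' (so every gene body spans `[0, body_norm)` regardless of its true
#' length), and `body_norm` plus real bp past the TTS. Strand-oriented.
#'
#' @param sites Motif sites (`GRanges`) carrying a `gene_id` metadata
#'   column naming the gene each site is analyzed against.
#' @param genes Stranded gene models ([read_gff3_genes()]).
#' @param upstream_bp,downstream_bp Real-bp flanks retained around the
#'   normalized body; defaults 2000.
#' @param body_norm Normalized gene-body length in bp; default 2000.
#' @param bin_bp Bin width; default 200.
#' @return A list: `coords` (numeric, one normalized coordinate per mapped
#'   site), `profile` (data.frame `bin_lo` / `bin_hi` / `count`) and
#'   `n_skipped` (sites dropped because their gene id is unknown or out of
#'   the plotted range).
#' @export
normalized_position_profile <- function(sites, genes, upstream_bp = 2000,
                                        downstream_bp = 2000,
                                        body_norm = 2000, bin_bp = 200) {
  stopifnot(is(sites, "GRanges"), is(genes, "GRanges"))
  if (is.null(sites$gene_id))
    stop("sites must carry a 'gene_id' column", call. = FALSE)
  if (any(width(genes) < 1L)) stop("genes must have positive length",
                                   call. = FALSE)
  gi <- match(sites$gene_id, genes$gene_id)
  known <- !is.na(gi)
  n_skipped <- sum(!known)
  sites <- sites[known]; gi <- gi[known]
  gn <- genes[gi]
  plus <- as.character(strand(gn)) == "+"
  m <- interval_center(sites)
  L <- as.numeric(width(gn))
  ## bp from TSS in gene orientation, on the continuous axis
  u <- ifelse(plus, m - .bp_lo(gn), .bp_hi(gn) - m)
  coord <- ifelse(u < 0, u,
           ifelse(u < L, u / L * body_norm, body_norm + (u - L)))
  in_range <- coord >= -upstream_bp & coord < body_norm + downstream_bp
  n_skipped <- n_skipped + sum(!in_range)
  if (n_skipped > 0L)
    message("normalized_position_profile: skipped ", n_skipped, " site(s)")
  coord <- coord[in_range]
  edges <- seq(-upstream_bp, body_norm + downstream_bp, by = bin_bp)
  idx <- findInterval(coord, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  list(coords = coord,
       profile = data.frame(bin_lo = edges[-length(edges)],
                            bin_hi = edges[-1L], count = counts),
       n_skipped = n_skipped)
}
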