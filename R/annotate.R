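## Peak-to-gene association and localization coding.
##
## Each peak-gene link carries one localization code:
##   S — the peak interval contains the TSS base;
##   P — the peak lies entirely 5' (upstream) of the TSS;
##   G — the peak lies entirely 3' of the TSS (gene body; peaks running past
##       the TTS are still coded G, since S is reserved for the start).
## Signed distances run from the TSS to the peak center in gene orientation,
## negative upstream.

#' Associate consensus peaks with genes
#'
#' A link is created for every gene whose body overlaps the peak by at least
#' 1 bp, plus every gene whose promoter window (the `upstream_bp` bases 5'
#' of the TSS) overlaps the peak. One peak may link several genes and one
#' gene several peaks.
#'
#' @param consensus Consensus peaks (`GRanges`, as from
#'   [merge_replicates()]; any `GRanges` with `peak_id` and optionally
#'   `support`/`condition` metadata works).
#' @param genes Stranded gene models ([read_gff3_genes()]).
#' @param upstream_bp Promoter window length upstream of the TSS, default
#'   2000.
#' @return A `data.frame` with one row per link: `peak_id`, `gene_id`,
#'   `localization` (`"P"`, `"S"` or `"G"`), `signed_distance` (bp from TSS
#'   to peak center, strand-oriented, negative upstream; half-integers for
#'   odd extents), plus `support` and `condition` copied from the peak when
#'   available. Rows are ordered by (gene_id, peak_id).
#' @export
associate_peaks <- function(consensus, genes, upstream_bp = 2000) {
  stopifnot(is(consensus, "GRanges"), is(genes, "GRanges"))
  if (upstream_bp < 0) stop("upstream_bp must be >= 0", call. = FALSE)
  if (length(genes) == 0L) {
    warning("associate_peaks: empty gene list", call. = FALSE)
    return(.empty_links())
  }
  if (length(consensus) == 0L) return(.empty_links())
  if (is.null(consensus$peak_id))
    consensus$peak_id <- paste0("peak_", seq_along(consensus))
  promoters <- GenomicRanges::promoters(genes, upstream = upstream_bp,
                                        downstream = 0)
  promoters <- GenomicRanges::trim(promoters)
  body_hits <- findOverlaps(consensus, genes, minoverlap = 1L,
                            ignore.strand = TRUE)
  prom_hits <- findOverlaps(consensus, promoters, minoverlap = 1L,
                            ignore.strand = TRUE)
  pairs <- unique(rbind(as.matrix(body_hits), as.matrix(prom_hits)))
  if (nrow(pairs) == 0L) return(.empty_links())
  pk <- consensus[pairs[, 1L]]
  gn <- genes[pairs[, 2L]]
  tss1 <- gene_tss(gn)                       # 1-based TSS base
  plus <- as.character(strand(gn)) == "+"
  contains_tss <- start(pk) <= tss1 & tss1 <= end(pk)
  ## entirely 5' of the TSS base, in gene orientation
  upstream_of <- ifelse(plus, end(pk) < tss1, start(pk) > tss1)
  localization <- ifelse(contains_tss, "S", ifelse(upstream_of, "P", "G"))
  ## continuous TSS coordinate: left edge of the TSS base on +, right edge on -
  tss_c <- ifelse(plus, tss1 - 1, tss1)
  dist <- ifelse(plus, interval_center(pk) - tss_c,
                 tss_c - interval_center(pk))
  links <- data.frame(
    peak_id = pk$peak_id, gene_id = gn$gene_id,
    localization = localization, signed_distance = dist,
    stringsAsFactors = FALSE)
  if (!is.null(pk$support)) links$support <- pk$support
  if (!is.null(pk$condition)) links$condition <- pk$condition
  links <- links[order(links$gene_id, links$peak_id), ]
  rownames(links) <- NULL
  links
}

.empty_links <- function() {
  data.frame(peak_id = character(0), gene_id = character(0),
             localization = character(0), signed_distance = numeric(0),
             support = integer(0), condition = character(0),
             stringsAsFactors = FALSE)
}

#' Histogram of peak positions relative to the TSS
#'
#' Counts link distances into half-open bins `[edge_i, edge_{i+1})`. Links
#' outside the outermost edges are not counted.
#'
#' @param links Output of [associate_peaks()].
#' @param bin_edges Strictly increasing numeric vector of bp offsets
#'   (negative = upstream).
#' @return A `data.frame` with columns `bin_lo`, `bin_hi`, `count`.
#' @export
tss_distance_histogram <- function(links,
                                   bin_edges = seq(-2000, 2000, by = 200)) {
  if (any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  d <- links$signed_distance
  idx <- findInterval(d, bin_edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1L & idx < length(bin_edges)]
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1L], count = counts)
}

#' Per-gene localization code strings
#'
#' Condenses all links of each gene into the compact reporting code used for
#' candidate tables: replicate support followed by the localization letter,
#' one entry per peak, comma-joined and ordered by decreasing support (ties
#' by peak id) — e.g. a gene bound by a support-4 and a support-2 promoter
#' peak is coded `"4P, 2P"`.
#'
#' @param links Output of [associate_peaks()]; must carry a `support`
#'   column.
#' @return Named character vector, one code string per gene.
#' @export
localization_codes <- function(links) {
  if (is.null(links$support))
    stop("links must carry a 'support' column", call. = FALSE)
  if (nrow(links) == 0L) return(setNames(character(0), character(0)))
  split_links <- split(links, links$gene_id)
  vapply(split_links, function(lk) {
    lk <- lk[order(-lk$support, lk$peak_id), ]
    paste(paste0(lk$support, lk$localization), collapse = ", ")
  }, character(1))
}
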