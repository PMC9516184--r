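## Consensus peak construction across replicate ChIP-seq experiments.
##
## Two replicate peaks are merged when at least `min_frac` (default 80%) of
## the length of the shorter of the two segments is covered by their overlap.
## Merging is evaluated pairwise on the ORIGINAL replicate peaks and closed
## transitively (single linkage); the union segment is never re-tested
## against its members. A direct consequence is that every consensus segment
## is at least as long as the broadest replicate peak it absorbs.

#' Reciprocal-overlap merge criterion for two peak segments
#'
#' @param a,b `GRanges` of equal length (or one of length 1, recycled);
#'   compared element-wise.
#' @param min_frac Minimum fraction of the shorter segment that the overlap
#'   must cover, in `(0, 1]`. Default 0.8.
#' @return Logical vector: `TRUE` where the pair satisfies the criterion.
#'   Pairs on different chromosomes are `FALSE`, not an error. The criterion
#'   is symmetric in `a` and `b`.
#' @examples
#' a <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(1001, 1500))
#' b <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(1101, 1700))
#' merge_criterion(a, b)  # overlap 400 of shortest 500 -> TRUE
#' @export
merge_criterion <- function(a, b, min_frac = 0.8) {
  .check_frac(min_frac, "min_frac")
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same_chrom <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmax(0, pmin(.bp_hi(a), .bp_hi(b)) - pmax(.bp_lo(a), .bp_lo(b)))
  shortest <- pmin(width(a), width(b))
  same_chrom & ov >= min_frac * shortest
}

.check_frac <- function(x, what, max_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      (max_one && x > 1))
    stop(what, " must be a single number in (0, ",
         if (max_one) "1]" else "Inf)", call. = FALSE)
  invisible(x)
}

## union-find with path compression; returns component id per element
.uf_components <- function(n, edges_a, edges_b) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge replicate peaks into consensus peaks
#'
#' Builds the graph whose edges are peak pairs satisfying
#' [merge_criterion()], takes its connected components, and emits one
#' consensus peak per component spanning the union (min start, max end) of
#' the members. Support is the number of distinct replicates contributing to
#' the component — two peaks from the same replicate count once. Components
#' supported by fewer than `min_support` replicates are dropped (the count
#' is reported via a message).
#'
#' @param peaks `GRanges` of replicate peaks as returned by [read_peaks()];
#'   all peaks must share one `condition` and one `genotype`.
#' @param min_frac Passed to [merge_criterion()]. Default 0.8.
#' @param min_support Minimum number of distinct supporting replicates for a
#'   consensus peak to be retained. Default 2.
#' @return A `GRanges` of consensus peaks sorted by (chromosome, start),
#'   with metadata columns `peak_id`, `support`, `n_members`, `member_ids`
#'   (comma-joined member peak ids), `condition`, `genotype`. The result is
#'   independent of the input order of `peaks`.
#' @export
merge_replicates <- function(peaks, min_frac = 0.8, min_support = 2L) {
  .check_frac(min_frac, "min_frac")
  stopifnot(is(peaks, "GRanges"))
  if (min_support < 1L) stop("min_support must be >= 1", call. = FALSE)
  if (length(peaks) == 0L) return(.empty_consensus())
  cond <- unique(peaks$condition); geno <- unique(peaks$genotype)
  if (length(cond) != 1L || length(geno) != 1L)
    stop("merge_replicates expects peaks from a single (condition, genotype)",
         call. = FALSE)
  ## canonical order first, so the result cannot depend on input order
  ord <- order(as.character(seqnames(peaks)), start(peaks), end(peaks),
               peaks$replicate_id)
  peaks <- peaks[ord]
  key <- paste(peaks$replicate_id, as.character(seqnames(peaks)),
               start(peaks), end(peaks))
  if (anyDuplicated(key)) {
    warning("deduplicated ", sum(duplicated(key)),
            " identical peak(s) repeated within a replicate", call. = FALSE)
    peaks <- peaks[!duplicated(key)]
  }
  hits <- findOverlaps(peaks, drop.self = TRUE, drop.redundant = TRUE)
  qa <- queryHits(hits); qb <- subjectHits(hits)
  keep <- merge_criterion(peaks[qa], peaks[qb], min_frac = min_frac)
  comp <- .uf_components(length(peaks), qa[keep], qb[keep])
  comp <- match(comp, unique(comp))
  cstart <- tapply(start(peaks), comp, min)
  cend   <- tapply(end(peaks), comp, max)
  cchrom <- tapply(as.character(seqnames(peaks)), comp, `[[`, 1L)
  support <- as.integer(tapply(peaks$replicate_id, comp,
                               function(r) length(unique(r))))
  members <- tapply(peaks$peak_id, comp,
                    function(m) paste(sort(m), collapse = ","))
  n_members <- as.integer(tapply(comp, comp, length))
  gr <- GRanges(as.vector(cchrom), IRanges(as.vector(cstart), as.vector(cend)))
  gr$support <- support
  gr$n_members <- n_members
  gr$member_ids <- as.vector(members)
  gr$condition <- cond
  gr$genotype <- geno
  dropped <- support < min_support
  if (any(dropped))
    message("merge_replicates: dropped ", sum(dropped),
            " consensus peak(s) with support < ", min_support)
  gr <- gr[!dropped]
  gr <- gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
  gr$peak_id <- sprintf("%s_cp%04d", cond, seq_along(gr))
  names(gr) <- gr$peak_id
  gr
}

.empty_consensus <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(support = integer(0), n_members = integer(0),
                         member_ids = character(0), condition = character(0),
                         genotype = character(0), peak_id = character(0))
  gr
}

#' Tabulate consensus peaks by replicate support
#'
#' @param consensus Output of [merge_replicates()] (may combine conditions).
#' @return A `data.frame` with columns `condition`, `support`, `n_peaks`;
#'   per-condition counts sum to the number of consensus peaks.
#' @export
consensus_summary <- function(consensus) {
  stopifnot(is(consensus, "GRanges"))
  if (length(consensus) == 0L)
    return(data.frame(condition = character(0), support = integer(0),
                      n_peaks = integer(0)))
  tab <- as.data.frame(table(condition = consensus$condition,
                             support = consensus$support),
                       stringsAsFactors = FALSE)
  tab$support <- as.integer(tab$support)
  names(tab)[names(tab) == "Freq"] <- "n_peaks"
  tab <- tab[tab$n_peaks > 0L, ]
  rownames(tab) <- NULL
  tab[order(tab$condition, tab$support), ]
}
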