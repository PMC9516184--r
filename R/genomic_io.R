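#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevels<- sortSeqlevels
#' @importFrom BiocGenerics start end width strand sort
#' @importFrom methods is
#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

## All ranges are held as GRanges (1-based, closed), the native R/Bioconductor
## convention. BED and narrowPeak are 0-based half-open on disk and are
## converted on read/write; GFF3 is 1-based closed and maps directly.
## Continuous ("bp-extent") coordinates used for centers and windows treat a
## range as the real interval [start - 1, end], so a range of width L has
## extent L and its center may fall on a half-integer.

CONDITIONS <- c("low_cu", "control_cu")
GENOTYPES  <- c("tagged", "untagged_control")

## bp-extent bounds of a GRanges: left edge and right edge on the real line
.bp_lo <- function(gr) as.numeric(start(gr)) - 1
.bp_hi <- function(gr) as.numeric(end(gr))

#' Continuous center of genomic ranges
#'
#' The mid-point of the bp extent covered by each range. For a range covering
#' an odd number of bases this is a half-integer; it is kept exact (never
#' rounded) because downstream window arithmetic compares real numbers.
#'
#' @param gr A `GRanges`.
#' @return Numeric vector of center coordinates on the continuous bp axis
#'   (a range covering BED interval `[s, e)` has center `(s + e) / 2`).
#' @export
interval_center <- function(gr) {
  (.bp_lo(gr) + .bp_hi(gr)) / 2
}

.assert_choice <- function(x, choices, what) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices)
    stop(what, " must be one of: ", paste(choices, collapse = ", "),
         call. = FALSE)
  x
}

#' Read ChIP-seq peak calls from a BED or narrowPeak file
#'
#' Accepts BED3/BED6 and ENCODE narrowPeak (10-column) dialects. Coordinates
#' on disk are 0-based half-open and are converted to the 1-based closed
#' `GRanges` convention. Chromosome names are taken verbatim: no
#' `"Chr1"`/`"1"` aliasing is attempted, so mismatched naming between inputs
#' surfaces as empty overlaps rather than being silently masked.
#'
#' @param path Path to a tab-separated peak file without header.
#' @param replicate_id Replicate label, e.g. `"R1"`.
#' @param condition `"low_cu"` or `"control_cu"`.
#' @param genotype `"tagged"` (epitope-tagged line) or `"untagged_control"`
#'   (mock/negative-control immunoprecipitation).
#' @return A `GRanges` with metadata columns `replicate_id`, `condition`,
#'   `genotype`, `score` (NA when absent) and `summit_offset` (bp from peak
#'   start to the summit; NA unless the file is narrowPeak with a valid
#'   10th column).
#' @export
read_peaks <- function(path, replicate_id, condition, genotype) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("peak file not found: ", path, call. = FALSE)
  condition <- .assert_choice(condition, CONDITIONS, "condition")
  genotype  <- .assert_choice(genotype, GENOTYPES, "genotype")
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("no peak records in ", path, call. = FALSE)
    return(.empty_peaks(replicate_id, condition, genotype))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed peak line ", which(nf < 3L)[1L], " in ", path,
         ": fewer than 3 tab-separated fields", call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(s0) | is.na(e0) | s0 != floor(s0) | e0 != floor(e0)
  if (any(bad))
    stop("malformed peak line ", which(bad)[1L], " in ", path,
         ": non-integer coordinates", call. = FALSE)
  if (any(e0 <= s0))
    stop("malformed peak line ", which(e0 <= s0)[1L], " in ", path,
         ": end <= start", call. = FALSE)
  if (any(!nzchar(chrom)))
    stop("malformed peak line ", which(!nzchar(chrom))[1L], " in ", path,
         ": empty chromosome name", call. = FALSE)
  score <- rep(NA_real_, length(lines))
  has5 <- nf >= 5L
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  if (any(!is.na(score) & score < 0))
    stop("malformed peak line ", which(!is.na(score) & score < 0)[1L],
         " in ", path, ": negative score", call. = FALSE)
  summit <- rep(NA_integer_, length(lines))
  has10 <- nf >= 10L
  if (any(has10)) {
    sm <- suppressWarnings(as.integer(vapply(fields[has10], `[[`, "", 10L)))
    sm[!is.na(sm) & sm < 0L] <- NA_integer_   # -1 means "no summit called"
    summit[has10] <- sm
  }
  gr <- GRanges(chrom, IRanges(s0 + 1, e0))
  mcols(gr) <- DataFrame(
    replicate_id = replicate_id, condition = condition, genotype = genotype,
    score = score, summit_offset = summit)
  gr$peak_id <- paste0(replicate_id, ":", chrom, ":", s0, "-", e0)
  gr
}

.empty_peaks <- function(replicate_id = character(0), condition = character(0),
                         genotype = character(0)) {
  gr <- GRanges()
  mcols(gr) <- DataFrame(
    replicate_id = character(0), condition = character(0),
    genotype = character(0), score = numeric(0),
    summit_offset = integer(0), peak_id = character(0))
  gr
}

#' Read gene models from a GFF3 file
#'
#' Only records of type `gene` are consumed; all other feature types (mRNA,
#' exon, CDS, ...) are skipped and the skipped count is reported via a
#' message. GFF3 coordinates are 1-based closed, matching the internal
#' `GRanges` convention directly. Every gene must carry an `ID` attribute and
#' an explicit strand, since the transcriptional start site (TSS) is
#' strand-defined: it is the 5' extremity of the gene model.
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges` with metadata column `gene_id`, named by `gene_id`.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gff <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gff$type) == "gene"
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("read_gff3_genes: skipped ", n_skipped, " non-gene feature(s)")
  genes <- gff[keep]
  ids <- genes$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    bad <- if (is.null(ids)) 1L else which(is.na(ids) | !nzchar(ids))[1L]
    stop("gene record ", bad, " in ", path, " lacks an ID attribute",
         call. = FALSE)
  }
  str <- as.character(strand(genes))
  if (any(str == "*"))
    stop("gene '", ids[which(str == "*")[1L]], "' in ", path,
         " has no strand; gene models must be stranded", call. = FALSE)
  out <- granges(genes)
  out$gene_id <- as.character(ids)
  names(out) <- out$gene_id
  out
}

#' Transcription start / termination sites of gene models
#'
#' @param genes A stranded `GRanges` of gene models.
#' @return For `gene_tss`, the 1-based coordinate of the first transcribed
#'   base (gene start on `+`, gene end on `-`); `gene_tts` gives the
#'   opposite extremity.
#' @export
gene_tss <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' @rdname gene_tss
#' @export
gene_tts <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))
}

#' Read a per-gene differential-expression table
#'
#' Consumes the tab-separated product of an upstream differential-expression
#' analysis (one row per gene per genotype contrast). The log2 fold change is
#' oriented so that positive values mean higher expression in the wild type
#' than in the mutant, matching the relative-transcript-level (RTL,
#' WT/mutant) convention. Missing adjusted p-values (e.g. genes removed by
#' independent filtering) are preserved as `NA`, never coerced to 1.
#'
#' @param path Path to a TSV file with a header row.
#' @param columns Named character vector mapping the internal field names
#'   `gene_id`, `contrast`, `log2fc`, `padj`, `base_mean` to the column
#'   names used in the file.
#' @return A `data.frame` with columns `gene_id`, `contrast`, `log2fc`,
#'   `padj`, `base_mean`.
#' @export
read_de_table <- function(path,
                          columns = c(gene_id = "gene_id",
                                      contrast = "contrast",
                                      log2fc = "log2fc",
                                      padj = "padj",
                                      base_mean = "base_mean")) {
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  need <- c("gene_id", "contrast", "log2fc", "padj", "base_mean")
  if (!all(need %in% names(columns)))
    stop("'columns' must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(unname(columns[need]), names(tab))
  if (length(missing_cols))
    stop("DE table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  de <- data.frame(
    gene_id = as.character(tab[[columns[["gene_id"]]]]),
    contrast = as.character(tab[[columns[["contrast"]]]]),
    log2fc = as.numeric(tab[[columns[["log2fc"]]]]),
    padj = as.numeric(tab[[columns[["padj"]]]]),
    base_mean = as.numeric(tab[[columns[["base_mean"]]]]),
    stringsAsFactors = FALSE)
  if (anyDuplicated(de[c("gene_id", "contrast")]))
    stop("duplicate (gene, contrast) rows in ", path, call. = FALSE)
  bad_p <- !is.na(de$padj) & (de$padj < 0 | de$padj > 1)
  if (any(bad_p))
    stop("padj outside [0, 1] in ", path, " (gene ",
         de$gene_id[which(bad_p)[1L]], ")", call. = FALSE)
  de
}

#' Write genomic ranges as BED6
#'
#' Output is sorted by (chromosome, start) and converted back to the on-disk
#' 0-based half-open convention, so `read_peaks(write_bed(x))` reproduces all
#' interval fields exactly. The score column receives `$score` when present
#' (e.g. replicate support for consensus peaks), otherwise 0; the name column
#' receives `names(x)` or `$peak_id` when available.
#'
#' @param gr A `GRanges`.
#' @param path Output file path.
#' @param score Optional numeric vector overriding the score column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, score = NULL) {
  stopifnot(is(gr, "GRanges"))
  if (length(gr) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (is.null(score)) {
    score <- if (!is.null(gr$support)) gr$support
             else if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  }
  score[is.na(score)] <- 0
  nm <- if (!is.null(names(gr)) && all(nzchar(names(gr)))) names(gr)
        else if (!is.null(gr$peak_id)) gr$peak_id
        else paste0("region_", seq_along(gr))
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  ord <- order(as.character(seqnames(gr)), start(gr), end(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1, scientific = FALSE,
                                  trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE),
                   name = nm, score = score, strand = str)[ord, ]
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
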