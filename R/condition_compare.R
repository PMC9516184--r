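## Cross-condition classification of consensus peaks.
##
## A consensus peak is considered present in both conditions when the
## windows spanning its center +/- 30% of its segment length overlap between
## the two condition-specific peak sets. Centers are kept as exact reals
## (half-integers for odd extents), so window comparisons are never subject
## to rounding.

#' Center windows of consensus peaks
#'
#' For a peak of continuous extent `[s, e)` with center `c = (s + e) / 2`
#' and length `L = e - s`, the window is `(c - frac * L, c + frac * L)` on
#' the continuous bp axis.
#'
#' @param gr A `GRanges`.
#' @param frac Half-width as a fraction of segment length; default 0.3.
#' @return A `data.frame` with columns `chrom`, `lo`, `hi` (real-valued).
#' @export
center_window <- function(gr, frac = 0.3) {
  .check_frac(frac, "frac", max_one = FALSE)
  ctr <- interval_center(gr)
  L <- as.numeric(width(gr))
  data.frame(chrom = as.character(seqnames(gr)),
             lo = ctr - frac * L, hi = ctr + frac * L,
             stringsAsFactors = FALSE)
}

#' Do the center windows of two peaks overlap?
#'
#' @param p,q `GRanges`, recycled to equal length and compared element-wise.
#' @param frac Window half-width fraction; default 0.3.
#' @return Logical vector: `TRUE` where the two windows intersect
#'   (half-open comparison: `lo_p < hi_q` and `lo_q < hi_p`) on the same
#'   chromosome. Symmetric in `p` and `q`.
#' @export
windows_overlap <- function(p, q, frac = 0.3) {
  n <- max(length(p), length(q))
  if (length(p) == 1L) p <- rep(p, n)
  if (length(q) == 1L) q <- rep(q, n)
  stopifnot(length(p) == length(q))
  wp <- center_window(p, frac)
  wq <- center_window(q, frac)
  wp$chrom == wq$chrom & wp$lo < wq$hi & wq$lo < wp$hi
}

## indices of rows in `wb` whose window overlaps each row of `wa`;
## returns logical vector "has any partner" and first partner index (NA if none)
.window_match <- function(wa, wb) {
  has <- logical(nrow(wa))
  first <- rep(NA_integer_, nrow(wa))
  if (nrow(wa) == 0L || nrow(wb) == 0L) return(list(has = has, first = first))
  for (ch in unique(wa$chrom)) {
    ia <- which(wa$chrom == ch)
    ib <- which(wb$chrom == ch)
    if (length(ib) == 0L) next
    for (i in ia) {
      hit <- ib[wa$lo[i] < wb$hi[ib] & wb$lo[ib] < wa$hi[i]]
      if (length(hit)) {
        has[i] <- TRUE
        first[i] <- hit[1L]
      }
    }
  }
  list(has = has, first = first)
}

#' Classify consensus peaks as condition-specific or shared
#'
#' A peak from one condition is `shared` when its center window overlaps the
#' center window of any peak from the other condition; matching is per peak,
#' not per pair, so a peak may be shared with several partners yet count
#' once. Venn counts satisfy `low_only + shared_low == length(low)` and
#' `control_only + shared_control == length(ctrl)`.
#'
#' @param low,ctrl Consensus peaks ([merge_replicates()]) for the low-copper
#'   and control-copper condition of the tagged genotype.
#' @param frac Window half-width fraction; default 0.3.
#' @return A list with `classes` (data.frame: `peak_id`, `condition`,
#'   `presence` in `{low_cu_only, control_cu_only, shared}`,
#'   `matched_partner` peak id or NA) and `venn` (named numeric vector:
#'   `low_only`, `shared_low`, `shared_control`, `control_only`).
#' @export
classify_presence <- function(low, ctrl, frac = 0.3) {
  .check_frac(frac, "frac", max_one = FALSE)
  wl <- center_window(low, frac)
  wc <- center_window(ctrl, frac)
  ml <- .window_match(wl, wc)
  mc <- .window_match(wc, wl)
  id_low <- if (length(low)) low$peak_id else character(0)
  id_ctrl <- if (length(ctrl)) ctrl$peak_id else character(0)
  side <- function(ids, cond, only, m, other_ids) {
    data.frame(peak_id = ids, condition = rep(cond, length(ids)),
               presence = ifelse(m$has, "shared", only),
               matched_partner = as.character(other_ids[m$first]),
               stringsAsFactors = FALSE)
  }
  classes <- rbind(
    side(id_low, "low_cu", "low_cu_only", ml, id_ctrl),
    side(id_ctrl, "control_cu", "control_cu_only", mc, id_low))
  venn <- c(low_only = sum(!ml$has), shared_low = sum(ml$has),
            shared_control = sum(mc$has), control_only = sum(!mc$has))
  list(classes = classes, venn = venn)
}

#' Flag consensus peaks overlapped by mock (negative-control) peaks
#'
#' Peaks called in the untagged control line indicate antibody
#' cross-reaction artifacts. A consensus peak is flagged when it shares at
#' least 1 bp with any mock segment — plain interval intersection, not the
#' center-window rule. Flagged peaks are reported, never removed here;
#' exclusion is the caller's decision.
#'
#' @param consensus Consensus peaks (`GRanges`).
#' @param mock_peaks Mock peaks (`GRanges`), typically a single replicate
#'   per condition from the untagged genotype.
#' @return A list with `flags` (logical, parallel to `consensus`) and
#'   `n_flagged`.
#' @export
flag_control_overlap <- function(consensus, mock_peaks) {
  stopifnot(is(consensus, "GRanges"), is(mock_peaks, "GRanges"))
  flags <- countOverlaps(consensus, mock_peaks, minoverlap = 1L,
                         ignore.strand = TRUE) > 0L
  list(flags = unname(flags), n_flagged = sum(flags))
}
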