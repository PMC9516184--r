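## ChIP x expression integration: combine binding evidence (a gene linked to
## at least one consensus peak under a condition) with the genotype-contrast
## expression class of the same gene to call candidate direct targets.

## contrast labels in DE tables -> condition labels used by the peak modules
CONTRAST_CONDITION <- c(wt_vs_mut_lowcu = "low_cu",
                        wt_vs_mut_controlcu = "control_cu")

#' Classify genes by genotype-dependent expression
#'
#' `activated` means the transcript is higher in the wild type than in the
#' mutant (log2 WT/mutant fold change above `min_abs_log2fc`, adjusted
#' p-value at or below `padj_max`), i.e. the factor is required for normal
#' expression; `repressed` is the mirror image. Genes with a missing or
#' non-significant adjusted p-value are `unchanged`.
#'
#' @param de DE table ([read_de_table()]).
#' @param padj_max Adjusted p-value ceiling, in `(0, 1]`. Default 0.05.
#' @param min_abs_log2fc Minimum |log2 fold change| (exclusive). Default 0.
#' @return `de` with added columns `condition` (mapped from `contrast`) and
#'   `class` in `{activated, repressed, unchanged}`.
#' @export
classify_regulation <- function(de, padj_max = 0.05, min_abs_log2fc = 0) {
  .check_frac(padj_max, "padj_max")
  if (min_abs_log2fc < 0) stop("min_abs_log2fc must be >= 0", call. = FALSE)
  sig <- !is.na(de$padj) & de$padj <= padj_max & !is.na(de$log2fc)
  cls <- rep("unchanged", nrow(de))
  cls[sig & de$log2fc > min_abs_log2fc] <- "activated"
  cls[sig & de$log2fc < -min_abs_log2fc] <- "repressed"
  de$condition <- unname(CONTRAST_CONDITION[de$contrast])
  if (anyNA(de$condition))
    stop("unknown contrast label(s): ",
         paste(unique(de$contrast[is.na(de$condition)]), collapse = ", "),
         "; expected ", paste(names(CONTRAST_CONDITION), collapse = ", "),
         call. = FALSE)
  de$class <- cls
  de
}

#' Call candidate direct target genes
#'
#' A gene is a direct-activation candidate under a condition when it has at
#' least one linked consensus peak under that condition AND its expression
#' class there is `activated`; repression candidates analogously. Calls are
#' deduplicated at the gene level.
#'
#' @param links Peak-gene links ([associate_peaks()]) carrying a `condition`
#'   column; links from both conditions may be concatenated.
#' @param classes Output of [classify_regulation()].
#' @param peak_presence_filter `"any"` keeps every peak present under the
#'   condition (shared peaks included); `"condition_specific"` keeps only
#'   peaks absent from the other condition and requires a `presence` column
#'   on `links` (merged in from [classify_presence()]`$classes`).
#' @return A list with `calls` (data.frame: `gene_id`, `condition`,
#'   `verdict` in `{direct_activation_candidate,
#'   direct_repression_candidate}`, `peak_ids`, `log2fc`, `padj`) and
#'   `set_sizes` (data.frame of per-condition candidate counts).
#' @export
call_targets <- function(links, classes,
                         peak_presence_filter = c("any",
                                                  "condition_specific")) {
  peak_presence_filter <- match.arg(peak_presence_filter)
  if (is.null(links$condition))
    stop("links must carry a 'condition' column", call. = FALSE)
  if (peak_presence_filter == "condition_specific") {
    if (is.null(links$presence))
      stop("peak_presence_filter = 'condition_specific' requires a",
           " 'presence' column on links", call. = FALSE)
    links <- links[links$presence != "shared", , drop = FALSE]
  }
  calls <- list()
  for (cond in unique(classes$condition)) {
    lk <- links[links$condition == cond, , drop = FALSE]
    cl <- classes[classes$condition == cond, , drop = FALSE]
    for (verdict in c("activated", "repressed")) {
      hit <- cl[cl$class == verdict & cl$gene_id %in% lk$gene_id, ,
                drop = FALSE]
      if (nrow(hit) == 0L) next
      pk <- vapply(hit$gene_id, function(g)
        paste(sort(unique(lk$peak_id[lk$gene_id == g])), collapse = ","),
        character(1))
      calls[[length(calls) + 1L]] <- data.frame(
        gene_id = hit$gene_id, condition = cond,
        verdict = if (verdict == "activated") "direct_activation_candidate"
                  else "direct_repression_candidate",
        peak_ids = unname(pk), log2fc = hit$log2fc, padj = hit$padj,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene_id = character(0), condition = character(0),
               verdict = character(0), peak_ids = character(0),
               log2fc = numeric(0), padj = numeric(0),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$condition, calls$verdict, calls$gene_id), ]
  rownames(calls) <- NULL
  sizes <- as.data.frame(table(condition = calls$condition,
                               verdict = calls$verdict),
                         stringsAsFactors = FALSE)
  names(sizes)[names(sizes) == "Freq"] <- "n_genes"
  list(calls = calls, set_sizes = sizes)
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability of observing at least `k` genes shared between a
#' set of size `K` and an independently drawn set of size `n` from a
#' universe of `N` genes. Computed in log space via [stats::phyper()].
#'
#' @param N Universe size.
#' @param K Size of the first gene set.
#' @param n Size of the second gene set.
#' @param k Observed overlap.
#' @return A list: `N`, `K`, `n`, `k`, `expected` (`n * K / N`) and
#'   `p_value` = P(X >= k).
#' @examples
#' hypergeom_overlap(10, 5, 5, 5)$p_value  # 1 / choose(10, 5)
#' @export
hypergeom_overlap <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != floor(vals)))
    stop("N, K, n, k must be nonnegative integers", call. = FALSE)
  if (K > N || n > N) stop("K and n must not exceed N", call. = FALSE)
  if (k > min(K, n)) stop("k must not exceed min(K, n)", call. = FALSE)
  p <- exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                         log.p = TRUE))
  list(N = N, K = K, n = n, k = k, expected = n * K / N, p_value = p)
}

#' Benjamini-Hochberg adjustment for a vector of overlap-test p-values
#'
#' Convenience wrapper used when many external gene lists are tested against
#' one candidate set.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values ([stats::p.adjust()], method `"BH"`).
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
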