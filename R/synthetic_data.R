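## Self-contained synthetic dataset with the statistical structure the
## pipeline assumes: a random genome with non-overlapping stranded genes,
## true binding sites planted in promoters (with motif instances), noisy
## per-replicate peak calls around each site, background peaks, mock
## (untagged-control) peaks, and a genotype-contrast DE table whose planted
## effects are tied to a subset of the bound genes. Everything derives from
## one RNG stream seeded once, so a given seed reproduces every file byte
## for byte.

#' Configuration for the synthetic dataset
#'
#' Defaults describe the reference simulation used throughout the package's
#' validation: 250 genes on two 1-Mb chromosomes, 200 true promoter binding
#' sites (30% present only under low copper, the rest under both
#' conditions), four tagged-line replicates per condition with 20-bp center
#' jitter and 20% per-replicate dropout, 100 background peaks per
#' replicate, and a planted expression effect of |log2FC| = 4 for 20
#' bound-activated and 20 bound-repressed genes under the low-copper
#' contrast (the control-copper contrast is null throughout).
#'
#' @param seed Integer seed for the single RNG stream.
#' @param n_chrom,chrom_len_bp Genome shape.
#' @param n_genes Number of non-overlapping genes (split across
#'   chromosomes).
#' @param gene_len_range Gene length range in bp.
#' @param n_true_sites Number of true binding sites; each occupies the
#'   promoter of a distinct gene, centered `site_center_offset` bp from the
#'   TSS.
#' @param site_width_bp,site_center_offset True-site geometry (bp).
#' @param frac_sites_lowcu_only Fraction of true sites present only under
#'   low copper; the rest are present under both conditions.
#' @param replicate_count Tagged-line replicates per condition.
#' @param peak_width_bp,peak_width_sd_bp Emitted peak width distribution.
#' @param jitter_sd_bp SD of the Normal center jitter applied per emitted
#'   replicate peak.
#' @param replicate_dropout_prob Probability that a replicate misses a true
#'   site.
#' @param background_peaks_per_replicate Unreproducible noise peaks per
#'   replicate per condition, placed away from true sites.
#' @param mock_peaks_per_condition Peaks emitted for the untagged control
#'   (one mock replicate per condition); a quarter of them sit on true
#'   sites to emulate antibody cross-reaction.
#' @param motif IUPAC pattern planted (two concrete instances per true
#'   site).
#' @param de_effect_log2fc Planted |log2 WT/mutant| for bound-activated
#'   genes (sign flipped for repressed).
#' @param de_dispersion Negative-binomial dispersion of simulated counts.
#' @param de_reps Replicates per genotype in the DE simulation.
#' @param n_bound_activated,n_bound_repressed Bound genes with a planted
#'   low-copper expression effect.
#' @param n_bound_unchanged Bound genes explicitly left null; must equal
#'   `n_true_sites - n_bound_activated - n_bound_repressed`.
#' @param n_unbound_de Unbound genes given a planted effect (half up, half
#'   down), to exercise the peak-AND-expression conjunction.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_len_bp = 1e6, n_genes = 250L,
                       gene_len_range = c(1000L, 3000L),
                       n_true_sites = 200L,
                       site_width_bp = 300L, site_center_offset = -150L,
                       frac_sites_lowcu_only = 0.3,
                       replicate_count = 4L,
                       peak_width_bp = 400L, peak_width_sd_bp = 25L,
                       jitter_sd_bp = 20,
                       replicate_dropout_prob = 0.2,
                       background_peaks_per_replicate = 100L,
                       mock_peaks_per_condition = 20L,
                       motif = "GTACTRC",
                       de_effect_log2fc = 4,
                       de_dispersion = 0.05,
                       de_reps = 3L,
                       n_bound_activated = 20L,
                       n_bound_repressed = 20L,
                       n_bound_unchanged = NULL,
                       n_unbound_de = 30L) {
  if (is.null(n_bound_unchanged))
    n_bound_unchanged <- n_true_sites - n_bound_activated - n_bound_repressed
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len_bp = chrom_len_bp, n_genes = as.integer(n_genes),
              gene_len_range = as.integer(gene_len_range),
              n_true_sites = as.integer(n_true_sites),
              site_width_bp = as.integer(site_width_bp),
              site_center_offset = as.integer(site_center_offset),
              frac_sites_lowcu_only = frac_sites_lowcu_only,
              replicate_count = as.integer(replicate_count),
              peak_width_bp = as.integer(peak_width_bp),
              peak_width_sd_bp = peak_width_sd_bp,
              jitter_sd_bp = jitter_sd_bp,
              replicate_dropout_prob = replicate_dropout_prob,
              background_peaks_per_replicate =
                as.integer(background_peaks_per_replicate),
              mock_peaks_per_condition = as.integer(mock_peaks_per_condition),
              motif = as.character(motif),
              de_effect_log2fc = de_effect_log2fc,
              de_dispersion = de_dispersion, de_reps = as.integer(de_reps),
              n_bound_activated = as.integer(n_bound_activated),
              n_bound_repressed = as.integer(n_bound_repressed),
              n_bound_unchanged = as.integer(n_bound_unchanged),
              n_unbound_de = as.integer(n_unbound_de))
  counts <- unlist(cfg[c("n_chrom", "n_genes", "n_true_sites",
                         "replicate_count", "background_peaks_per_replicate",
                         "mock_peaks_per_condition", "n_bound_activated",
                         "n_bound_repressed", "n_bound_unchanged",
                         "n_unbound_de")])
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$frac_sites_lowcu_only < 0 || cfg$frac_sites_lowcu_only > 1)
    stop("frac_sites_lowcu_only must be in [0, 1]", call. = FALSE)
  if (cfg$replicate_dropout_prob < 0 || cfg$replicate_dropout_prob > 1)
    stop("replicate_dropout_prob must be in [0, 1]", call. = FALSE)
  if (cfg$n_true_sites > cfg$n_genes)
    stop("n_true_sites must not exceed n_genes", call. = FALSE)
  if (cfg$n_bound_activated + cfg$n_bound_repressed + cfg$n_bound_unchanged !=
      cfg$n_true_sites)
    stop("bound-gene class counts must sum to n_true_sites", call. = FALSE)
  if (cfg$n_unbound_de > cfg$n_genes - cfg$n_true_sites)
    stop("n_unbound_de exceeds the number of unbound genes", call. = FALSE)
  iupac_motif(cfg$motif)
  ## geometry check: genes need room for body + promoter + spacing
  slot <- max(cfg$gene_len_range) + 4000
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  if (per_chrom * slot > cfg$chrom_len_bp - 10000)
    stop("genome too small for n_genes (", per_chrom, " genes x ", slot,
         " bp per chromosome)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

## sample a concrete realization of an IUPAC pattern
.realize_motif <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(IUPAC_CODES[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.write_narrowpeak <- function(df, path) {
  ## df: chrom, start0, end0, name, score, signal, p, q, summit
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.4f\t%.4f\t%.4f\t%d",
                       df$chrom, df$start0, df$end0, df$name, df$score,
                       df$signal, df$p, df$q, df$summit), con)
}

#' Generate the synthetic dataset
#'
#' Writes `genome.fa`, `genes.gff3`, one narrowPeak file per tagged-line
#' replicate and condition (`peaks_<condition>_R<k>.narrowPeak`), one mock
#' narrowPeak per condition (`mock_<condition>.narrowPeak`),
#' `de_table.tsv`, and `truth.json` recording every planted site and gene
#' class. Two runs with the same configuration produce byte-identical
#' files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`
#'   (the truth record as an R list).
#' @export
simulate_dataset <- function(config = sim_config(), outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  cfg <- config

  ## ---- genes: sequential layout with randomized gaps, promoters clear ----
  chrom_names <- paste0("chr", seq_len(cfg$n_chrom))
  genes <- list()
  chrom_of <- rep(chrom_names, length.out = cfg$n_genes)
  chrom_of <- sort(chrom_of)  # fill chr1 first, deterministic
  cursor <- setNames(rep(5000, cfg$n_chrom), chrom_names)
  for (i in seq_len(cfg$n_genes)) {
    ch <- chrom_of[i]
    glen <- sample(seq(cfg$gene_len_range[1], cfg$gene_len_range[2], by = 50),
                   1L)
    gap <- sample(3000:4000, 1L)
    s0 <- cursor[[ch]]                       # 0-based start
    strand <- sample(c("+", "-"), 1L)
    genes[[i]] <- data.frame(gene_id = sprintf("GENE%04d", i), chrom = ch,
                             start0 = s0, end0 = s0 + glen, strand = strand,
                             stringsAsFactors = FALSE)
    cursor[[ch]] <- s0 + glen + gap
  }
  genes <- do.call(rbind, genes)
  if (any(cursor > cfg$chrom_len_bp - 5000))
    stop("gene layout exceeded chromosome length", call. = FALSE)

  ## ---- true sites in promoters of the first n_true_sites genes ----
  bound <- genes[seq_len(cfg$n_true_sites), , drop = FALSE]
  tss0 <- ifelse(bound$strand == "+", bound$start0, bound$end0)
  dirn <- ifelse(bound$strand == "+", 1, -1)
  site_center <- tss0 + dirn * cfg$site_center_offset
  half <- cfg$site_width_bp / 2
  n_lowonly <- round(cfg$frac_sites_lowcu_only * cfg$n_true_sites)
  sites <- data.frame(
    site_id = sprintf("site%04d", seq_len(cfg$n_true_sites)),
    chrom = bound$chrom, center = site_center,
    start0 = as.integer(floor(site_center - half)),
    end0 = as.integer(ceiling(site_center + half)),
    gene_id = bound$gene_id,
    condition_class = rep(c("low_cu_only", "shared"),
                          c(n_lowonly, cfg$n_true_sites - n_lowonly)),
    stringsAsFactors = FALSE)

  ## ---- genome sequence with motif instances planted inside sites ----
  seqs <- lapply(chrom_names, function(ch)
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_len_bp, replace = TRUE),
          collapse = ""))
  names(seqs) <- chrom_names
  mlen <- nchar(cfg$motif)
  for (i in seq_len(nrow(sites))) {
    for (off in c(-40L, 40L)) {
      inst <- .realize_motif(cfg$motif)
      if (sample(c(TRUE, FALSE), 1L)) inst <- .revcomp_chr(inst)
      at0 <- as.integer(round(sites$center[i] + off - mlen / 2))
      substr(seqs[[sites$chrom[i]]], at0 + 1L, at0 + mlen) <- inst
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chrom_names

  ## ---- tagged-line replicate peaks ----
  conds_of_site <- function(cls)
    if (cls == "shared") CONDITIONS else "low_cu"
  peak_files <- character(0)
  peaks_by_file <- list()
  for (cond in CONDITIONS) {
    for (k in seq_len(cfg$replicate_count)) {
      rows <- list()
      for (i in seq_len(nrow(sites))) {
        present <- cond %in% conds_of_site(sites$condition_class[i])
        keep <- stats::runif(1) >= cfg$replicate_dropout_prob
        jit <- stats::rnorm(1, 0, cfg$jitter_sd_bp)
        wid <- max(50, round(stats::rnorm(1, cfg$peak_width_bp,
                                          cfg$peak_width_sd_bp)))
        if (!present || !keep) next
        ctr <- sites$center[i] + jit
        s0 <- max(0L, as.integer(round(ctr - wid / 2)))
        e0 <- min(as.integer(cfg$chrom_len_bp), s0 + wid)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = sites$chrom[i], start0 = s0, end0 = e0,
          name = sprintf("%s_%s_R%d", sites$site_id[i], cond, k),
          score = as.integer(round(stats::runif(1, 200, 1000))),
          signal = stats::runif(1, 2, 20), p = stats::runif(1, 5, 30),
          q = stats::runif(1, 2, 20), summit = as.integer(round(wid / 2)),
          stringsAsFactors = FALSE)
      }
      ## background peaks, kept clear of true sites and their flanks
      n_bg <- 0L
      while (n_bg < cfg$background_peaks_per_replicate) {
        ch <- sample(chrom_names, 1L)
        wid <- max(50, round(stats::rnorm(1, cfg$peak_width_bp,
                                          cfg$peak_width_sd_bp)))
        s0 <- as.integer(round(stats::runif(1, 0, cfg$chrom_len_bp - wid)))
        near <- sites$chrom == ch &
          s0 < sites$end0 + 1000 & s0 + wid > sites$start0 - 1000
        if (any(near)) next
        n_bg <- n_bg + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start0 = s0, end0 = s0 + wid,
          name = sprintf("bg_%s_R%d_%04d", cond, k, n_bg),
          score = as.integer(round(stats::runif(1, 50, 300))),
          signal = stats::runif(1, 1, 5), p = stats::runif(1, 2, 8),
          q = stats::runif(1, 1, 5), summit = as.integer(round(wid / 2)),
          stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows)
      df <- df[order(df$chrom, df$start0, df$end0), , drop = FALSE]
      fn <- sprintf("peaks_%s_R%d.narrowPeak", cond, k)
      peaks_by_file[[fn]] <- df
      peak_files <- c(peak_files, fn)
    }
  }

  ## ---- mock (untagged control) peaks: 25% on true sites, rest uniform ----
  mock_files <- character(0)
  for (cond in CONDITIONS) {
    n_on <- floor(cfg$mock_peaks_per_condition / 4)
    rows <- list()
    if (n_on > 0L && nrow(sites) > 0L) {
      on_idx <- sample(nrow(sites), min(n_on, nrow(sites)))
      for (j in seq_along(on_idx)) {
        i <- on_idx[j]
        wid <- sample(150:300, 1L)
        s0 <- as.integer(round(sites$center[i] - wid / 2))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = sites$chrom[i], start0 = s0, end0 = s0 + wid,
          name = sprintf("mock_%s_on_%03d", cond, j),
          score = as.integer(round(stats::runif(1, 30, 150))),
          signal = stats::runif(1, 1, 3), p = stats::runif(1, 2, 6),
          q = stats::runif(1, 1, 3), summit = as.integer(round(wid / 2)),
          stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(cfg$mock_peaks_per_condition - n_on)) {
      ch <- sample(chrom_names, 1L)
      wid <- sample(150:300, 1L)
      s0 <- as.integer(round(stats::runif(1, 0, cfg$chrom_len_bp - wid)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start0 = s0, end0 = s0 + wid,
        name = sprintf("mock_%s_bg_%03d", cond, j),
        score = as.integer(round(stats::runif(1, 30, 150))),
        signal = stats::runif(1, 1, 3), p = stats::runif(1, 2, 6),
        q = stats::runif(1, 1, 3), summit = as.integer(round(wid / 2)),
        stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start0 = integer(0),
                 end0 = integer(0), name = character(0), score = integer(0),
                 signal = numeric(0), p = numeric(0), q = numeric(0),
                 summit = integer(0))
    df <- df[order(df$chrom, df$start0, df$end0), , drop = FALSE]
    fn <- sprintf("mock_%s.narrowPeak", cond)
    peaks_by_file[[fn]] <- df
    mock_files <- c(mock_files, fn)
  }

  ## ---- gene expression classes and DE table ----
  cls_low <- rep("unchanged", cfg$n_genes)
  cls_low[seq_len(cfg$n_bound_activated)] <- "activated"
  cls_low[cfg$n_bound_activated + seq_len(cfg$n_bound_repressed)] <-
    "repressed"
  if (cfg$n_unbound_de > 0L) {
    ub <- cfg$n_true_sites + seq_len(cfg$n_unbound_de)
    half_up <- ceiling(cfg$n_unbound_de / 2)
    cls_low[ub[seq_len(half_up)]] <- "activated"
    cls_low[ub[-seq_len(half_up)]] <- "repressed"
  }
  cls_ctrl <- rep("unchanged", cfg$n_genes)
  lfc_true <- function(cls) switch(cls, activated = cfg$de_effect_log2fc,
                                   repressed = -cfg$de_effect_log2fc, 0)
  base_mu <- exp(stats::rnorm(cfg$n_genes, log(150), 0.8))
  de_rows <- list()
  for (contrast in names(CONTRAST_CONDITION)) {
    cls <- if (CONTRAST_CONDITION[[contrast]] == "low_cu") cls_low
           else cls_ctrl
    for (i in seq_len(cfg$n_genes)) {
      mu_wt <- base_mu[i]
      mu_mut <- mu_wt * 2^(-lfc_true(cls[i]))
      size <- 1 / cfg$de_dispersion
      cwt <- stats::rnbinom(cfg$de_reps, mu = mu_wt, size = size)
      cmt <- stats::rnbinom(cfg$de_reps, mu = mu_mut, size = size)
      lwt <- log2(cwt + 0.5); lmt <- log2(cmt + 0.5)
      lfc <- mean(lwt) - mean(lmt)
      ## Wald z on log2 counts with model (delta-method) variance:
      ## var(log2 X) ~ (1/ln2)^2 * (1/mu + alpha) for X ~ NB(mu, alpha)
      vfun <- function(cn) (1 / log(2))^2 *
        (1 / max(mean(cn), 0.5) + cfg$de_dispersion)
      se <- sqrt(vfun(cwt) / cfg$de_reps + vfun(cmt) / cfg$de_reps)
      p <- 2 * stats::pnorm(-abs(lfc / se))
      de_rows[[length(de_rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], contrast = contrast,
        base_mean = mean(c(cwt, cmt)), log2fc = lfc, pvalue = p,
        stringsAsFactors = FALSE)
    }
  }
  de <- do.call(rbind, de_rows)
  de$padj <- NA_real_
  for (contrast in unique(de$contrast)) {
    sel <- de$contrast == contrast
    ## emulate independent filtering: very low counts get no adjusted p
    testable <- sel & de$base_mean >= 5 & !is.na(de$pvalue)
    de$padj[testable] <- stats::p.adjust(de$pvalue[testable], method = "BH")
  }

  ## ---- write files ----
  paths <- list(genome = file.path(outdir, "genome.fa"),
                genes = file.path(outdir, "genes.gff3"),
                de_table = file.path(outdir, "de_table.tsv"),
                truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
  gff <- c("##gff-version 3",
           sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   genes$chrom, genes$start0 + 1L, genes$end0, genes$strand,
                   genes$gene_id, genes$gene_id))
  writeLines(gff, paths$genes)
  for (fn in names(peaks_by_file)) {
    .write_narrowpeak(peaks_by_file[[fn]], file.path(outdir, fn))
    paths[[fn]] <- file.path(outdir, fn)
  }
  de_out <- de[, c("gene_id", "contrast", "base_mean", "log2fc", "padj")]
  de_out$base_mean <- sprintf("%.4f", de_out$base_mean)
  de_out$log2fc <- sprintf("%.6f", de_out$log2fc)
  de_out$padj <- ifelse(is.na(de$padj), "NA", sprintf("%.6g", de$padj))
  con <- file(paths$de_table, open = "wt")
  write.table(de_out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  truth <- list(
    config = unclass(cfg),
    sites = sites,
    genes = data.frame(genes,
                       bound = seq_len(cfg$n_genes) <= cfg$n_true_sites,
                       class_low_cu = cls_low, class_control_cu = cls_ctrl,
                       stringsAsFactors = FALSE))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth,
                 peak_files = peak_files, mock_files = mock_files))
}

#' Score pipeline output against the planted truth
#'
#' A true site counts as recovered under a condition when at least one
#' consensus peak from that condition has its center inside the site's
#' interval; a consensus peak is a true positive when its center lies
#' inside any true site present under its condition. Candidate target calls
#' are compared per condition and verdict against the planted bound-AND-
#' regulated gene sets.
#'
#' @param consensus Named list of consensus `GRanges`, one per condition
#'   (`low_cu`, `control_cu`).
#' @param truth Truth record: the list returned by [simulate_dataset()]
#'   (element `truth`) or a path to `truth.json`.
#' @param calls Optional candidate-call data.frame
#'   ([call_targets()]`$calls`).
#' @return A list with per-condition `site_recovery` (data.frame:
#'   `condition`, `n_true`, `n_recovered`, `n_consensus`, `recall`,
#'   `precision`; precision is `NA` when there are no consensus peaks) and,
#'   when `calls` is given, `target_calls` (data.frame per condition and
#'   verdict: set sizes, `n_overlap`, `precision`, `recall`,
#'   `exact_match`).
#' @export
score_against_truth <- function(consensus, truth, calls = NULL) {
  if (is.character(truth)) truth <- jsonlite::read_json(truth,
                                                        simplifyVector = TRUE)
  sites <- as.data.frame(truth$sites)
  rec <- list()
  for (cond in CONDITIONS) {
    cp <- consensus[[cond]]
    present <- sites$condition_class == "shared" |
      (cond == "low_cu" & sites$condition_class == "low_cu_only")
    tr <- sites[present, , drop = FALSE]
    if (is.null(cp) || length(cp) == 0L) {
      rec[[cond]] <- data.frame(condition = cond, n_true = nrow(tr),
                                n_recovered = 0L, n_consensus = 0L,
                                recall = if (nrow(tr)) 0 else NA_real_,
                                precision = NA_real_)
      next
    }
    ctr <- interval_center(cp)
    ch <- as.character(seqnames(cp))
    hit_site <- vapply(seq_len(nrow(tr)), function(i)
      any(ch == tr$chrom[i] & ctr >= tr$start0[i] & ctr < tr$end0[i]),
      logical(1))
    peak_tp <- vapply(seq_along(cp), function(j)
      any(tr$chrom == ch[j] & ctr[j] >= tr$start0 & ctr[j] < tr$end0),
      logical(1))
    rec[[cond]] <- data.frame(
      condition = cond, n_true = nrow(tr), n_recovered = sum(hit_site),
      n_consensus = length(cp),
      recall = if (nrow(tr)) sum(hit_site) / nrow(tr) else NA_real_,
      precision = sum(peak_tp) / length(cp))
  }
  out <- list(site_recovery = do.call(rbind, rec))
  rownames(out$site_recovery) <- NULL
  if (!is.null(calls)) {
    tg <- as.data.frame(truth$genes)
    res <- list()
    for (cond in CONDITIONS) {
      cls_col <- paste0("class_", cond)
      for (verdict in c("activated", "repressed")) {
        want <- tg$gene_id[tg$bound & tg[[cls_col]] == verdict]
        vlab <- if (verdict == "activated") "direct_activation_candidate"
                else "direct_repression_candidate"
        got <- calls$gene_id[calls$condition == cond & calls$verdict == vlab]
        ov <- length(intersect(want, got))
        res[[length(res) + 1L]] <- data.frame(
          condition = cond, verdict = vlab, n_true = length(want),
          n_called = length(got), n_overlap = ov,
          precision = if (length(got)) ov / length(got) else NA_real_,
          recall = if (length(want)) ov / length(want) else NA_real_,
          exact_match = setequal(want, got))
      }
    }
    out$target_calls <- do.call(rbind, res)
  }
  out
}
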