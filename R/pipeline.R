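## End-to-end orchestration: simulate (optional) -> merge -> compare ->
## annotate -> integrate -> motifs, with a machine-readable manifest.
## Every stage is deterministic given the inputs; all randomness lives in
## the simulator, so re-running a configuration reproduces identical
## outputs (verified by checksums in the manifest).

#' Build a pipeline run configuration
#'
#' Defaults are the parameter set the pipeline is built around: merge
#' fraction 0.8, minimum support 2 (of 4 replicates), cross-condition
#' window fraction 0.3, promoter window 2,000 bp, adjusted-p ceiling 0.05,
#' center-distance bin 75 bp, positional-profile bin 200 bp, and gene-body
#' normalization to 2,000 bp.
#'
#' @param out_dir Output directory for all result files.
#' @param seed Seed forwarded to the simulator when `input_dir` is NULL.
#' @param sim A [sim_config()] used when simulating (its `seed` field is
#'   overridden by `seed`).
#' @param input_dir Directory holding pre-existing input files laid out as
#'   written by [simulate_dataset()]; when NULL (default) the dataset is
#'   simulated into `<out_dir>/sim`.
#' @param min_frac,min_support Consensus-merging parameters.
#' @param window_frac Cross-condition center-window fraction.
#' @param upstream_bp Promoter window for peak-gene association.
#' @param padj_max,min_abs_log2fc Expression-class thresholds.
#' @param motifs Named character vector of IUPAC patterns to scan.
#' @param center_bin_bp,profile_bin_bp,body_norm Motif-statistic bins.
#' @param peak_presence_filter Passed to [call_targets()].
#' @param exclude_control_flagged Drop consensus peaks overlapped by mock
#'   peaks before annotation? Default FALSE (flags are reported either
#'   way).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(),
                       input_dir = NULL,
                       min_frac = 0.8, min_support = 2L, window_frac = 0.3,
                       upstream_bp = 2000, padj_max = 0.05,
                       min_abs_log2fc = 0,
                       motifs = motif_presets()[c("gtactrc", "tcttctst")],
                       center_bin_bp = 75, profile_bin_bp = 200,
                       body_norm = 2000,
                       peak_presence_filter = "any",
                       exclude_control_flagged = FALSE) {
  .check_frac(min_frac, "min_frac")
  .check_frac(window_frac, "window_frac", max_one = FALSE)
  .check_frac(padj_max, "padj_max")
  if (min_support < 1L) stop("min_support must be >= 1", call. = FALSE)
  if (upstream_bp < 0) stop("upstream_bp must be >= 0", call. = FALSE)
  if (any(c(center_bin_bp, profile_bin_bp, body_norm) <= 0))
    stop("bin sizes and body_norm must be positive", call. = FALSE)
  for (m in motifs) iupac_motif(m)
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    names(motifs) <- tolower(motifs)
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 input_dir = input_dir, min_frac = min_frac,
                 min_support = as.integer(min_support),
                 window_frac = window_frac, upstream_bp = upstream_bp,
                 padj_max = padj_max, min_abs_log2fc = min_abs_log2fc,
                 motifs = motifs, center_bin_bp = center_bin_bp,
                 profile_bin_bp = profile_bin_bp, body_norm = body_norm,
                 peak_presence_filter = peak_presence_filter,
                 exclude_control_flagged = exclude_control_flagged),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirror the arguments of [run_config()]; keys under `sim:` are
#' forwarded to [sim_config()]. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file is read (e.g. from CLI
#'   flags).
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  sim_args <- vals$sim
  vals$sim <- NULL
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(sim_args)) {
    unknown_sim <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(unknown_sim))
      stop("unknown sim key(s): ", paste(unknown_sim, collapse = ", "),
           call. = FALSE)
    vals$sim <- do.call(sim_config, sim_args)
  }
  do.call(run_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate (unless `input_dir` is set) -> consensus merging per
#' condition -> cross-condition comparison and mock-overlap flagging ->
#' peak-gene annotation -> expression integration and target calling ->
#' motif scanning and positional statistics, writing one file per product
#' plus `manifest.json` with parameters, per-stage counts and md5
#' checksums of every output.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages? Default TRUE.
#' @return Invisibly, a list with the in-memory stage results (`consensus`,
#'   `presence`, `links`, `targets`, `motif_stats`, `scores`, `manifest`).
#' @export
run_all <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  note <- if (quiet) function(...) invisible() else message
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  ## ---- inputs ----
  truth <- NULL
  if (is.null(config$input_dir)) {
    sim_dir <- file.path(config$out_dir, "sim")
    sim <- .stage("simulate",
                  simulate_dataset(config$sim, sim_dir))
    truth <- sim$truth
    input_dir <- sim_dir
    note("simulate: ", config$sim$n_true_sites, " true sites")
  } else {
    input_dir <- config$input_dir
    tj <- file.path(input_dir, "truth.json")
    if (file.exists(tj)) truth <- tj
  }

  reps <- seq_len(config$sim$replicate_count)
  consensus <- list()
  mock <- list()
  for (cond in CONDITIONS) {
    pk <- .stage("merge", {
      per_rep <- lapply(reps, function(k)
        read_peaks(file.path(input_dir,
                             sprintf("peaks_%s_R%d.narrowPeak", cond, k)),
                   replicate_id = paste0("R", k), condition = cond,
                   genotype = "tagged"))
      do.call(c, per_rep)
    })
    consensus[[cond]] <- .stage("merge",
      merge_replicates(pk, min_frac = config$min_frac,
                       min_support = config$min_support))
    counts[[paste0("peaks_in_", cond)]] <- length(pk)
    counts[[paste0("consensus_", cond)]] <- length(consensus[[cond]])
    write_bed(consensus[[cond]],
              file.path(config$out_dir, paste0("consensus_", cond, ".bed")))
    .write_tsv(as.data.frame(consensus[[cond]]),
               file.path(config$out_dir,
                         paste0("consensus_", cond, "_members.tsv")))
    mf <- file.path(input_dir, sprintf("mock_%s.narrowPeak", cond))
    mock[[cond]] <- if (file.exists(mf))
      suppressWarnings(read_peaks(mf, replicate_id = "M1", condition = cond,
                                  genotype = "untagged_control"))
      else .empty_peaks()
    note("merge ", cond, ": ", length(consensus[[cond]]), " consensus peaks")
  }

  ## ---- cross-condition comparison + mock flags ----
  presence <- .stage("compare",
    classify_presence(consensus$low_cu, consensus$control_cu,
                      frac = config$window_frac))
  all_mock <- do.call(c, unname(mock))
  flags <- lapply(consensus, function(cp)
    flag_control_overlap(cp, all_mock))
  for (cond in CONDITIONS) {
    consensus[[cond]]$control_flagged <- flags[[cond]]$flags
    pres <- presence$classes
    consensus[[cond]]$presence <-
      pres$presence[match(consensus[[cond]]$peak_id, pres$peak_id)]
    counts[[paste0("control_flagged_", cond)]] <- flags[[cond]]$n_flagged
    if (config$exclude_control_flagged)
      consensus[[cond]] <- consensus[[cond]][!consensus[[cond]]$control_flagged]
  }
  counts$venn <- as.list(presence$venn)
  jsonlite::write_json(c(as.list(presence$venn),
                         list(control_flagged =
                                lapply(flags, `[[`, "n_flagged"))),
                       file.path(config$out_dir, "venn_counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_tsv(presence$classes, file.path(config$out_dir,
                                         "peak_presence.tsv"))
  note("compare: venn ", paste(presence$venn, collapse = "/"))

  ## ---- annotation ----
  genes <- .stage("annotate",
                  read_gff3_genes(file.path(input_dir, "genes.gff3")))
  links <- .stage("annotate", {
    lk <- lapply(CONDITIONS, function(cond) {
      l <- associate_peaks(consensus[[cond]], genes,
                           upstream_bp = config$upstream_bp)
      cls <- presence$classes
      l$presence <- cls$presence[match(l$peak_id, cls$peak_id)]
      l
    })
    do.call(rbind, lk)
  })
  counts$links <- nrow(links)
  counts$linked_genes <- length(unique(links$gene_id))
  .write_tsv(links, file.path(config$out_dir, "peak_gene_links.tsv"))
  .write_tsv(tss_distance_histogram(links),
             file.path(config$out_dir, "tss_distance_histogram.tsv"))
  note("annotate: ", nrow(links), " links")

  ## ---- integration ----
  de <- .stage("integrate",
               read_de_table(file.path(input_dir, "de_table.tsv")))
  classes <- classify_regulation(de, padj_max = config$padj_max,
                                 min_abs_log2fc = config$min_abs_log2fc)
  targets <- .stage("integrate",
    call_targets(links, classes,
                 peak_presence_filter = config$peak_presence_filter))
  counts$target_calls <- nrow(targets$calls)
  .write_tsv(targets$calls, file.path(config$out_dir, "target_calls.tsv"))
  ## in-pipeline overlap test: linked genes low-Cu vs control-Cu over the
  ## annotated-gene universe
  gl <- unique(links$gene_id[links$condition == "low_cu"])
  gc <- unique(links$gene_id[links$condition == "control_cu"])
  ov <- hypergeom_overlap(length(genes), length(gl), length(gc),
                          length(intersect(gl, gc)))
  jsonlite::write_json(list(set_sizes = targets$set_sizes,
                            linked_gene_overlap = ov),
                       file.path(config$out_dir, "integration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("integrate: ", nrow(targets$calls), " candidate calls")

  ## ---- motifs ----
  genome <- .read_genome(file.path(input_dir, "genome.fa"))
  motif_stats <- list()
  for (mn in names(config$motifs)) {
    for (cond in CONDITIONS) {
      spp <- .stage("motifs",
        sites_per_peak(consensus[[cond]], genome, config$motifs[[mn]]))
      dens <- center_distance_density(spp$sites,
                                      bin_bp = config$center_bin_bp)
      ## primary gene per peak = closest-TSS link
      lk <- links[links$condition == cond, , drop = FALSE]
      lk <- lk[order(abs(lk$signed_distance)), , drop = FALSE]
      primary <- lk[!duplicated(lk$peak_id), c("peak_id", "gene_id")]
      sites <- spp$sites
      sites$gene_id <- primary$gene_id[match(sites$peak_id, primary$peak_id)]
      sites <- sites[!is.na(sites$gene_id)]
      prof <- normalized_position_profile(
        sites, genes, bin_bp = config$profile_bin_bp,
        body_norm = config$body_norm)
      key <- paste0(mn, "_", cond)
      motif_stats[[key]] <- list(counts = spp$counts,
                                 copies_histogram = spp$histogram,
                                 center_density = dens,
                                 profile = prof$profile)
      .write_tsv(spp$histogram,
                 file.path(config$out_dir,
                           paste0("motif_", key, "_copies.tsv")))
      .write_tsv(dens, file.path(config$out_dir,
                                 paste0("motif_", key, "_center.tsv")))
      .write_tsv(prof$profile,
                 file.path(config$out_dir,
                           paste0("motif_", key, "_profile.tsv")))
      counts[[paste0("motif_sites_", key)]] <- length(spp$sites)
    }
  }
  note("motifs: ", length(motif_stats), " motif/condition sets")

  ## ---- truth scoring + manifest ----
  scores <- NULL
  if (!is.null(truth)) {
    scores <- score_against_truth(consensus, truth, calls = targets$calls)
    jsonlite::write_json(scores, file.path(config$out_dir, "scores.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  outputs <- sort(list.files(config$out_dir, recursive = TRUE,
                             full.names = FALSE))
  outputs <- setdiff(outputs, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(config$out_dir, outputs)))
  names(checksums) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("ChIPdirect")),
    parameters = unclass(config)[setdiff(names(config),
                                         c("sim", "out_dir", "input_dir"))],
    sim = unclass(config$sim),
    counts = counts,
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(consensus = consensus, presence = presence, links = links,
                 targets = targets, motif_stats = motif_stats,
                 scores = scores, manifest = manifest))
}
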