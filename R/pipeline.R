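# End-to-end orchestration: promoters + matrix -> site maps, calibration
# report and optional expression tables, reproducible from a seed.

#' Build a validated pipeline configuration
#'
#' Exactly one of a fixed `threshold` and `calibrate = TRUE` must be active:
#' pass a numeric threshold (default 0.8) for a fixed cutoff, or
#' `calibrate = TRUE` with `threshold = NULL` to derive the cutoff from the
#' empirical null at `target_fpr`.
#'
#' @param matrix Path to a motif matrix file (JASPAR/MEME/JSON) or a
#'   [frequency_matrix()].
#' @param out_dir Output directory.
#' @param genome,gff Genome FASTA and GFF3 annotation paths (with `genes`),
#'   used when `promoters` is not given.
#' @param promoters Alternative input: promoter FASTA path or a
#'   `promoter_set` data frame.
#' @param genes Character vector of gene ids, or path to a TSV whose first
#'   column holds gene ids (header optional; a `gene_id` column is used when
#'   present).
#' @param window Upstream window length (default 1000).
#' @param threshold Fixed normalized-score cutoff (default 0.8); `NULL` when
#'   calibrating.
#' @param calibrate Derive the threshold from the null (default `FALSE`).
#' @param target_fpr Per-window false-positive-rate target for calibration.
#' @param null_method,replicates Null model (see [generate_null_set()]).
#' @param seed Integer seed governing every random draw in the run.
#' @param ct_table Optional Ct CSV path for the expression stage.
#' @param reference_gene,calibrator Passed to [ddct_fold_change()].
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(matrix, out_dir,
                       genome = NULL, gff = NULL, promoters = NULL,
                       genes = NULL, window = 1000L,
                       threshold = 0.8, calibrate = FALSE, target_fpr = 0.01,
                       null_method = "shuffle_mono", replicates = 10L,
                       seed = 1L,
                       ct_table = NULL, reference_gene = "actb",
                       calibrator = "glycerol") {
  if (isTRUE(calibrate) && !is.null(threshold))
    stop(input_error("exactly one of a fixed threshold and calibrate=TRUE may be active; pass threshold = NULL when calibrating"))
  if (!isTRUE(calibrate)) {
    if (is.null(threshold)) stop(input_error("either set a fixed threshold or calibrate = TRUE"))
    if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
      stop(input_error("threshold must be in (0, 1]"))
  }
  if (is.null(promoters) && (is.null(genome) || is.null(gff) || is.null(genes)))
    stop(input_error("need either promoters, or genome + gff + genes"))
  structure(
    list(matrix = matrix, out_dir = out_dir, genome = genome, gff = gff,
         promoters = promoters, genes = genes, window = as.integer(window),
         threshold = threshold, calibrate = isTRUE(calibrate),
         target_fpr = target_fpr, null_method = null_method,
         replicates = as.integer(replicates), seed = as.integer(seed),
         ct_table = ct_table, reference_gene = reference_gene,
         calibrator = calibrator),
    class = "run_config"
  )
}

input_error <- function(msg) {
  structure(class = c("input_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

stage_error <- function(stage, cond) {
  structure(class = c("stage_error", "error", "condition"),
            list(message = paste0("stage '", stage, "': ", conditionMessage(cond)),
                 call = conditionCall(cond), stage = stage))
}

read_gene_list <- function(genes) {
  if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
    d <- utils::read.delim(genes, stringsAsFactors = FALSE)
    col <- if ("gene_id" %in% names(d)) d$gene_id else d[[1]]
    # headerless single-column lists: read.delim consumed the first id as header
    first <- names(d)[1]
    if (!"gene_id" %in% names(d) && !first %in% c("gene_id", "gene") &&
        !grepl("^X(\\.|$)", first))
      col <- c(first, col)
    as.character(col)
  } else {
    as.character(genes)
  }
}

#' Run the promoter-scanning pipeline
#'
#' Executes, in order: matrix loading, promoter acquisition (extraction from
#' genome + GFF3 or a ready promoter FASTA), both-strand scanning and site
#' calling, null-model comparison (histograms and a threshold report; the
#' selected threshold replaces the fixed one when `calibrate = TRUE`), and an
#' optional ddCt expression stage. Writes `hits.tsv`, `hits.bed`,
#' `site_map.tsv`, `site_map.json`, `histogram.tsv`,
#' `threshold_report.json`, `promoters.fasta`, `regions.bed` (when genomic
#' intervals exist), `fold_change.tsv` (when a Ct table is given),
#' `manifest.json` and `run.log`. Rerunning with an identical configuration
#' and seed reproduces every TSV/JSON/BED output byte for byte (`run.log`
#' carries wall-clock lines and is exempt).
#'
#' A failing stage raises a `stage_error` naming the stage, and partial
#' outputs of the run are removed. An empty gene list yields headered,
#' empty outputs and a warning.
#'
#' @param config A [run_config()].
#' @return Invisibly, a manifest list: paths of written files, the effective
#'   threshold, seeds and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  out_path <- function(name) file.path(config$out_dir, name)
  fail <- function(stage, cond) {
    unlink(written)
    stop(stage_error(stage, cond))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }
  note("crzscan ", as.character(utils::packageVersion("crzscan")),
       " | R ", paste(R.version$major, R.version$minor, sep = "."))
  note("seed ", config$seed, " | threshold ",
       if (config$calibrate) "calibrated" else config$threshold)

  set.seed(config$seed)

  m <- run_stage("load_matrix", {
    fm <- if (inherits(config$matrix, "frequency_matrix")) config$matrix
          else read_motif_matrix(config$matrix)
    build_scoring_matrix(fm)
  })
  note("matrix '", m$source_id, "' width ", m$width,
       " max score ", format(m$max_score, digits = 6), " bits")

  promoters <- run_stage("promoters", {
    if (!is.null(config$promoters)) {
      p <- if (is.data.frame(config$promoters)) config$promoters
           else read_promoter_fasta(config$promoters)
      if (!is.null(config$genes)) {
        ids <- read_gene_list(config$genes)
        missing <- setdiff(ids, p$gene_id)
        if (length(missing))
          stop("gene id(s) not in promoter set: ", paste(missing, collapse = ", "))
        p <- p[match(ids, p$gene_id), , drop = FALSE]
      }
      p
    } else {
      ids <- read_gene_list(config$genes)
      extract_upstream_regions(config$genome, config$gff, ids, window = config$window)
    }
  })
  if (nrow(promoters) == 0)
    warning("empty gene list: writing headered empty outputs")
  note(nrow(promoters), " promoter(s)")

  scan_with <- function(threshold) scan_promoters(promoters, m, threshold = threshold)

  null_res <- NULL
  report <- NULL
  if (nrow(promoters) > 0 && config$replicates >= 1) {
    null_res <- run_stage("null_model", {
      null_distribution(promoters, m, method = config$null_method,
                        replicates = config$replicates, seed = config$seed)
    })
    real_scores <- run_stage("null_model", normalized_score_sample(promoters$sequence, m))
    report <- run_stage("null_model", {
      select_threshold(real_scores, null_res, target_fpr = config$target_fpr,
                       reference_threshold = if (config$calibrate) 0.8 else config$threshold)
    })
    hist_tab <- run_stage("null_model", score_histograms(real_scores, null_res))
    run_stage("null_model", write_histogram_tsv(hist_tab, out_path("histogram.tsv")))
    written <- c(written, out_path("histogram.tsv"))
    run_stage("null_model", write_threshold_json(report, out_path("threshold_report.json")))
    written <- c(written, out_path("threshold_report.json"))
    note("null: ", null_res$n_windows, " windows (", config$null_method,
         " x ", config$replicates, ")")
  }

  threshold <- if (config$calibrate) {
    if (is.null(report) || !isTRUE(report$attainable))
      fail("calibrate", simpleError("no attainable threshold from the null model"))
    report$threshold
  } else config$threshold
  note("effective threshold ", threshold)

  scan <- run_stage("scan", scan_with(threshold))
  run_stage("scan", {
    write_hits_tsv(scan, out_path("hits.tsv"))
    write_hits_bed(scan, out_path("hits.bed"), promoters = promoters)
    write_site_map_tsv(scan, out_path("site_map.tsv"))
    write_site_map_json(scan, out_path("site_map.json"))
    write_promoter_fasta(promoters, out_path("promoters.fasta"))
  })
  written <- c(written, out_path(c("hits.tsv", "hits.bed", "site_map.tsv",
                                   "site_map.json", "promoters.fasta")))
  if (nrow(promoters) && any(!is.na(promoters$contig))) {
    run_stage("scan", write_regions_bed(promoters, out_path("regions.bed")))
    written <- c(written, out_path("regions.bed"))
  }
  note(nrow(scan$hits), " site(s) called")

  if (!is.null(config$ct_table)) {
    folds <- run_stage("expression", {
      ct <- if (is.data.frame(config$ct_table)) validate_ct_records(config$ct_table)
            else read_ct_table(config$ct_table)
      ddct_fold_change(ct, reference_gene = config$reference_gene,
                       calibrator = config$calibrator)
    })
    run_stage("expression", write_fold_change_tsv(folds, out_path("fold_change.tsv")))
    written <- c(written, out_path("fold_change.tsv"))
    note(nrow(folds), " fold-change row(s)")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("crzscan")),
    seed = config$seed,
    window = config$window,
    threshold = threshold,
    calibrated = config$calibrate,
    target_fpr = if (config$calibrate) config$target_fpr else NULL,
    null_method = config$null_method,
    null_replicates = config$replicates,
    matrix = m$source_id,
    matrix_width = m$width,
    max_score_bits = m$max_score,
    n_promoters = nrow(promoters),
    n_hits = nrow(scan$hits),
    outputs = basename(written)
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, out_path("manifest.json"))
  # run.log is diagnostic only: timestamps here, nowhere else
  writeLines(c(paste0("# ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")), log_lines),
             out_path("run.log"))
  invisible(c(manifest, list(files = written, scan = scan, report = report)))
}
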