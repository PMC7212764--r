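# Relative expression from qPCR Ct tables: the 2^-ddCt (Livak) method with
# reference-gene normalization and a calibrator condition.

#' Read a Ct table
#'
#' CSV with columns `strain`, `condition`, `gene`, `replicate`, `ct`
#' (an optional `sample` column is ignored). Ct values must be positive
#' cycle numbers and replicates positive integers.
#'
#' @param path CSV path.
#' @return `data.frame` of Ct records.
#' @export
read_ct_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("strain", "condition", "gene", "replicate", "ct")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  validate_ct_records(d[need])
}

validate_ct_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(!is.finite(records$ct)) || any(records$ct <= 0))
    stop("every ct must be a positive cycle number")
  if (any(records$replicate < 1))
    stop("replicate indices must be >= 1")
  records
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Within every (strain, condition) group, replicate Ct values are averaged
#' per gene and `dCt = mean Ct(target) - mean Ct(reference)` computed against
#' the reference gene. For each strain, `ddCt = dCt(group) - dCt(calibrator
#' condition of the same strain)`; the fold change is `2^-ddCt` (amplification
#' efficiency fixed at 2, the method's defining assumption) and `log10_fold =
#' log10(fold)` matches the scale expression figures are usually drawn on.
#'
#' Replicate dispersion: per-replicate dCt values (target and reference
#' paired by replicate id) give `sd_dct`; the per-replicate fold-change table
#' is attached as attribute `"replicate_folds"` for error bars.
#'
#' @param records Ct `data.frame` with columns `strain`, `condition`,
#'   `gene`, `replicate`, `ct` (see [read_ct_table()]).
#' @param reference_gene Endogenous reference gene name (e.g. the beta-actin
#'   transcript; default `"actb"`).
#' @param calibrator Calibrator condition name (default `"glycerol"`); each
#'   strain is normalized to its own calibrator group.
#' @return `data.frame` with one row per (strain, condition, target gene):
#'   `strain`, `condition`, `gene`, `dct`, `ddct`, `fold`
#'   (`= 2^-ddct`), `log10_fold`, `n` (target replicates), `sd_dct`.
#'   Calibrator-condition rows are included (fold 1 by construction).
#' @examples
#' ct <- data.frame(
#'   strain = "WT",
#'   condition = rep(c("scb", "glycerol"), each = 2),
#'   gene = rep(c("cel7a", "actb"), 2),
#'   replicate = 1L,
#'   ct = c(20, 15, 24, 15))
#' ddct_fold_change(ct, reference_gene = "actb", calibrator = "glycerol")$fold
#' @export
ddct_fold_change <- function(records, reference_gene = "actb",
                             calibrator = "glycerol") {
  records <- validate_ct_records(records)
  grp_key <- paste(records$strain, records$condition, sep = " / ")
  groups <- unique(data.frame(strain = records$strain, condition = records$condition,
                              stringsAsFactors = FALSE))

  # per-group mean Ct per gene and per-replicate dCt
  dct_of <- function(strain, condition) {
    g <- records[records$strain == strain & records$condition == condition, , drop = FALSE]
    ref <- g[g$gene == reference_gene, , drop = FALSE]
    if (!nrow(ref))
      stop("reference gene '", reference_gene, "' missing in group ",
           strain, " / ", condition)
    ref_mean <- mean(ref$ct)
    targets <- setdiff(unique(g$gene), reference_gene)
    rows <- lapply(targets, function(gene) {
      t <- g[g$gene == gene, , drop = FALSE]
      rep_match <- match(t$replicate, ref$replicate)
      dct_rep <- t$ct - ref$ct[rep_match]  # NA where replicate unpaired
      data.frame(gene = gene,
                 dct = mean(t$ct) - ref_mean,
                 n = nrow(t),
                 sd_dct = if (sum(!is.na(dct_rep)) >= 2) stats::sd(dct_rep, na.rm = TRUE)
                          else NA_real_,
                 stringsAsFactors = FALSE)
    })
    list(table = do.call(rbind, rows),
         per_rep = do.call(rbind, lapply(targets, function(gene) {
           t <- g[g$gene == gene, , drop = FALSE]
           rep_match <- match(t$replicate, ref$replicate)
           data.frame(strain = strain, condition = condition, gene = gene,
                      replicate = t$replicate,
                      dct = t$ct - ref$ct[rep_match], stringsAsFactors = FALSE)
         })))
  }

  per_group <- lapply(seq_len(nrow(groups)), function(i)
    dct_of(groups$strain[i], groups$condition[i]))
  names(per_group) <- paste(groups$strain, groups$condition, sep = " / ")

  out_rows <- list()
  rep_rows <- list()
  for (i in seq_len(nrow(groups))) {
    strain <- groups$strain[i]
    condition <- groups$condition[i]
    cal_key <- paste(strain, calibrator, sep = " / ")
    if (!cal_key %in% names(per_group))
      stop("calibrator group '", calibrator, "' missing for strain ", strain)
    cal <- per_group[[cal_key]]$table
    cur <- per_group[[i]]$table
    if (is.null(cur)) next
    cal_dct <- cal$dct[match(cur$gene, cal$gene)]
    if (anyNA(cal_dct))
      stop("gene(s) ", paste(cur$gene[is.na(cal_dct)], collapse = ", "),
           " missing from calibrator group ", cal_key)
    ddct <- cur$dct - cal_dct
    out_rows[[i]] <- data.frame(strain = strain, condition = condition,
                                gene = cur$gene, dct = cur$dct, ddct = ddct,
                                fold = 2^(-ddct), log10_fold = log10(2^(-ddct)),
                                n = cur$n, sd_dct = cur$sd_dct,
                                stringsAsFactors = FALSE)
    pr <- per_group[[i]]$per_rep
    if (!is.null(pr) && nrow(pr)) {
      pr$ddct <- pr$dct - cal_dct[match(pr$gene, cur$gene)]
      pr$fold <- 2^(-pr$ddct)
      rep_rows[[i]] <- pr
    }
  }
  out <- do.call(rbind, out_rows)
  if (is.null(out))
    out <- data.frame(strain = character(0), condition = character(0),
                      gene = character(0), dct = numeric(0), ddct = numeric(0),
                      fold = numeric(0), log10_fold = numeric(0),
                      n = integer(0), sd_dct = numeric(0))
  rownames(out) <- NULL
  attr(out, "replicate_folds") <- do.call(rbind, rep_rows)
  attr(out, "reference_gene") <- reference_gene
  attr(out, "calibrator") <- calibrator
  out
}

#' Write a fold-change table
#'
#' @param folds Result of [ddct_fold_change()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fold_change_tsv <- function(folds, path) {
  utils::write.table(folds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
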