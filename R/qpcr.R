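# Relative expression from qPCR Cq tables by the 2^-ddCt method,
# normalised against a panel of three reference genes.
#
# Amplification efficiency is fixed at 2 (100%), as the 2^-ddCt formula
# assumes; efficiency-corrected variants are out of scope. Reference
# aggregation is the arithmetic mean of reference Cq values, which equals
# geometric-mean normalisation of the linear-scale quantities.

#' Aggregate replicate Cq values per strain and gene
#'
#' @param records data.frame with columns \code{strain_id}, \code{gene_id},
#'   \code{replicate}, \code{cq} (Cq in cycles, within (0, 50)).
#' @return data.frame with one row per (strain_id, gene_id):
#'   \code{cq_mean}, \code{cq_sd} (sample SD, \code{NA} for n = 1), \code{n}.
#' @examples
#' aggregateCq(data.frame(strain_id = "s", gene_id = "g",
#'                        replicate = 1:2, cq = c(19, 21)))
#' @export
aggregateCq <- function(records) {
  records <- as.data.frame(records)
  req <- c("strain_id", "gene_id", "replicate", "cq")
  stopifnot(all(req %in% names(records)))
  if (nrow(records) == 0L) stop("missing data: no Cq records supplied")
  if (any(!is.finite(records$cq) | records$cq <= 0 | records$cq >= 50))
    stop("cq values must be finite and within (0, 50)")
  agg <- do.call(rbind, lapply(
    split(records, list(records$strain_id, records$gene_id), drop = TRUE),
    function(g) data.frame(
      strain_id = g$strain_id[1], gene_id = g$gene_id[1],
      cq_mean = mean(g$cq),
      cq_sd = if (nrow(g) > 1L) stats::sd(g$cq) else NA_real_,
      n = nrow(g))))
  rownames(agg) <- NULL
  agg[order(agg$strain_id, agg$gene_id), , drop = FALSE]
}

#' Compute a delta-Ct value against three reference genes
#'
#' dCt = target mean Cq minus the arithmetic mean of the three reference-gene
#' mean Cq values. On the linear scale this equals normalising the target
#' quantity by the geometric mean of the three reference quantities.
#'
#' @param target_mean_cq target-gene mean Cq (cycles).
#' @param reference_mean_cqs numeric vector of exactly three reference-gene
#'   mean Cq values.
#' @return dCt in cycles.
#' @examples
#' deltaCq(20, c(18, 19, 20))  # 1
#' @export
deltaCq <- function(target_mean_cq, reference_mean_cqs) {
  stopifnot(is.numeric(target_mean_cq), is.finite(target_mean_cq))
  if (length(reference_mean_cqs) != 3L)
    stop("reference panel must contain exactly three genes, got ",
         length(reference_mean_cqs))
  stopifnot(all(is.finite(reference_mean_cqs)))
  target_mean_cq - mean(reference_mean_cqs)
}

#' Fold change and log2 relative expression from two delta-Ct values
#'
#' ddCt = dCt(sample) - dCt(calibrator); fold change = 2^-ddCt;
#' log2 relative expression = -ddCt. The calibrator against itself gives a
#' fold change of exactly 1.
#'
#' @param delta_cq_sample,delta_cq_calibrator dCt values in cycles.
#' @return list with \code{ddcq}, \code{fold_change}, \code{log2_rel_expr}.
#' @examples
#' ddcqFoldChange(3, 4)$fold_change  # 2: one cycle fewer doubles the template
#' @export
ddcqFoldChange <- function(delta_cq_sample, delta_cq_calibrator) {
  stopifnot(is.finite(delta_cq_sample), is.finite(delta_cq_calibrator))
  ddcq <- delta_cq_sample - delta_cq_calibrator
  list(ddcq = ddcq, fold_change = 2^(-ddcq), log2_rel_expr = -ddcq)
}

# Per-replicate dCt values for one strain: target Cq of replicate r minus the
# mean reference Cq of the same replicate. Requires every reference gene to
# be measured in each replicate used.
.replicate_dcq <- function(records, strain_id, gene_id, reference_genes) {
  s <- records[records$strain_id == strain_id, , drop = FALSE]
  tg <- s[s$gene_id == gene_id, , drop = FALSE]
  if (nrow(tg) == 0L) return(NULL)
  refs <- s[s$gene_id %in% reference_genes, , drop = FALSE]
  dcq <- vapply(seq_len(nrow(tg)), function(i) {
    r <- refs[refs$replicate == tg$replicate[i], , drop = FALSE]
    if (length(unique(r$gene_id)) == 3L && nrow(r) == 3L)
      tg$cq[i] - mean(r$cq)
    else NA_real_
  }, numeric(1))
  dcq <- dcq[is.finite(dcq)]
  if (length(dcq) == 0L) NULL else dcq
}

#' Build a relative-expression table by the 2^-ddCt method
#'
#' For each (strain, target gene), dCt is computed per biological replicate
#' (target Cq minus the mean of the three reference-gene Cq of the same
#' replicate), summarised as mean, SD and n, then expressed relative to the
#' calibrator strain: ddCt = dCt - dCt(calibrator), fold change = 2^-ddCt.
#' The ddCt-scale SD combines sample and calibrator replicate SDs as
#' sqrt(sd^2 + sd_cal^2). Statistical comparisons should run on the
#' dCt / log2 scale; fold changes are for display.
#'
#' @param records Cq data.frame (\code{strain_id}, \code{gene_id},
#'   \code{replicate}, \code{cq}).
#' @param reference_genes character vector of exactly three reference gene
#'   ids, disjoint from target genes.
#' @param calibrator_id strain id used as calibrator; default is the
#'   alphabetically first strain present.
#' @return data.frame with one row per (strain_id, gene_id) target pair:
#'   \code{delta_cq_mean}, \code{delta_cq_sd}, \code{n},
#'   \code{calibrator_id}, \code{log2_rel_expr}, \code{fold_change},
#'   \code{ddcq_sd}.
#' @export
buildExpressionTable <- function(records, reference_genes,
                                 calibrator_id = NULL) {
  records <- as.data.frame(records)
  if (length(unique(reference_genes)) != 3L || length(reference_genes) != 3L)
    stop("reference panel must contain exactly three distinct gene ids")
  genes <- unique(records$gene_id)
  if (!all(reference_genes %in% genes))
    stop("reference gene(s) absent from records: ",
         paste(setdiff(reference_genes, genes), collapse = ", "))
  targets <- setdiff(genes, reference_genes)
  if (length(targets) == 0L) stop("no target genes in records")
  strains_present <- sort(unique(records$strain_id))
  if (is.null(calibrator_id)) calibrator_id <- strains_present[1]
  if (!calibrator_id %in% strains_present)
    stop("calibrator strain ", calibrator_id, " absent from records")

  cal_dcq <- lapply(targets, function(g)
    .replicate_dcq(records, calibrator_id, g, reference_genes))
  names(cal_dcq) <- targets
  bad <- targets[vapply(cal_dcq, is.null, logical(1))]
  if (length(bad))
    stop("incomplete calibrator: strain ", calibrator_id,
         " lacks usable replicates for gene(s) ", paste(bad, collapse = ", "))

  rows <- list()
  for (s in strains_present) for (g in targets) {
    dcq <- .replicate_dcq(records, s, g, reference_genes)
    if (is.null(dcq)) next
    dmean <- mean(dcq)
    dsd <- if (length(dcq) > 1L) stats::sd(dcq) else NA_real_
    cal <- cal_dcq[[g]]
    cal_sd <- if (length(cal) > 1L) stats::sd(cal) else NA_real_
    fc <- ddcqFoldChange(dmean, mean(cal))
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = s, gene_id = g, delta_cq_mean = dmean, delta_cq_sd = dsd,
      n = length(dcq), calibrator_id = calibrator_id,
      log2_rel_expr = fc$log2_rel_expr, fold_change = fc$fold_change,
      ddcq_sd = sqrt(dsd^2 + cal_sd^2))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a Cq table from CSV
#'
#' Expects the header \code{strain_id,gene_id,replicate,cq}.
#'
#' @param path path to the Cq CSV.
#' @return data.frame of Cq records.
#' @export
readCqTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("strain_id", "gene_id", "replicate", "cq") %in% names(df)))
  df
}
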