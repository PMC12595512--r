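# End-to-end orchestration: validation -> qPCR -> inheritance ->
# group statistics -> ROS imaging, with CSV outputs, structured logging
# and a manifest carrying checksums for provenance.

.log_stage <- function(log, stage, rows_in, rows_out, note = "") {
  line <- sprintf("[%s] rows_in=%d rows_out=%d %s", stage, rows_in,
                  rows_out, note)
  message(line)
  c(log, line)
}

#' Build trio phenotypes from an expression table
#'
#' Extracts (mean, sd, n) per trio member and target gene from a
#' [buildExpressionTable()] result, on the log2 relative-expression scale
#' (the additive scale the m/a/d decomposition assumes; fold changes are
#' display-only).
#'
#' @param expr expression table from [buildExpressionTable()].
#' @param trios data.frame with columns \code{p1_id}, \code{p2_id},
#'   \code{f1_id}.
#' @return list of [trioPhenotype()] objects, one per trio x gene, with
#'   trait ids \code{"<gene>:<f1_id>"}.
#' @export
expressionTrios <- function(expr, trios) {
  trios <- as.data.frame(trios)
  stopifnot(all(c("p1_id", "p2_id", "f1_id") %in% names(trios)))
  out <- list()
  for (i in seq_len(nrow(trios))) {
    for (g in unique(expr$gene_id)) {
      memb <- lapply(c(trios$p1_id[i], trios$p2_id[i], trios$f1_id[i]),
                     function(id) {
                       row <- expr[expr$strain_id == id & expr$gene_id == g, ]
                       if (nrow(row) != 1L) return(NULL)
                       list(mean = row$log2_rel_expr, sd = row$delta_cq_sd,
                            n = row$n)
                     })
      if (any(vapply(memb, is.null, logical(1)))) next
      out[[length(out) + 1L]] <- trioPhenotype(
        paste0(g, ":", trios$f1_id[i]), memb[[1]], memb[[2]], memb[[3]])
    }
  }
  out
}

#' Run the full study analysis
#'
#' Executes panel/marker validation, qPCR relative expression, per-trio
#' inheritance calls, production-trait ANOVA + Scheffe letter displays and
#' ROS quantification, writing every result table plus a manifest to
#' \code{outdir}. Inputs come either from a seeded simulation or from a
#' directory of CSVs (\code{panel.csv}, \code{markers.csv}, \code{cq.csv},
#' \code{production.csv}, \code{trios.csv}, optionally
#' \code{ros_sidecar.csv} + \code{images/}). Stages whose inputs are absent
#' are skipped with a warning, never silently.
#'
#' @param outdir output directory (created if needed).
#' @param simulate logical; generate inputs with [simulateStudy()].
#' @param input_dir directory of input CSVs when \code{simulate = FALSE}.
#' @param config a [simulationConfig()] (simulation parameters).
#' @param seed integer seed for the simulation.
#' @param alpha significance level for ANOVA/Scheffe and transgressive
#'   calls.
#' @param epsilon inheritance-mode classification tolerance.
#' @param calibrator_id calibrator strain for the 2^-ddCt method; default
#'   the alphabetically first parental monokaryon of the panel.
#' @param reference_genes three reference gene ids; default from config.
#' @param images logical; include the imaging stage in simulations.
#' @return (invisibly) list with the result tables, the log and the
#'   manifest path.
#' @export
runStudy <- function(outdir, simulate = TRUE, input_dir = NULL,
                     config = simulationConfig(), seed = 1L, alpha = 0.05,
                     epsilon = 0.1, calibrator_id = NULL,
                     reference_genes = NULL, images = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  if (simulate) {
    study <- simulateStudy(config, seed,
                           image_dir = file.path(outdir, "images"),
                           images = images)
    panel <- study@panel
    markers <- study@markers
    cq <- study@cq
    production <- study@production
    trios_df <- .design_trios()
    ros_sidecar <- study@ros_sidecar
    image_dir <- study@image_dir
    if (is.null(reference_genes))
      reference_genes <- study@truth$reference_genes
  } else {
    stopifnot(!is.null(input_dir))
    rd <- function(f) {
      p <- file.path(input_dir, f)
      if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE)
      else NULL
    }
    panel_df <- rd("panel.csv")
    if (is.null(panel_df)) stop("input stage: panel.csv is required")
    panel <- StrainPanel(panel_df)
    markers <- rd("markers.csv")
    cq <- rd("cq.csv")
    production <- rd("production.csv")
    trios_df <- rd("trios.csv")
    ros_sidecar <- rd("ros_sidecar.csv")
    image_dir <- file.path(input_dir, "images")
    if (is.null(reference_genes))
      stop("reference_genes must be given for non-simulated input")
  }
  if (is.null(calibrator_id)) {
    mono <- panel@strains$strain_id[panel@strains$karyon == "monokaryon"]
    calibrator_id <- sort(mono)[1]
  }
  outputs <- list()
  wr <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
    outputs[[name]] <<- file.path(outdir, name)
  }

  # --- stage: validation ------------------------------------------------
  wr(panel@strains, "panel.csv")
  n_valid <- 0L
  if (!is.null(trios_df) && nrow(trios_df)) {
    val <- lapply(seq_len(nrow(trios_df)), function(i) {
      trio <- CrossTrio(trios_df$p1_id[i], trios_df$p2_id[i],
                        trios_df$f1_id[i])
      v <- validateCrossTrio(trio, panel)
      data.frame(p1_id = trio@p1_id, p2_id = trio@p2_id,
                 f1_id = trio@f1_id, valid = v$valid,
                 transmitting_parent = if (is.na(v$transmitting_parent))
                   "" else v$transmitting_parent,
                 message = v$message, stringsAsFactors = FALSE)
    })
    val <- do.call(rbind, val)
    wr(val, "trio_validation.csv")
    if (any(!val$valid))
      stop("validation stage: uniparental mitochondrial inheritance ",
           "violated for trio(s): ",
           paste(val$f1_id[!val$valid], collapse = ", "))
    n_valid <- nrow(val)
  }
  if (!is.null(markers) && nrow(markers)) {
    mito <- markers[markers$locus == "mito_cox1", , drop = FALSE]
    calls <- data.frame(
      strain_id = mito$strain_id,
      fragment_kb = mito$fragment_kb,
      called_mitotype = vapply(mito$fragment_kb, callMitotype,
                               character(1)),
      stringsAsFactors = FALSE)
    calls$panel_mitotype <- panel@strains$mitotype[
      match(calls$strain_id, panel@strains$strain_id)]
    calls$concordant <- calls$called_mitotype == calls$panel_mitotype
    wr(calls, "mitotype_calls.csv")
    if (any(!calls$concordant, na.rm = TRUE))
      stop("validation stage: marker mitotype call disagrees with panel ",
           "for strain(s): ",
           paste(calls$strain_id[!calls$concordant], collapse = ", "))
  }
  log <- .log_stage(log, "validation", nrow(panel@strains), n_valid,
                    sprintf("calibrator=%s", calibrator_id))

  # --- stage: qpcr ------------------------------------------------------
  expr <- NULL
  if (!is.null(cq) && nrow(cq)) {
    expr <- buildExpressionTable(cq, reference_genes, calibrator_id)
    wr(expr, "expression.csv")
    log <- .log_stage(log, "qpcr", nrow(cq), nrow(expr))
  } else {
    warning("qpcr stage skipped: no Cq records")
    log <- .log_stage(log, "qpcr", 0L, 0L, "SKIPPED")
  }

  # --- stage: inheritance ----------------------------------------------
  mi <- NULL
  if (!is.null(expr) && !is.null(trios_df) && nrow(trios_df)) {
    trio_ph <- expressionTrios(expr, trios_df)
    mi <- miTable(trio_ph, epsilon = epsilon, alpha = alpha)
    wr(mi, "mi_table.csv")
    log <- .log_stage(log, "inheritance", length(trio_ph), nrow(mi))
  } else {
    warning("inheritance stage skipped: needs expression table and trios")
    log <- .log_stage(log, "inheritance", 0L, 0L, "SKIPPED")
  }

  # --- stage: group_stats ----------------------------------------------
  if (!is.null(production) && nrow(production)) {
    stats_rows <- list(); letter_rows <- list()
    for (trait in unique(production$trait)) {
      d <- production[production$trait == trait, ]
      summ <- summarizeGroups(data.frame(label = d$strain_id,
                                         value = d$value))
      an <- anovaFromSummary(summ)
      sp <- suppressWarnings(scheffePairwise(summ, alpha = alpha))
      ld <- letterGroups(sp)
      stats_rows[[trait]] <- data.frame(
        trait = trait, f_stat = an$f_stat, df_between = an$df_between,
        df_within = an$df_within, p_value = an$p_value,
        ms_within = an$ms_within, stringsAsFactors = FALSE)
      letter_rows[[trait]] <- data.frame(
        trait = trait, label = names(ld$letters),
        mean = unname(sp$means[names(ld$letters)]),
        letters = unname(ld$letters), stringsAsFactors = FALSE)
    }
    wr(do.call(rbind, stats_rows), "production_anova.csv")
    wr(do.call(rbind, letter_rows), "production_letters.csv")
    log <- .log_stage(log, "group_stats", nrow(production),
                      length(stats_rows))
  } else {
    warning("group_stats stage skipped: no production data")
    log <- .log_stage(log, "group_stats", 0L, 0L, "SKIPPED")
  }

  # --- stage: ros_imaging ----------------------------------------------
  ros_summary <- NULL
  if (!is.null(ros_sidecar) && nrow(ros_sidecar) &&
      dir.exists(image_dir)) {
    ros <- measureRosBatch(ros_sidecar, image_dir)
    ros_summary <- summarizeRos(ros)
    wr(ros, "ros_measurements.csv")
    wr(ros_summary, "ros_summary.csv")
    log <- .log_stage(log, "ros_imaging", nrow(ros_sidecar), nrow(ros))
  } else {
    warning("ros_imaging stage skipped: no images/sidecar")
    log <- .log_stage(log, "ros_imaging", 0L, 0L, "SKIPPED")
  }

  # --- manifest ---------------------------------------------------------
  writeLines(log, file.path(outdir, "run.log"))
  out_files <- sort(names(outputs))
  manifest <- list(
    seed = seed, alpha = alpha, epsilon = epsilon,
    calibrator_id = calibrator_id,
    reference_genes = reference_genes,
    config_hash = .config_hash(config),
    outputs = lapply(out_files, function(f) list(
      file = f, md5 = unname(tools::md5sum(outputs[[f]])))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(expression = expr, mi_table = mi,
                 ros_summary = ros_summary, log = log,
                 manifest = manifest_path, outdir = outdir))
}

.config_hash <- function(config) {
  ser <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
               collapse = "\n")
  f <- tempfile(); on.exit(unlink(f))
  writeLines(ser, f)
  unname(tools::md5sum(f))
}

#' Write a human-readable study report
#'
#' Summarises a completed [runStudy()] output directory: inheritance-mode
#' counts, heterosis distribution, transgressive calls, production letter
#' displays and ROS means. Missing stage outputs yield a partial report
#' with a notice.
#'
#' @param outdir a [runStudy()] output directory.
#' @param file report path; default \code{report.txt} inside
#'   \code{outdir}.
#' @return (invisibly) the report lines.
#' @export
writeReport <- function(outdir, file = file.path(outdir, "report.txt")) {
  if (!dir.exists(outdir) || !length(list.files(outdir)))
    stop("no run outputs found in ", outdir)
  rd <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE)
    else NULL
  }
  lines <- c("Mitonuclear hybrid study report",
             strrep("=", 32), "")
  tv <- rd("trio_validation.csv")
  if (!is.null(tv)) {
    lines <- c(lines, sprintf("Trios validated: %d (%d valid)", nrow(tv),
                              sum(tv$valid)), "")
  } else lines <- c(lines, "NOTICE: no trio validation output", "")
  mi <- rd("mi_table.csv")
  if (!is.null(mi)) {
    tab <- table(mi$mode)
    lines <- c(lines, "Inheritance-mode counts (trio x gene):",
               sprintf("  %-26s %d", names(tab), as.integer(tab)), "",
               sprintf("MPH percent: median %.1f, range [%.1f, %.1f]",
                       stats::median(mi$mph_percent, na.rm = TRUE),
                       min(mi$mph_percent, na.rm = TRUE),
                       max(mi$mph_percent, na.rm = TRUE)),
               sprintf("Transgressive calls: %d of %d",
                       sum(mi$transgressive, na.rm = TRUE), nrow(mi)), "")
  } else lines <- c(lines, "NOTICE: no inheritance output", "")
  pl <- rd("production_letters.csv")
  if (!is.null(pl)) {
    lines <- c(lines, "Production letter displays:")
    for (trait in unique(pl$trait)) {
      d <- pl[pl$trait == trait, ]
      lines <- c(lines, sprintf("  %s:", trait),
                 sprintf("    %-16s %8.1f  %s", d$label, d$mean, d$letters))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "NOTICE: no production output", "")
  rs <- rd("ros_summary.csv")
  if (!is.null(rs)) {
    lines <- c(lines, "ROS percent stained area (mean over replicates):",
               sprintf("  %-16s %-8s %6.1f%%", rs$strain_id, rs$channel,
                       rs$mean), "")
  } else lines <- c(lines, "NOTICE: no ROS output", "")
  writeLines(lines, file)
  invisible(lines)
}
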