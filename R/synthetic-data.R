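# Seeded generator for every input the analysis consumes, with ground truth
# attached: the strain panel with reciprocal-mitotype hybrid pairs, marker
# fragment tables, growth-rate tables with strain x environment structure,
# trio-structured qPCR Cq tables with known inheritance modes, production
# traits, stained-plug images with known stained fraction, and a divergent
# truncation-selection breeding trajectory with inbreeding bookkeeping.

#' Default simulation configuration
#'
#' Returns the full parameter list of the synthetic study. Defaults encode
#' the study design being emulated: a panel of 5 parental monokaryons and
#' 8 reciprocal-mitotype hybrids; bimodal growth with fast and slow line
#' means of 4.07 and 1.12 mm/day; trio-structured expression for eight
#' target genes normalised against three reference genes; production traits
#' (earliness, flushes, yield) with a mitotype effect in the slow
#' background; plug images with known stained fractions.
#'
#' @param ... named overrides of top-level entries (lists are replaced
#'   wholesale).
#' @return named list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    # growth model: mm/day
    growth = list(
      fast_mean = 4.07, slow_mean = 1.12,
      tester_mean = 4.5,            # the tester outgrows other parentals
      hybrid_fast_mean = 4.2, hybrid_slow_mean = 1.5,
      env_offsets = c(`15C_malt` = -0.6, `24C_malt` = 0, `32C_malt` = -0.3,
                      `24C_glucose` = -0.2, `24C_sucrose` = -0.3,
                      `24C_glycerol` = -0.8),
      # strain x environment interactions: the (t)-mitotype slow hybrid
      # outperforms its (n) counterpart across environments
      interactions = list(dNS423_T1_t = c(`24C_malt` = 1.2,
                                          `15C_malt` = 0.8,
                                          `32C_malt` = 1.0)),
      residual_sd = 0.15, replicates = 3L),
    # expression model: log2 units relative to an arbitrary baseline
    expression = list(
      reference_genes = c("ref1", "ref2", "ref3"),
      target_genes = c("nd1", "bcs1", "rip1", "cox4", "cox5b",
                       "sod1", "cat", "gpx"),
      baseline_cq = 26, reference_cq = 20,
      baseline_log2_expr = 6,
      parental_span_a = 3,          # half the parental span, log2 units
      ratio_set = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5),
      cq_noise_sd = 0.2, replicates = 3L),
    # production model: per-hybrid means/SDs (earliness days, flush count,
    # yield g); the slow (t) hybrid fruits like the fast ones
    production = list(
      earliness_mean = c(dNF418_T1_n = 13, dNF418_T1_t = 13,
                         dNF419_T1_n = 14, dNF419_T1_t = 14,
                         dNS423_T1_n = 38, dNS423_T1_t = 26,
                         dNS426_T1_n = 35, dNS426_T1_t = 36),
      earliness_sd = c(dNF418_T1_n = 2, dNF418_T1_t = 1,
                       dNF419_T1_n = 3, dNF419_T1_t = 1,
                       dNS423_T1_n = 3, dNS423_T1_t = 1,
                       dNS426_T1_n = 1, dNS426_T1_t = 2),
      flush_rate = c(dNF418_T1_n = 2, dNF418_T1_t = 3,
                     dNF419_T1_n = 3, dNF419_T1_t = 3,
                     dNS423_T1_n = 0.2, dNS423_T1_t = 2,
                     dNS426_T1_n = 0.3, dNS426_T1_t = 0.2),
      yield_mean = c(dNF418_T1_n = 299.2, dNF418_T1_t = 256.0,
                     dNF419_T1_n = 199.7, dNF419_T1_t = 211.8,
                     dNS423_T1_n = 29.2, dNS423_T1_t = 148.2,
                     dNS426_T1_n = 39.4, dNS426_T1_t = 35.4),
      yield_sd = c(dNF418_T1_n = 77.2, dNF418_T1_t = 41.5,
                   dNF419_T1_n = 15.1, dNF419_T1_t = 36.7,
                   dNS423_T1_n = 5.0, dNS423_T1_t = 11.6,
                   dNS426_T1_n = 12.4, dNS426_T1_t = 13.0),
      replicates = 3L),
    # ROS imaging model
    ros = list(
      stained_fraction = c(dNS423_T1_n = 0.55, dNS426_T1_n = 0.45,
                           dNS423_T1_t = 0.15, dNS426_T1_t = 0.40,
                           dNF418_T1_n = 0.10, dNF418_T1_t = 0.12,
                           dNF419_T1_n = 0.10, dNF419_T1_t = 0.12),
      channel = "DHE", image_size = 128L, blob_radius = 4L,
      bg_intensity = 0.2, fg_intensity = 0.8, intensity_sd = 0.03,
      replicates = 3L),
    # breeding model
    breeding = list(
      generations = 4L, population = 200L, selected_fraction = 0.2,
      heritability = 0.5, genetic_sd = 0.8, env_sd = 0.3,
      base_mean = 2.6))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

# The fixed design panel: 2 founder heterokaryons, 5 parental monokaryons
# (4 bred-line, 1 tester) and 8 reciprocal-mitotype F1 hybrids.
.design_panel <- function() {
  monos <- c("mNF418", "mNF419", "mNS423", "mNS426")
  growth <- c("fast", "fast", "slow", "slow")
  hyb <- as.vector(t(outer(sub("^m", "", monos),
                           c("n", "t"),
                           function(p, mt) paste0("d", p, "_T1_", mt))))
  data.frame(
    strain_id = c("dN001", "dT009", monos, "mT1", hyb),
    karyon = c("heterokaryon", "heterokaryon", rep("monokaryon", 5),
               rep("heterokaryon", 8)),
    generation = c("F1", "F1", rep("F4", 4), "F1", rep("F1", 8)),
    growth_class = c("fast", "fast", growth, "fast",
                     rep(growth, each = 2)),
    mitotype = c("n", "t", rep("n", 4), "t", rep(c("n", "t"), 4)),
    stringsAsFactors = FALSE)
}

# The 8 analysis trios: bred-line monokaryon x tester -> hybrid.
.design_trios <- function() {
  hyb <- .design_panel()
  hyb <- hyb[hyb$karyon == "heterokaryon" & grepl("_T1_", hyb$strain_id), ]
  do.call(rbind, lapply(hyb$strain_id, function(f1) {
    p1 <- paste0("m", sub("^d(.*)_T1_[nt]$", "\\1", f1))
    data.frame(p1_id = p1, p2_id = "mT1", f1_id = f1,
               stringsAsFactors = FALSE)
  }))
}

.marker_table <- function(panel) {
  df <- panel@strains
  rows <- list()
  nuc_kb <- function(gc, id) {
    if (id == "mT1" || id == "dT009") return(0.3)
    if (gc == "fast") 0.4 else 3.6
  }
  for (i in seq_len(nrow(df))) {
    id <- df$strain_id[i]
    if (df$karyon[i] == "monokaryon") {
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = id, locus = "nuclear_chrVII",
        fragment_kb = nuc_kb(df$growth_class[i], id))
    } else if (grepl("_T1_", id)) {
      # hybrids carry both parental nuclear genomes: two bands
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = id, locus = "nuclear_chrVII",
        fragment_kb = nuc_kb(df$growth_class[i], id))
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = id, locus = "nuclear_chrVII", fragment_kb = 0.3)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = id, locus = "mito_cox1",
      fragment_kb = if (df$mitotype[i] == "n") 1.9 else 0.2)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate growth-rate replicates across environments
#'
#' value = mu(strain) + beta(environment) + gamma(strain x environment) +
#' Normal(0, residual_sd), with \code{replicates} values per cell.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @return list with \code{data} (data.frame \code{strain_id},
#'   \code{environment}, \code{replicate}, \code{value}) and \code{truth}
#'   (data.frame of cell means \code{strain_id}, \code{environment},
#'   \code{true_mean}).
#' @export
simulateGrowth <- function(config = simulationConfig(), seed = 1L) {
  g <- config$growth
  panel <- .design_panel()
  mu <- vapply(seq_len(nrow(panel)), function(i) {
    id <- panel$strain_id[i]
    if (id == "mT1") return(g$tester_mean)
    if (panel$karyon[i] == "monokaryon")
      return(if (panel$growth_class[i] == "fast") g$fast_mean else g$slow_mean)
    if (panel$growth_class[i] == "fast") g$hybrid_fast_mean
    else g$hybrid_slow_mean
  }, numeric(1))
  names(mu) <- panel$strain_id
  envs <- names(g$env_offsets)
  grid <- expand.grid(strain_id = panel$strain_id, environment = envs,
                      stringsAsFactors = FALSE)
  gamma <- vapply(seq_len(nrow(grid)), function(i) {
    ia <- g$interactions[[grid$strain_id[i]]]
    if (is.null(ia)) 0 else {
      v <- ia[grid$environment[i]]
      if (is.na(v)) 0 else unname(v)
    }
  }, numeric(1))
  grid$true_mean <- mu[grid$strain_id] + g$env_offsets[grid$environment] + gamma
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  reps <- g$replicates
  data <- grid[rep(seq_len(nrow(grid)), each = reps), c("strain_id", "environment")]
  data$replicate <- rep(seq_len(reps), nrow(grid))
  data$value <- rep(grid$true_mean, each = reps) +
    stats::rnorm(nrow(data), 0, g$residual_sd)
  rownames(data) <- NULL
  list(data = data, truth = grid)
}

#' Simulate a trio-structured qPCR Cq panel with known inheritance modes
#'
#' For each trio and target gene, the true log2 expression levels are
#' P1 = b + a, P2 = b - a (b the baseline, a the parental span / 2) and
#' F1 = b + ratio * a, with the true dominance ratio cycled through
#' \code{ratio_set}. Target Cq = baseline_cq - log2 expression + noise;
#' reference genes are constant + noise.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @param trios data.frame \code{p1_id,p2_id,f1_id}; defaults to the design
#'   panel's 8 hybrid trios.
#' @param n_trios optionally replicate/extend the trio set to this many
#'   trios (synthetic strain ids) for recovery experiments.
#' @return list with \code{data} (Cq records), \code{truth} (one row per
#'   trio x gene: ids, \code{gene_id}, true \code{a}, \code{ratio},
#'   \code{mode}, \code{mph_percent}, member log2 levels) and
#'   \code{reference_genes}.
#' @export
simulateCqPanel <- function(config = simulationConfig(), seed = 1L,
                            trios = NULL, n_trios = NULL) {
  e <- config$expression
  stopifnot(e$parental_span_a > 0)
  if (is.null(trios)) trios <- .design_trios()
  if (!is.null(n_trios)) {
    idx <- rep(seq_len(nrow(trios)), length.out = n_trios)
    trios <- trios[idx, , drop = FALSE]
    trios$f1_id <- paste0(trios$f1_id, "_r", seq_len(n_trios))
    trios$p1_id <- paste0(trios$p1_id, "_r", seq_len(n_trios))
    trios$p2_id <- paste0(trios$p2_id, "_r", seq_len(n_trios))
  }
  genes <- e$target_genes
  b <- e$baseline_log2_expr
  a <- e$parental_span_a
  # deterministic ratio assignment: cycle the ratio set over trio x gene
  design <- expand.grid(trio = seq_len(nrow(trios)), gene_id = genes,
                        stringsAsFactors = FALSE)
  design$ratio <- e$ratio_set[(seq_len(nrow(design)) - 1L) %%
                                length(e$ratio_set) + 1L]
  design$p1_id <- trios$p1_id[design$trio]
  design$p2_id <- trios$p2_id[design$trio]
  design$f1_id <- trios$f1_id[design$trio]
  design$a <- a
  design$p1_log2 <- b + a
  design$p2_log2 <- b - a
  design$f1_log2 <- b + design$ratio * a
  design$mode <- vapply(design$ratio, classifyMode, character(1))
  design$mph_percent <- 100 * (design$f1_log2 - b) / b

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  strains_l2 <- list()
  for (i in seq_len(nrow(design))) {
    strains_l2[[design$p1_id[i]]][[design$gene_id[i]]] <- design$p1_log2[i]
    strains_l2[[design$p2_id[i]]][[design$gene_id[i]]] <- design$p2_log2[i]
    strains_l2[[design$f1_id[i]]][[design$gene_id[i]]] <- design$f1_log2[i]
  }
  reps <- e$replicates
  rows <- list()
  for (s in names(strains_l2)) {
    for (g in names(strains_l2[[s]])) {
      cq <- e$baseline_cq - strains_l2[[s]][[g]] +
        stats::rnorm(reps, 0, e$cq_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = s, gene_id = g, replicate = seq_len(reps), cq = cq)
    }
    for (rg in e$reference_genes) {
      cq <- e$reference_cq + stats::rnorm(reps, 0, e$cq_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = s, gene_id = rg, replicate = seq_len(reps), cq = cq)
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  design$trio <- NULL
  list(data = data, truth = design, reference_genes = e$reference_genes)
}

#' Simulate production-trait replicates
#'
#' Yield and earliness are Normal per strain; flush counts are shifted
#' Poisson, 1 + Poisson(rate), so every fruiting strain has at least one
#' flush.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @param replicates replicate count per strain x trait (default from
#'   config).
#' @return list with \code{data} (data.frame \code{strain_id}, \code{trait},
#'   \code{replicate}, \code{value}) and \code{truth} (configured means/SDs).
#' @export
simulateProduction <- function(config = simulationConfig(), seed = 1L,
                               replicates = NULL) {
  p <- config$production
  if (any(p$flush_rate < 0)) stop("flush_rate must be non-negative")
  if (is.null(replicates)) replicates <- p$replicates
  ids <- names(p$earliness_mean)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- list()
  for (id in ids) {
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = id, trait = "earliness", replicate = seq_len(replicates),
      value = stats::rnorm(replicates, p$earliness_mean[[id]],
                           p$earliness_sd[[id]]))
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = id, trait = "flushes", replicate = seq_len(replicates),
      value = 1 + stats::rpois(replicates, p$flush_rate[[id]]))
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = id, trait = "yield", replicate = seq_len(replicates),
      value = stats::rnorm(replicates, p$yield_mean[[id]], p$yield_sd[[id]]))
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  truth <- data.frame(
    strain_id = ids,
    earliness_mean = unname(p$earliness_mean[ids]),
    earliness_sd = unname(p$earliness_sd[ids]),
    flush_mean = 1 + unname(p$flush_rate[ids]),
    yield_mean = unname(p$yield_mean[ids]),
    yield_sd = unname(p$yield_sd[ids]), stringsAsFactors = FALSE)
  list(data = data, truth = truth)
}

# Paint bright blobs inside the disc until the target stained fraction of
# plug pixels is reached; returns the stained logical mask.
.paint_blobs <- function(mask, target_fraction, blob_radius) {
  plug_px <- sum(mask)
  target_px <- round(target_fraction * plug_px)
  stained <- matrix(FALSE, nrow(mask), ncol(mask))
  if (target_px == 0) return(stained)
  if (target_fraction >= 1) { stained[mask] <- TRUE; return(stained) }
  idx <- which(mask, arr.ind = TRUE)
  guard <- 0L
  while (sum(stained & mask) < target_px && guard < 10000L) {
    guard <- guard + 1L
    c0 <- idx[sample.int(nrow(idx), 1L), ]
    rr <- (seq_len(nrow(mask)) - c0[1])^2
    cc <- (seq_len(ncol(mask)) - c0[2])^2
    blob <- outer(rr, cc, "+") <= blob_radius^2
    need <- target_px - sum(stained & mask)
    add <- which(blob & mask & !stained)
    if (length(add) > need) add <- add[seq_len(need)]
    stained[add] <- TRUE
  }
  stained
}

#' Simulate stained-plug images with known stained fraction
#'
#' Writes one 8-bit grayscale PNG per strain x replicate: a plug disc of
#' background intensity with bright blobs covering the configured fraction
#' of the plug area, plus a sidecar CSV and a truth table recording the
#' exact achieved pixel fraction.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @param dir output directory for the images (created if needed).
#' @return list with \code{sidecar} (data.frame \code{strain_id},
#'   \code{channel}, \code{replicate}, \code{filename}, \code{cx},
#'   \code{cy}, \code{r}), \code{truth} (\code{strain_id}, \code{replicate},
#'   \code{target_fraction}, \code{true_fraction}) and \code{dir}.
#' @export
simulatePlugImages <- function(config = simulationConfig(), seed = 1L,
                               dir = tempfile("plugs")) {
  r <- config$ros
  if (any(r$stained_fraction < 0 | r$stained_fraction > 1))
    stop("stained fractions must lie in [0, 1]")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sz <- r$image_size
  cx <- (sz + 1) / 2; cy <- (sz + 1) / 2
  radius <- 0.45 * sz
  mask <- outer((seq_len(sz) - cy)^2, (seq_len(sz) - cx)^2, "+") <= radius^2
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  side <- list(); truth <- list()
  for (id in names(r$stained_fraction)) {
    f <- r$stained_fraction[[id]]
    for (rep_i in seq_len(r$replicates)) {
      stained <- .paint_blobs(mask, f, r$blob_radius)
      img <- matrix(0, sz, sz)
      img[mask] <- stats::rnorm(sum(mask), r$bg_intensity, r$intensity_sd)
      img[stained] <- stats::rnorm(sum(stained), r$fg_intensity,
                                   r$intensity_sd)
      img <- pmin(pmax(img, 0), 1)
      img <- round(img * 255) / 255           # 8-bit quantisation
      fn <- sprintf("%s_%s_rep%d.png", id, r$channel, rep_i)
      png::writePNG(img, file.path(dir, fn))
      side[[length(side) + 1L]] <- data.frame(
        strain_id = id, channel = r$channel, replicate = rep_i,
        filename = fn, cx = cx, cy = cy, r = radius,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        strain_id = id, replicate = rep_i, target_fraction = f,
        true_fraction = sum(stained & mask) / sum(mask),
        stringsAsFactors = FALSE)
    }
  }
  list(sidecar = do.call(rbind, side), truth = do.call(rbind, truth),
       dir = dir)
}

#' Inbreeding coefficient after t generations
#'
#' Two recurrences are provided. \code{"selfing"}: sibling monokaryons
#' derived from one heterokaryon are gametes of a single genotype, so each
#' intercross generation is selfing-equivalent and F_t = 1 - (1/2)^t
#' (0.96875 at t = 5). \code{"fullsib"}: the diploid full-sib recurrence
#' F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4.
#'
#' @param t non-negative integer generation count.
#' @param scheme \code{"selfing"} (default) or \code{"fullsib"}.
#' @return inbreeding coefficient in [0, 1).
#' @examples
#' inbreedingCoefficient(5)  # 0.96875
#' @export
inbreedingCoefficient <- function(t, scheme = c("selfing", "fullsib")) {
  scheme <- match.arg(scheme)
  stopifnot(t >= 0, t == round(t))
  if (scheme == "selfing") return(1 - 0.5^t)
  f <- c(0, 0)  # F_{t-2}, F_{t-1}
  if (t == 0) return(0)
  for (i in seq_len(t)) {
    new <- (1 + 2 * f[2] + f[1]) / 4
    f <- c(f[2], new)
  }
  f[2]
}

#' Simulate a divergent truncation-selection breeding programme
#'
#' Each generation, offspring phenotypes are genetic mean + Normal genetic
#' deviation + Normal environmental noise; the top (direction "up") or
#' bottom ("down") \code{selected_fraction} is selected and the next
#' genetic mean moves by heritability times the selection differential.
#' Sibling monokaryons from one heterokaryon are treated as gametes of a
#' single genotype, so inbreeding follows the selfing-equivalent recurrence
#' F_t = 1 - (1/2)^t.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @param direction \code{"up"} or \code{"down"}.
#' @return data.frame with one row per generation (0 = base):
#'   \code{generation}, \code{mean_phenotype}, \code{genetic_mean},
#'   \code{f_selfing}, \code{f_fullsib}.
#' @export
simulateBreeding <- function(config = simulationConfig(), seed = 1L,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  b <- config$breeding
  stopifnot(b$generations >= 1L, b$selected_fraction > 0,
            b$selected_fraction <= 1)
  if (b$heritability < 0 || b$heritability > 1)
    stop("heritability must lie in [0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gmean <- b$base_mean
  rows <- list()
  for (t in 0:b$generations) {
    pheno <- gmean + stats::rnorm(b$population, 0, b$genetic_sd) +
      stats::rnorm(b$population, 0, b$env_sd)
    rows[[t + 1L]] <- data.frame(
      generation = t, mean_phenotype = mean(pheno), genetic_mean = gmean,
      f_selfing = inbreedingCoefficient(t, "selfing"),
      f_fullsib = inbreedingCoefficient(t, "fullsib"))
    n_sel <- max(1L, round(b$selected_fraction * b$population))
    sel <- if (direction == "up")
      sort(pheno, decreasing = TRUE)[seq_len(n_sel)]
    else sort(pheno)[seq_len(n_sel)]
    gmean <- gmean + b$heritability * (mean(sel) - mean(pheno))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Runs every generator under sub-seeds derived from \code{seed} and bundles
#' the tables, images and ground truth into a [SyntheticStudy-class].
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed; identical config + seed gives identical output.
#' @param image_dir directory for the plug images.
#' @param images logical; generate plug images (slowest stage).
#' @return A [SyntheticStudy-class].
#' @export
simulateStudy <- function(config = simulationConfig(), seed = 1L,
                          image_dir = tempfile("plugs"), images = TRUE) {
  seed <- as.integer(seed)
  panel <- StrainPanel(.design_panel())
  growth <- simulateGrowth(config, seed + 1L)
  cq <- simulateCqPanel(config, seed + 2L)
  prod <- simulateProduction(config, seed + 3L)
  ros <- if (images) simulatePlugImages(config, seed + 4L, dir = image_dir)
         else list(sidecar = data.frame(), truth = data.frame(),
                   dir = character(0))
  new("SyntheticStudy", panel = panel, markers = .marker_table(panel),
      growth = growth$data, cq = cq$data, production = prod$data,
      ros_sidecar = ros$sidecar, image_dir = ros$dir,
      truth = list(expression = cq$truth, growth_effects = growth$truth,
                   production = prod$truth, ros = ros$truth,
                   reference_genes = cq$reference_genes),
      seed = seed, config = unclass(config))
}

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy (seed", object@seed, ")\n")
  cat("  panel:     ", nrow(object@panel@strains), "strains\n")
  cat("  growth:    ", nrow(object@growth), "replicate measurements\n")
  cat("  cq:        ", nrow(object@cq), "Cq records\n")
  cat("  production:", nrow(object@production), "replicate measurements\n")
  cat("  plug images:", nrow(object@ros_sidecar), "\n")
})

#' Ground truth of a synthetic study
#'
#' @param study a [SyntheticStudy-class].
#' @param what one of \code{"expression"}, \code{"growth_effects"},
#'   \code{"production"}, \code{"ros"}, \code{"reference_genes"}.
#' @return the requested truth table.
#' @export
groundTruth <- function(study, what) {
  stopifnot(is(study, "SyntheticStudy"))
  if (!what %in% names(study@truth))
    stop("unknown ground-truth key: ", what, " (have: ",
         paste(names(study@truth), collapse = ", "), ")")
  study@truth[[what]]
}

#' Cross trios of a synthetic study
#'
#' @param study a [SyntheticStudy-class].
#' @return list of [CrossTrio-class] objects, one per hybrid.
#' @export
studyTrios <- function(study) {
  stopifnot(is(study, "SyntheticStudy"))
  tr <- .design_trios()
  lapply(seq_len(nrow(tr)), function(i)
    CrossTrio(tr$p1_id[i], tr$p2_id[i], tr$f1_id[i]))
}
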