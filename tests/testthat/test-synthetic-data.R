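test_that("identical config and seed give identical studies", {
  s1 <- simulateStudy(seed = 21, images = FALSE)
  s2 <- simulateStudy(seed = 21, images = FALSE)
  expect_identical(s1@growth, s2@growth)
  expect_identical(s1@cq, s2@cq)
  expect_identical(s1@production, s2@production)
  expect_identical(s1@truth$expression, s2@truth$expression)
  s3 <- simulateStudy(seed = 22, images = FALSE)
  expect_false(identical(s1@cq$cq, s3@cq$cq))
  # image generation is seeded too
  cfg <- simulationConfig()
  cfg$ros$stained_fraction <- c(s1 = 0.3); cfg$ros$replicates <- 1L
  d1 <- tempfile(); d2 <- tempfile()
  i1 <- simulatePlugImages(cfg, seed = 5, dir = d1)
  i2 <- simulatePlugImages(cfg, seed = 5, dir = d2)
  expect_identical(readPlugImage(file.path(d1, i1$sidecar$filename[1])),
                   readPlugImage(file.path(d2, i2$sidecar$filename[1])))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the generated panel matches the reciprocal-cross design", {
  study <- simulateStudy(seed = 1, images = FALSE)
  df <- strains(study@panel)
  expect_equal(nrow(df), 15L)
  expect_equal(sum(df$karyon == "monokaryon"), 5L)
  hyb <- df[df$karyon == "heterokaryon" & grepl("_T1_", df$strain_id), ]
  expect_equal(nrow(hyb), 8L)
  # reciprocal-mitotype pairs share the nuclear background
  nuc <- sub("_[nt]$", "", hyb$strain_id)
  expect_true(all(table(nuc) == 2L))
  for (b in unique(nuc)) {
    pair <- hyb$mitotype[nuc == b]
    expect_setequal(pair, c("n", "t"))
  }
})

test_that("growth simulation reproduces configured means and structure", {
  cfg <- simulationConfig()
  # all effects zero, no noise -> all values zero
  cfg$growth <- list(fast_mean = 0, slow_mean = 0, tester_mean = 0,
                     hybrid_fast_mean = 0, hybrid_slow_mean = 0,
                     env_offsets = c(`24C_malt` = 0), interactions = list(),
                     residual_sd = 0, replicates = 2L)
  g0 <- simulateGrowth(cfg, seed = 1)
  expect_true(all(g0$data$value == 0))
  # fast parental mean over 1000 replicates approaches 4.07
  cfg2 <- simulationConfig()
  cfg2$growth$replicates <- 1000L
  g <- simulateGrowth(cfg2, seed = 2)
  fast <- g$data$value[g$data$strain_id == "mNF418" &
                         g$data$environment == "24C_malt"]
  expect_equal(mean(fast), 4.07, tolerance = 0.05 / 4.07)
  # a strain x environment interaction is detectable
  tr <- g$truth
  expect_equal(
    tr$true_mean[tr$strain_id == "dNS423_T1_t" & tr$environment == "24C_malt"] -
      tr$true_mean[tr$strain_id == "dNS423_T1_n" & tr$environment == "24C_malt"],
    1.2)
})

test_that("noise-free Cq panels invert exactly through the pipeline", {
  cfg <- simulationConfig()
  cfg$expression$cq_noise_sd <- 0
  sim <- simulateCqPanel(cfg, seed = 1)
  et <- buildExpressionTable(sim$data, sim$reference_genes, "mNF418")
  trios <- unique(sim$truth[, c("p1_id", "p2_id", "f1_id")])
  mi <- miTable(expressionTrios(et, trios))
  key <- paste0(sim$truth$gene_id, ":", sim$truth$f1_id)
  idx <- match(mi$trait_id, key)
  expect_equal(mi$ratio, sim$truth$ratio[idx], tolerance = 1e-9)
  expect_equal(mi$mode, sim$truth$mode[idx])
})

test_that("production defaults have the published table shape and exact zero-noise means", {
  sim <- simulateProduction(seed = 3)
  expect_equal(length(unique(sim$data$strain_id)), 8L)
  expect_setequal(unique(sim$data$trait), c("earliness", "flushes", "yield"))
  expect_true(all(table(sim$data$strain_id, sim$data$trait) == 3L))
  expect_true(all(sim$data$value[sim$data$trait == "flushes"] >= 1))
  cfg <- simulationConfig()
  cfg$production$earliness_sd[] <- 0
  cfg$production$yield_sd[] <- 0
  cfg$production$flush_rate[] <- 0
  sim0 <- simulateProduction(cfg, seed = 1)
  d <- sim0$data
  expect_equal(d$value[d$strain_id == "dNS423_T1_n" & d$trait == "earliness"],
               rep(38, 3))
  expect_equal(d$value[d$strain_id == "dNF418_T1_n" & d$trait == "yield"],
               rep(299.2, 3))
  expect_equal(d$value[d$trait == "flushes"], rep(1, 24))
  # large-replicate means approach the configured values
  simN <- simulateProduction(seed = 4, replicates = 1000L)
  y <- simN$data$value[simN$data$strain_id == "dNF418_T1_n" &
                         simN$data$trait == "yield"]
  expect_lt(abs(mean(y) - 299.2), 2 * 77.2 / sqrt(1000))
})

test_that("plug generation honours the extreme stained fractions", {
  cfg <- simulationConfig()
  cfg$ros$stained_fraction <- c(none = 0, full = 1)
  cfg$ros$replicates <- 1L
  dir <- tempfile()
  sim <- simulatePlugImages(cfg, seed = 2, dir = dir)
  expect_equal(sim$truth$true_fraction[sim$truth$strain_id == "none"], 0)
  expect_equal(sim$truth$true_fraction[sim$truth$strain_id == "full"], 1)
  img <- readPlugImage(file.path(dir, "full_DHE_rep1.png"))
  mask <- segmentPlug(img, disc = list(cx = sim$sidecar$cx[1],
                                       cy = sim$sidecar$cy[1],
                                       r = sim$sidecar$r[1]))
  expect_equal(percentStainedArea(img, mask, "fixed",
                                  threshold = 0.5)$percent_area, 100)
  unlink(dir, recursive = TRUE)
})

test_that("inbreeding recurrences follow their closed forms", {
  expect_equal(inbreedingCoefficient(5), 0.96875)  # 1 - 1/32
  expect_equal(inbreedingCoefficient(0), 0)
  t <- 0:12
  f <- vapply(t, inbreedingCoefficient, numeric(1))
  expect_true(all(diff(f) > 0))       # strictly increasing
  expect_lt(abs(f[13] - 1), 3e-4)     # converges to 1
  # full-sib recurrence: slower, also monotone to 1
  ffs <- vapply(t, inbreedingCoefficient, numeric(1), scheme = "fullsib")
  expect_equal(ffs[2], 0.25)
  expect_equal(ffs[3], 0.375)
  expect_true(all(diff(ffs) > 0))
  expect_true(all(ffs[-1] < f[-1]))
})

test_that("truncation selection responds according to heritability", {
  cfg <- simulationConfig()
  cfg$breeding$heritability <- 0
  b0 <- simulateBreeding(cfg, seed = 5)
  expect_true(all(b0$genetic_mean == b0$genetic_mean[1]))
  cfg$breeding$heritability <- 0.5
  up <- vapply(1:20, function(s) {
    tr <- simulateBreeding(cfg, seed = s, direction = "up")
    tr$genetic_mean[nrow(tr)] - tr$genetic_mean[1]
  }, numeric(1))
  expect_true(all(up > 0))
  dn <- simulateBreeding(cfg, seed = 1, direction = "down")
  expect_lt(dn$genetic_mean[nrow(dn)], dn$genetic_mean[1])
  expect_error({
    cfg$breeding$heritability <- 1.5
    simulateBreeding(cfg, seed = 1)
  }, "heritability")
})

test_that("every analysis row joins exactly one ground-truth row", {
  study <- simulateStudy(seed = 31, images = FALSE)
  et <- buildExpressionTable(study@cq, study@truth$reference_genes,
                             "mNF418")
  trios <- unique(study@truth$expression[, c("p1_id", "p2_id", "f1_id")])
  mi <- miTable(expressionTrios(et, trios))
  truth <- groundTruth(study, "expression")
  key <- paste0(truth$gene_id, ":", truth$f1_id)
  expect_equal(sort(mi$trait_id), sort(key))
  expect_false(anyDuplicated(key) > 0)
  expect_error(groundTruth(study, "nope"), "unknown ground-truth key")
})
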