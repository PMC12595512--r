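test_that("replicate Cq aggregation reports mean, sample SD and n", {
  one <- aggregateCq(data.frame(strain_id = "s", gene_id = "g",
                                replicate = 1L, cq = 20))
  expect_equal(one$cq_mean, 20)
  expect_equal(one$n, 1L)
  expect_true(is.na(one$cq_sd))  # undefined, not zero
  two <- aggregateCq(data.frame(strain_id = "s", gene_id = "g",
                                replicate = 1:2, cq = c(19, 21)))
  expect_equal(two$cq_mean, 20)
  expect_equal(two$cq_sd, sqrt(2), tolerance = 1e-12)
  expect_equal(two$n, 2L)
  expect_error(aggregateCq(data.frame(strain_id = character(0),
                                      gene_id = character(0),
                                      replicate = integer(0),
                                      cq = numeric(0))), "missing data")
})

test_that("aggregation agrees with a streaming-mean oracle on 100 replicates", {
  set.seed(71)
  cq <- rnorm(100, 20, 0.5)
  # independent Welford streaming oracle
  m <- 0; s <- 0
  for (i in seq_along(cq)) {
    d <- cq[i] - m
    m <- m + d / i
    s <- s + d * (cq[i] - m)
  }
  agg <- aggregateCq(data.frame(strain_id = "s", gene_id = "g",
                                replicate = seq_along(cq), cq = cq))
  expect_equal(agg$cq_mean, m, tolerance = 1e-12)
  expect_equal(agg$cq_sd, sqrt(s / (length(cq) - 1)), tolerance = 1e-12)
  expect_lt(abs(agg$cq_mean - 20), 0.15)
})

test_that("delta-Ct equals geometric-mean normalisation in linear space", {
  expect_equal(deltaCq(20, c(18, 19, 20)), 1.0)
  expect_equal(deltaCq(19, c(19, 19, 19)), 0.0)
  expect_error(deltaCq(20, c(18, 19)), "exactly three")
  # oracle: quantities 2^-Cq, normalise by geometric mean of references
  set.seed(5)
  for (i in 1:20) {
    tcq <- runif(1, 15, 30); refs <- runif(3, 15, 30)
    q <- 2^(-tcq); qref <- 2^(-refs)
    oracle <- -log2(q / exp(mean(log(qref))))
    expect_equal(deltaCq(tcq, refs), oracle, tolerance = 1e-10)
  }
})

test_that("2^-ddCt fold changes follow the exponential form", {
  expect_equal(ddcqFoldChange(3, 3)$fold_change, 1.0)
  expect_equal(ddcqFoldChange(3, 4)$fold_change, 2.0)  # one-cycle doubling
  expect_equal(ddcqFoldChange(log2(10), 0)$fold_change, 0.1,
               tolerance = 1e-12)
  expect_equal(ddcqFoldChange(3.3219, 0)$fold_change, 2^-3.3219)
  fc <- ddcqFoldChange(5, 3)
  expect_equal(fc$fold_change, 2^fc$log2_rel_expr)
})

test_that("expression table honours calibrator self-consistency and Cq ratios", {
  refs <- c("r1", "r2", "r3")
  mk_cq <- function(strain, targets) {
    do.call(rbind, c(
      lapply(names(targets), function(g) data.frame(
        strain_id = strain, gene_id = g, replicate = 1:3,
        cq = targets[[g]])),
      lapply(refs, function(r) data.frame(
        strain_id = strain, gene_id = r, replicate = 1:3, cq = 20))))
  }
  # single strain as its own calibrator: all fold changes 1
  cq <- mk_cq("s1", list(gA = 24, gB = 27))
  et <- buildExpressionTable(cq, refs, "s1")
  expect_equal(et$fold_change, c(1, 1))
  # two strains, target Cq differing by exactly 2 cycles -> ratio 4
  cq2 <- rbind(mk_cq("s1", list(gA = 24)), mk_cq("s2", list(gA = 22)))
  et2 <- buildExpressionTable(cq2, refs, "s1")
  expect_equal(et2$fold_change[et2$strain_id == "s2"] /
                 et2$fold_change[et2$strain_id == "s1"], 4)
  # calibrator must carry every gene
  cq3 <- rbind(mk_cq("s1", list(gA = 24)), mk_cq("s2", list(gA = 22, gB = 25)))
  expect_error(buildExpressionTable(cq3, refs, "s1"),
               "incomplete calibrator")
})

test_that("adding a constant to every Cq of a sample leaves dCt unchanged", {
  study <- simulateCqPanel(seed = 3)
  refs <- study$reference_genes
  et0 <- buildExpressionTable(study$data, refs)
  shifted <- study$data
  one <- shifted$strain_id == shifted$strain_id[1]
  shifted$cq[one] <- shifted$cq[one] + 2.5
  et1 <- buildExpressionTable(shifted, refs)
  expect_equal(et1$delta_cq_mean, et0$delta_cq_mean, tolerance = 1e-12)
})

test_that("lower target Cq gives strictly higher fold change", {
  refs <- c("r1", "r2", "r3")
  base <- do.call(rbind, lapply(refs, function(r) data.frame(
    strain_id = "cal", gene_id = r, replicate = 1:2, cq = 20)))
  base <- rbind(base, data.frame(strain_id = "cal", gene_id = "gA",
                                 replicate = 1:2, cq = 25))
  fold_at <- function(cq_target) {
    s <- do.call(rbind, lapply(refs, function(r) data.frame(
      strain_id = "s", gene_id = r, replicate = 1:2, cq = 20)))
    s <- rbind(s, data.frame(strain_id = "s", gene_id = "gA",
                             replicate = 1:2, cq = cq_target))
    et <- buildExpressionTable(rbind(base, s), refs, "cal")
    et$fold_change[et$strain_id == "s"]
  }
  fc <- vapply(c(28, 26, 24, 22, 20), fold_at, numeric(1))
  expect_true(all(diff(fc) > 0))
})

test_that("synthetic expression is recovered within 3 SE for >= 95% of entries", {
  # 6 replicates keep the per-entry SE estimate stable (with 3, the
  # 2-df SD estimate makes the nominal 3 SE band noticeably liberal).
  # Entries of one panel share the calibrator's replicate error per gene,
  # so coverage is pooled over several independent panels.
  cfg <- simulationConfig()
  cfg$expression$replicates <- 6L
  covered <- unlist(lapply(17:21, function(seed) {
    study <- simulateCqPanel(cfg, seed = seed)
    et <- buildExpressionTable(study$data, study$reference_genes,
                               calibrator_id = "mNF418")
    truth <- study$truth
    # true log2 level of each strain relative to the calibrator strain
    lvl <- new.env()
    for (i in seq_len(nrow(truth))) {
      assign(paste(truth$p1_id[i], truth$gene_id[i]), truth$p1_log2[i], lvl)
      assign(paste(truth$p2_id[i], truth$gene_id[i]), truth$p2_log2[i], lvl)
      assign(paste(truth$f1_id[i], truth$gene_id[i]), truth$f1_log2[i], lvl)
    }
    cal <- vapply(unique(et$gene_id), function(g)
      get(paste("mNF418", g), lvl), numeric(1))
    true_rel <- vapply(seq_len(nrow(et)), function(i)
      get(paste(et$strain_id[i], et$gene_id[i]), lvl) - cal[[et$gene_id[i]]],
      numeric(1))
    se <- et$ddcq_sd / sqrt(et$n)
    abs(et$log2_rel_expr - true_rel) <= 3 * se
  }))
  expect_gte(mean(covered), 0.95)
})
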