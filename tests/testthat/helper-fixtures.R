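# Shared fixtures, all built in code.

# Minimal three-strain panel: two monokaryon parents with different
# mitotypes and one hybrid.
tiny_panel <- function(f1_mito = "n") {
  StrainPanel(data.frame(
    strain_id = c("mA", "mB", "dAB"),
    karyon = c("monokaryon", "monokaryon", "heterokaryon"),
    generation = c("F4", "F1", "F1"),
    growth_class = c("fast", "fast", "fast"),
    mitotype = c("n", "t", f1_mito),
    stringsAsFactors = FALSE))
}

# The published production summary table (8 hybrids, mean +- SD, n = 3).
earliness_summaries <- function() {
  data.frame(
    label = c("dNF418_T1_n", "dNF418_T1_t", "dNF419_T1_n", "dNF419_T1_t",
              "dNS423_T1_n", "dNS423_T1_t", "dNS426_T1_n", "dNS426_T1_t"),
    mean = c(13, 13, 14, 14, 38, 26, 35, 36),
    sd = c(2, 1, 3, 0, 3, 1, 1, 2),
    n = 3L, stringsAsFactors = FALSE)
}

yield_summaries <- function() {
  data.frame(
    label = c("dNF418_T1_n", "dNF418_T1_t", "dNF419_T1_n", "dNF419_T1_t",
              "dNS423_T1_n", "dNS423_T1_t", "dNS426_T1_n", "dNS426_T1_t"),
    mean = c(299.2, 256.0, 199.7, 211.8, 29.2, 148.2, 39.4, 35.4),
    sd = c(77.2, 41.5, 15.1, 36.7, 5.0, 11.6, 12.4, 13.0),
    n = 3L, stringsAsFactors = FALSE)
}

# A trio phenotype built directly from numbers.
mk_trio <- function(p1, p2, f1, sd = 0.2, n = 3L, trait = "trait") {
  trioPhenotype(trait,
                p1 = list(mean = p1, sd = sd, n = n),
                p2 = list(mean = p2, sd = sd, n = n),
                f1 = list(mean = f1, sd = sd, n = n))
}

# Raw replicate data for group-stat tests.
mk_groups <- function(means, n = 5L, sd = 1, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(means), function(i) data.frame(
    label = paste0("g", i),
    value = rnorm(n, means[i], sd), stringsAsFactors = FALSE)))
}
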