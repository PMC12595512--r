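#' @import methods
NULL

KARYON_LEVELS    <- c("monokaryon", "heterokaryon")
GROWTH_LEVELS    <- c("fast", "slow", "unknown")
MITOTYPE_LEVELS  <- c("n", "t", "unknown")
MARKER_LOCI      <- c("nuclear_chrVII", "mito_cox1")

#' Panel of strains used in a mitonuclear cross design
#'
#' A validated container for the strain panel of a mitonuclear hybrid study:
#' parental monokaryons, tester strains and reciprocal-mitotype heterokaryotic
#' hybrids. One row per strain with its karyon type, generation label, growth
#' class and mitochondrial haplotype.
#'
#' @slot strains data.frame with columns \code{strain_id}, \code{karyon}
#'   (\code{monokaryon}/\code{heterokaryon}), \code{generation},
#'   \code{growth_class} (\code{fast}/\code{slow}/\code{unknown}) and
#'   \code{mitotype} (\code{n}/\code{t}/\code{unknown}).
#'
#' @seealso [StrainPanel()], [readStrainPanel()], [validateCrossTrio()]
#' @export
setClass("StrainPanel", representation(strains = "data.frame"))

setValidity("StrainPanel", function(object) {
  df <- object@strains
  req <- c("strain_id", "karyon", "generation", "growth_class", "mitotype")
  if (!all(req %in% names(df)))
    return(paste("missing columns:", paste(setdiff(req, names(df)), collapse = ", ")))
  if (anyDuplicated(df$strain_id))
    return("strain_id values must be unique within a panel")
  if (!all(df$karyon %in% KARYON_LEVELS))
    return("karyon must be 'monokaryon' or 'heterokaryon'")
  if (!all(df$growth_class %in% GROWTH_LEVELS))
    return("growth_class must be 'fast', 'slow' or 'unknown'")
  if (!all(df$mitotype %in% MITOTYPE_LEVELS))
    return("mitotype must be 'n', 't' or 'unknown'")
  TRUE
})

#' A parent-parent-hybrid cross trio
#'
#' Identifies one cross: two parental strains and the resulting F1
#' heterokaryon, with an optional free-text trait scope.
#'
#' @slot p1_id,p2_id,f1_id strain identifiers resolving in a [StrainPanel].
#' @slot scope free-text scope of the traits the trio is analysed for.
#' @export
setClass("CrossTrio", representation(
  p1_id = "character", p2_id = "character", f1_id = "character",
  scope = "character"))

setValidity("CrossTrio", function(object) {
  if (length(object@p1_id) != 1L || length(object@p2_id) != 1L ||
      length(object@f1_id) != 1L)
    return("p1_id, p2_id and f1_id must each be a single strain id")
  if (object@p1_id == object@p2_id)
    return("the two parents of a trio must differ")
  TRUE
})

#' Seeded synthetic study with ground truth
#'
#' The complete set of input tables and images a mitonuclear-hybrid analysis
#' consumes, generated under a fixed seed, together with the generating
#' parameters ("ground truth") needed for recovery tests: true inheritance
#' modes and dominance ratios per trio and gene, true heterosis, true strain
#' and environment effects, and true stained fractions of the plug images.
#'
#' @slot panel [StrainPanel] of the simulated design.
#' @slot markers data.frame of marker fragment observations
#'   (\code{strain_id}, \code{locus}, \code{fragment_kb}).
#' @slot growth data.frame of growth-rate replicates
#'   (\code{strain_id}, \code{environment}, \code{replicate}, \code{value}).
#' @slot cq data.frame of qPCR cycle values
#'   (\code{strain_id}, \code{gene_id}, \code{replicate}, \code{cq}).
#' @slot production data.frame of production-trait replicates
#'   (\code{strain_id}, \code{trait}, \code{replicate}, \code{value}).
#' @slot ros_sidecar data.frame mapping plug images to strains
#'   (\code{strain_id}, \code{channel}, \code{replicate}, \code{filename},
#'   \code{cx}, \code{cy}, \code{r}).
#' @slot image_dir directory holding the generated plug images.
#' @slot truth named list of ground-truth tables (\code{expression},
#'   \code{growth_effects}, \code{production}, \code{ros}).
#' @slot seed integer seed the study was generated under.
#' @slot config the [simulationConfig()] list used.
#' @export
setClass("SyntheticStudy", representation(
  panel = "StrainPanel", markers = "data.frame", growth = "data.frame",
  cq = "data.frame", production = "data.frame", ros_sidecar = "data.frame",
  image_dir = "character", truth = "list", seed = "integer", config = "list"))

setValidity("SyntheticStudy", function(object) {
  if (length(object@seed) != 1L) return("seed must be a single integer")
  need <- c("expression", "growth_effects", "production")
  if (!all(need %in% names(object@truth)))
    return(paste("truth must contain:", paste(need, collapse = ", ")))
  TRUE
})
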