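# Strain-panel representation, marker-based genotype and mitotype calling,
# and uniparental mitochondrial inheritance checks.

# Reference fragment sizes (kb) observed on the gel for each marker system.
# Nuclear chromosome-VII amplicon: 0.4 kb in fast-growing bred lines, 3.6 kb
# in slow-growing ones, 0.3 kb in the tester line. Mitochondrial cox1
# amplicon: 1.9 kb for the (n) haplotype, 0.2 kb for (t).
NUCLEAR_REF_KB <- c(fast_line_allele = 0.4, slow_line_allele = 3.6,
                    tester_allele = 0.3)
MITO_REF_KB    <- c(n = 1.9, t = 0.2)

#' Construct a strain panel
#'
#' @param strains data.frame with columns \code{strain_id}, \code{karyon},
#'   \code{generation}, \code{growth_class}, \code{mitotype}.
#' @return A [StrainPanel-class] object.
#' @examples
#' StrainPanel(data.frame(strain_id = c("mA", "mB", "dAB"),
#'   karyon = c("monokaryon", "monokaryon", "heterokaryon"),
#'   generation = c("F4", "F1", "F1"),
#'   growth_class = c("fast", "fast", "fast"),
#'   mitotype = c("n", "t", "n")))
#' @export
StrainPanel <- function(strains) {
  strains <- as.data.frame(strains, stringsAsFactors = FALSE)
  for (col in c("strain_id", "karyon", "generation", "growth_class", "mitotype"))
    if (col %in% names(strains)) strains[[col]] <- as.character(strains[[col]])
  new("StrainPanel", strains = strains)
}

#' Read a strain panel from CSV
#'
#' Expects the header \code{strain_id,karyon,generation,growth_class,mitotype}.
#'
#' @param path path to the panel CSV.
#' @return A [StrainPanel-class].
#' @export
readStrainPanel <- function(path) {
  StrainPanel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @describeIn StrainPanel-class strain table accessor
#' @param x a \code{StrainPanel}.
#' @export
strains <- function(x) {
  stopifnot(is(x, "StrainPanel"))
  x@strains
}

setMethod("show", "StrainPanel", function(object) {
  df <- object@strains
  cat("StrainPanel with", nrow(df), "strains:",
      sum(df$karyon == "monokaryon"), "monokaryons,",
      sum(df$karyon == "heterokaryon"), "heterokaryons\n")
  cat("  mitotypes:", paste(sprintf("%s=%d", names(table(df$mitotype)),
                                    table(df$mitotype)), collapse = " "), "\n")
})

#' Construct a cross trio
#'
#' @param p1_id,p2_id,f1_id strain identifiers of the two parents and the F1
#'   hybrid.
#' @param scope optional free-text trait scope.
#' @return A [CrossTrio-class].
#' @export
CrossTrio <- function(p1_id, p2_id, f1_id, scope = "") {
  new("CrossTrio", p1_id = as.character(p1_id), p2_id = as.character(p2_id),
      f1_id = as.character(f1_id), scope = as.character(scope))
}

setMethod("show", "CrossTrio", function(object) {
  cat(sprintf("CrossTrio: %s x %s -> %s\n",
              object@p1_id, object@p2_id, object@f1_id))
})

.match_fragment <- function(fragment_kb, refs, tolerance_frac) {
  hits <- names(refs)[abs(fragment_kb - refs) <= tolerance_frac * refs]
  hits
}

#' Call a nuclear allele from a marker fragment size
#'
#' Matches an observed chromosome-VII amplicon length against the three
#' reference band sizes (0.4 kb fast-line, 3.6 kb slow-line, 0.3 kb tester)
#' within a relative tolerance. Ambiguity between reference bands is an
#' error, never a silent nearest match: a genotype miscall corrupts every
#' downstream trio built on it.
#'
#' @param fragment_kb observed fragment size in kilobases (> 0).
#' @param tolerance_frac relative tolerance, in (0, 0.5). The default 0.15
#'   reflects typical gel-sizing error while keeping the 0.3 and 0.4 kb bands
#'   separable (0.4 * 0.15 = 0.06 < 0.1).
#' @return One of \code{"fast_line_allele"}, \code{"slow_line_allele"},
#'   \code{"tester_allele"}.
#' @examples
#' callNuclearAllele(0.4)  # fast_line_allele
#' callNuclearAllele(3.5)  # slow_line_allele
#' @export
callNuclearAllele <- function(fragment_kb, tolerance_frac = 0.15) {
  stopifnot(is.numeric(fragment_kb), length(fragment_kb) == 1L, fragment_kb > 0,
            tolerance_frac > 0, tolerance_frac < 0.5)
  hits <- .match_fragment(fragment_kb, NUCLEAR_REF_KB, tolerance_frac)
  if (length(hits) == 0L)
    stop("unrecognized fragment: ", fragment_kb,
         " kb matches no nuclear reference band within tolerance")
  if (length(hits) > 1L)
    stop("ambiguous fragment: ", fragment_kb, " kb matches bands ",
         paste(hits, collapse = " and "), " within tolerance")
  hits
}

#' Call a mitotype from a cox1 fragment size
#'
#' The mitochondrial cox1 amplicon is 1.9 kb for the (n) haplotype and
#' 0.2 kb for the (t) haplotype.
#'
#' @inheritParams callNuclearAllele
#' @return \code{"n"} or \code{"t"}.
#' @examples
#' callMitotype(1.9)  # "n"
#' callMitotype(0.2)  # "t"
#' @export
callMitotype <- function(fragment_kb, tolerance_frac = 0.15) {
  stopifnot(is.numeric(fragment_kb), length(fragment_kb) == 1L, fragment_kb > 0,
            tolerance_frac > 0, tolerance_frac < 0.5)
  hits <- .match_fragment(fragment_kb, MITO_REF_KB, tolerance_frac)
  if (length(hits) == 0L)
    stop("unrecognized fragment: ", fragment_kb,
         " kb matches no cox1 reference band within tolerance")
  if (length(hits) > 1L)
    stop("ambiguous fragment: ", fragment_kb, " kb matches both cox1 bands")
  hits
}

#' Validate uniparental mitochondrial inheritance of a cross trio
#'
#' Mitochondria are inherited uniparentally in these crosses: a hybrid must
#' carry the mitochondrial haplotype of exactly one of its parents. The trio
#' is valid iff the F1 mitotype equals at least one parental mitotype; the
#' transmitting parent is named when the parents differ.
#'
#' @param trio a [CrossTrio-class].
#' @param panel a [StrainPanel-class] in which all three ids resolve.
#' @return A list with elements \code{valid} (logical),
#'   \code{transmitting_parent} (strain id, \code{NA} when ambiguous or
#'   invalid), \code{ambiguous} (logical; both parents share the F1 mitotype)
#'   and \code{message}.
#' @export
validateCrossTrio <- function(trio, panel) {
  stopifnot(is(trio, "CrossTrio"), is(panel, "StrainPanel"))
  df <- panel@strains
  ids <- c(trio@p1_id, trio@p2_id, trio@f1_id)
  missing <- setdiff(ids, df$strain_id)
  if (length(missing))
    stop("strain id(s) not in panel: ", paste(missing, collapse = ", "))
  row <- function(id) df[df$strain_id == id, , drop = FALSE]
  f1 <- row(trio@f1_id)
  if (f1$karyon != "heterokaryon")
    stop("F1 strain ", trio@f1_id, " is not a heterokaryon")
  mt <- c(p1 = row(trio@p1_id)$mitotype, p2 = row(trio@p2_id)$mitotype,
          f1 = f1$mitotype)
  if (mt[["f1"]] == "unknown")
    stop("incomplete data: F1 mitotype of ", trio@f1_id, " is unknown")
  match_p1 <- mt[["f1"]] == mt[["p1"]]
  match_p2 <- mt[["f1"]] == mt[["p2"]]
  if (!match_p1 && !match_p2) {
    return(list(valid = FALSE, transmitting_parent = NA_character_,
                ambiguous = FALSE,
                message = sprintf(
                  "F1 %s mitotype (%s) matches neither parent (%s, %s): uniparental inheritance violated",
                  trio@f1_id, mt[["f1"]], mt[["p1"]], mt[["p2"]])))
  }
  if (match_p1 && match_p2) {
    return(list(valid = TRUE, transmitting_parent = NA_character_,
                ambiguous = TRUE,
                message = "both parents share the F1 mitotype; transmitting parent ambiguous"))
  }
  parent <- if (match_p1) trio@p1_id else trio@p2_id
  list(valid = TRUE, transmitting_parent = parent, ambiguous = FALSE,
       message = sprintf("mitotype %s transmitted by %s", mt[["f1"]], parent))
}

#' Parse a strain name in the d(NS423 x T1, t) convention
#'
#' Convenience helper for names of the form \code{d(<P1> x <T>, <mitotype>)}
#' or \code{m<NAME> (<mitotype>)}. Explicit panel fields always win over
#' parsed names; this helper only bootstraps panels from legacy name lists.
#'
#' @param name strain name string; the multiplication sign may be \code{x}
#'   or the Unicode times sign.
#' @return A list with \code{karyon}, \code{p1}, \code{tester},
#'   \code{mitotype} (fields \code{NA} where not encoded in the name).
#' @export
parseStrainName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  nm <- gsub("×", "x", name)
  m <- regmatches(nm, regexec(
    "^d\\(\\s*([^x,]+?)\\s*x\\s*([^,]+?)\\s*,\\s*([nt])\\s*\\)$", nm))[[1]]
  if (length(m) == 4L)
    return(list(karyon = "heterokaryon", p1 = paste0("m", m[2]),
                tester = paste0("m", m[3]), mitotype = m[4]))
  m <- regmatches(nm, regexec("^m(\\S+)\\s*\\(([nt])\\)$", nm))[[1]]
  if (length(m) == 3L)
    return(list(karyon = "monokaryon", p1 = NA_character_,
                tester = NA_character_, mitotype = m[3]))
  list(karyon = NA_character_, p1 = NA_character_, tester = NA_character_,
       mitotype = NA_character_)
}

#' Read marker fragment observations from CSV
#'
#' Expects the header \code{strain_id,locus,fragment_kb} with locus one of
#' \code{nuclear_chrVII} or \code{mito_cox1}.
#'
#' @param path path to the marker CSV.
#' @return data.frame of marker observations.
#' @export
readMarkerTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("strain_id", "locus", "fragment_kb") %in% names(df)))
  if (!all(df$locus %in% MARKER_LOCI))
    stop("unknown locus value(s): ",
         paste(setdiff(df$locus, MARKER_LOCI), collapse = ", "))
  if (any(df$fragment_kb <= 0)) stop("fragment_kb must be positive")
  df
}
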