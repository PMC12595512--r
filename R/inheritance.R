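# Per-trio inheritance-mode classification from the dominance ratio d/a,
# mid-parent heterosis, transgressive-expression calls and parametric
# bootstrap uncertainty.
#
# Conventions. The mid-parent value m = (P1 + P2)/2; the additive deviation
# a = |P1 - P2|/2 is taken non-negative (half the parental span, oriented to
# the higher-value parent), which makes the sign conventions of the d/a bins
# well defined; the dominance deviation d = F1 - m. A positive d/a means the
# hybrid deviates toward the higher-value parent.

INHERITANCE_MODES <- c(
  "codominance", "partial_dominance_high", "partial_dominance_low",
  "complete_dominance_high", "complete_dominance_low",
  "overdominance", "underdominance", "undefined_parents_equal")

.member <- function(mean, sd = NA_real_, n = 1L) {
  stopifnot(is.finite(mean), n >= 1L)
  list(mean = mean, sd = sd, n = as.integer(n))
}

#' Assemble a trio phenotype
#'
#' Bundles the replicate summaries (mean, SD, n) of the two parents and the
#' F1 hybrid for one trait. Units are free: log2 relative expression,
#' mm/day growth, grams yield.
#'
#' @param trait_id trait label.
#' @param p1,p2,f1 each a list/vector with elements \code{mean}, \code{sd},
#'   \code{n}; \code{sd} may be \code{NA} when n = 1.
#' @return A \code{trioPhenotype} list (class \code{"TrioPhenotype"}).
#' @examples
#' trioPhenotype("growth", p1 = c(mean = 4.07, sd = 0.2, n = 3),
#'               p2 = c(mean = 1.12, sd = 0.2, n = 3),
#'               f1 = c(mean = 4.5, sd = 0.2, n = 3))
#' @export
trioPhenotype <- function(trait_id, p1, p2, f1) {
  as_m <- function(x) {
    x <- as.list(x)
    .member(as.numeric(x$mean),
            if (is.null(x$sd)) NA_real_ else as.numeric(x$sd),
            if (is.null(x$n)) 1L else as.integer(x$n))
  }
  p1 <- as_m(p1); p2 <- as_m(p2); f1 <- as_m(f1)
  for (m in list(p1, p2, f1))
    if (!is.na(m$sd) && m$sd < 0) stop("member SD must be >= 0")
  structure(list(trait_id = as.character(trait_id), p1 = p1, p2 = p2, f1 = f1),
            class = "TrioPhenotype")
}

#' Mid-parent, additive and dominance deviations of a trio
#'
#' @param trio a [trioPhenotype()].
#' @return list with \code{m} (mid-parent value), \code{a} (additive
#'   deviation, non-negative) and \code{d} (dominance deviation F1 - m), in
#'   trait units.
#' @examples
#' trioDeviations(trioPhenotype("t", c(mean = 4), c(mean = 2), c(mean = 5)))
#' @export
trioDeviations <- function(trio) {
  stopifnot(inherits(trio, "TrioPhenotype"))
  m <- (trio$p1$mean + trio$p2$mean) / 2
  a <- abs(trio$p1$mean - trio$p2$mean) / 2
  d <- trio$f1$mean - m
  list(m = m, a = a, d = d)
}

#' Dominance ratio d/a
#'
#' Returns d/a when the additive deviation is estimable, with positive sign
#' meaning deviation toward the higher-value parent. When a falls below
#' \code{a_min} (near-identical parents) the ratio is undefined (\code{NA})
#' rather than numerically exploding.
#'
#' @param d dominance deviation (trait units).
#' @param a additive deviation, >= 0 (trait units).
#' @param a_min smallest additive deviation considered estimable; typically
#'   the pooled standard error of the parental difference.
#' @return d/a, or \code{NA} when a < a_min.
#' @export
dominanceRatio <- function(d, a, a_min = 0) {
  stopifnot(is.finite(d), is.finite(a), a >= 0, a_min >= 0)
  if (a < a_min || a == 0) return(NA_real_)
  d / a
}

#' Classify the mode of inheritance from the dominance ratio
#'
#' Bins: d/a = 0 codominance; 0 < d/a < 1 partial dominance of the
#' higher-value parent (mirror for negative); |d/a| = 1 complete dominance
#' of the higher- or lower-value parent; |d/a| > 1 overdominance or
#' underdominance of the hybrid. With continuous data the point bins
#' (0 and +-1) are unreachable exactly, so a half-width \code{epsilon} is
#' applied around them.
#'
#' @param ratio dominance ratio d/a, possibly \code{NA}.
#' @param d dominance deviation; used to orient over/underdominance when
#'   the ratio is undefined (equal parents).
#' @param epsilon half-width of the codominance and complete-dominance bins,
#'   in d/a units; in [0, 0.5).
#' @param d_noise absolute noise band on d below which an undefined ratio is
#'   reported as \code{undefined_parents_equal}.
#' @return One of the mode labels in \code{INHERITANCE_MODES}.
#' @examples
#' classifyMode(0)     # codominance
#' classifyMode(1.8)   # overdominance
#' classifyMode(-1)    # complete_dominance_low
#' @export
classifyMode <- function(ratio, d = 0, epsilon = 0.1, d_noise = 0) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  if (is.na(ratio)) {
    if (abs(d) <= d_noise) return("undefined_parents_equal")
    return(if (d > 0) "overdominance" else "underdominance")
  }
  if (abs(ratio) <= epsilon) return("codominance")
  if (abs(ratio - 1) <= epsilon) return("complete_dominance_high")
  if (abs(ratio + 1) <= epsilon) return("complete_dominance_low")
  if (ratio > 1 + epsilon) return("overdominance")
  if (ratio < -1 - epsilon) return("underdominance")
  if (ratio > 0) "partial_dominance_high" else "partial_dominance_low"
}

#' Mid-parent heterosis in percent
#'
#' MPH = 100 * (F1 - m) / m: the percent deviation of the hybrid from the
#' mid-parent value (100 means the hybrid doubles the mid-parent).
#'
#' @param f1_mean F1 hybrid mean (trait units).
#' @param m mid-parent value (trait units, non-zero).
#' @return MPH in percent.
#' @examples
#' midParentHeterosis(3, 2)  # 50
#' @export
midParentHeterosis <- function(f1_mean, m) {
  stopifnot(is.finite(f1_mean), is.finite(m))
  if (m == 0) stop("undefined MPH: mid-parent value is zero")
  100 * (f1_mean - m) / m
}

# Default a_min: pooled standard error of the parental difference, halved to
# the a scale. NA SDs (single replicates) contribute zero.
.default_a_min <- function(trio) {
  v1 <- if (is.na(trio$p1$sd)) 0 else trio$p1$sd^2 / trio$p1$n
  v2 <- if (is.na(trio$p2$sd)) 0 else trio$p2$sd^2 / trio$p2$n
  sqrt(v1 + v2) / 2
}

#' Welch two-sample test from summary statistics
#'
#' Unequal-variance t test computed from (mean, sd, n) pairs; used for
#' transgressive-expression calls where only replicate summaries exist.
#'
#' @param m1,s1,n1 mean, SD and replicate count of the first sample.
#' @param m2,s2,n2 mean, SD and replicate count of the second sample.
#' @return list with \code{t}, \code{df} (Welch-Satterthwaite) and
#'   \code{p_value} (two-sided).
#' @export
welchFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, is.finite(s1), is.finite(s2))
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    return(list(t = t, df = n1 + n2 - 2,
                p_value = if (m1 == m2) 1 else 0))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Call transgressive expression of a hybrid
#'
#' TRUE iff the F1 mean lies strictly outside the parental range AND Welch
#' tests against both parents reject at \code{alpha} in the same direction.
#' The parental boundary itself is not transgressive.
#'
#' @param trio a [trioPhenotype()] with n >= 2 and defined SD for every
#'   member.
#' @param alpha significance level of the two Welch tests (default 0.05).
#' @return list with \code{transgressive} (logical), \code{direction}
#'   (\code{"above"}, \code{"below"} or \code{NA}) and the two Welch p
#'   values.
#' @export
callTransgressive <- function(trio, alpha = 0.05) {
  stopifnot(inherits(trio, "TrioPhenotype"))
  for (m in list(trio$p1, trio$p2, trio$f1))
    if (m$n < 2 || is.na(m$sd))
      stop("insufficient replication: transgressive calls need n >= 2 and a defined SD for every member")
  lo <- min(trio$p1$mean, trio$p2$mean)
  hi <- max(trio$p1$mean, trio$p2$mean)
  f1 <- trio$f1$mean
  w1 <- welchFromSummary(f1, trio$f1$sd, trio$f1$n,
                         trio$p1$mean, trio$p1$sd, trio$p1$n)
  w2 <- welchFromSummary(f1, trio$f1$sd, trio$f1$n,
                         trio$p2$mean, trio$p2$sd, trio$p2$n)
  out <- list(transgressive = FALSE, direction = NA_character_,
              p_vs_p1 = w1$p_value, p_vs_p2 = w2$p_value)
  if (f1 > hi && w1$p_value < alpha && w2$p_value < alpha &&
      w1$t > 0 && w2$t > 0) {
    out$transgressive <- TRUE; out$direction <- "above"
  } else if (f1 < lo && w1$p_value < alpha && w2$p_value < alpha &&
             w1$t < 0 && w2$t < 0) {
    out$transgressive <- TRUE; out$direction <- "below"
  }
  out
}

#' Parametric bootstrap of a trio's dominance ratio, mode and heterosis
#'
#' Resamples each member mean from Normal(mean, sd/sqrt(n)), recomputes the
#' dominance ratio, MPH and mode per replicate, and returns percentile
#' confidence intervals plus the fraction of replicates agreeing with the
#' point-estimate mode.
#'
#' @param trio a [trioPhenotype()] with n >= 2 and defined SD per member.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed for reproducibility.
#' @param level confidence level of the percentile intervals.
#' @param epsilon classification tolerance passed to [classifyMode()].
#' @return list with \code{ratio_ci}, \code{mph_ci} (each c(low, high)),
#'   \code{level}, \code{mode_stability} and the point estimates.
#' @export
bootstrapTrio <- function(trio, B = 1000L, seed = 1L, level = 0.95,
                          epsilon = 0.1) {
  stopifnot(inherits(trio, "TrioPhenotype"), B >= 100L,
            level > 0, level < 1)
  for (m in list(trio$p1, trio$p2, trio$f1))
    if (m$n < 2 || is.na(m$sd))
      stop("insufficient replication: bootstrap needs n >= 2 and a defined SD for every member")
  dev <- trioDeviations(trio)
  a_min <- .default_a_min(trio)
  point_ratio <- dominanceRatio(dev$d, dev$a, a_min)
  point_mode <- classifyMode(point_ratio, dev$d, epsilon, d_noise = a_min)
  point_mph <- if (dev$m != 0) midParentHeterosis(trio$f1$mean, dev$m) else NA_real_

  se <- function(m) m$sd / sqrt(m$n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p1 <- stats::rnorm(B, trio$p1$mean, se(trio$p1))
  p2 <- stats::rnorm(B, trio$p2$mean, se(trio$p2))
  f1 <- stats::rnorm(B, trio$f1$mean, se(trio$f1))
  m <- (p1 + p2) / 2
  a <- abs(p1 - p2) / 2
  d <- f1 - m
  ratio <- ifelse(a >= pmax(a_min, .Machine$double.eps), d / a, NA_real_)
  mph <- ifelse(m != 0, 100 * d / m, NA_real_)
  modes <- vapply(seq_len(B), function(i)
    classifyMode(ratio[i], d[i], epsilon, d_noise = a_min), character(1))

  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(ratio = point_ratio, mode = point_mode, mph_percent = point_mph,
       ratio_ci = unname(stats::quantile(ratio, qs, na.rm = TRUE)),
       mph_ci = unname(stats::quantile(mph, qs, na.rm = TRUE)),
       level = level,
       mode_stability = mean(modes == point_mode))
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Full inheritance call for one trio
#'
#' Combines deviations, dominance ratio, mode classification, mid-parent
#' heterosis, the transgressive call and (optionally) bootstrap intervals
#' into one row of the MI table.
#'
#' @param trio a [trioPhenotype()].
#' @param epsilon classification tolerance (see [classifyMode()]).
#' @param alpha significance level of the transgressive Welch tests.
#' @param bootstrap logical; add bootstrap CIs and mode stability (requires
#'   n >= 2 and SDs for all members).
#' @param B,seed,level bootstrap parameters (see [bootstrapTrio()]).
#' @return One-row data.frame with columns \code{trait_id}, \code{m},
#'   \code{a}, \code{d}, \code{ratio}, \code{mode}, \code{mph_percent},
#'   \code{transgressive}, \code{direction}, and when bootstrapped
#'   \code{ratio_lo}, \code{ratio_hi}, \code{mph_lo}, \code{mph_hi},
#'   \code{mode_stability}.
#' @export
inheritanceCall <- function(trio, epsilon = 0.1, alpha = 0.05,
                            bootstrap = FALSE, B = 1000L, seed = 1L,
                            level = 0.95) {
  stopifnot(inherits(trio, "TrioPhenotype"))
  dev <- trioDeviations(trio)
  a_min <- .default_a_min(trio)
  ratio <- dominanceRatio(dev$d, dev$a, a_min)
  mode <- classifyMode(ratio, dev$d, epsilon, d_noise = a_min)
  mph <- if (dev$m != 0) midParentHeterosis(trio$f1$mean, dev$m) else NA_real_
  has_reps <- all(vapply(list(trio$p1, trio$p2, trio$f1),
                         function(m) m$n >= 2 && !is.na(m$sd), logical(1)))
  tg <- if (has_reps) callTransgressive(trio, alpha)
        else list(transgressive = NA, direction = NA_character_)
  out <- data.frame(
    trait_id = trio$trait_id, m = dev$m, a = dev$a, d = dev$d,
    ratio = ratio, mode = mode, mph_percent = mph,
    transgressive = tg$transgressive, direction = tg$direction,
    stringsAsFactors = FALSE)
  if (bootstrap) {
    bs <- bootstrapTrio(trio, B = B, seed = seed, level = level,
                        epsilon = epsilon)
    out$ratio_lo <- bs$ratio_ci[1]; out$ratio_hi <- bs$ratio_ci[2]
    out$mph_lo <- bs$mph_ci[1];     out$mph_hi <- bs$mph_ci[2]
    out$mode_stability <- bs$mode_stability
  }
  out
}

#' Inheritance (MI) table over a set of trios
#'
#' @param trios list of [trioPhenotype()] objects.
#' @param ... passed to [inheritanceCall()].
#' @return data.frame with one row per trio.
#' @export
miTable <- function(trios, ...) {
  stopifnot(length(trios) > 0)
  out <- do.call(rbind, lapply(trios, inheritanceCall, ...))
  rownames(out) <- NULL
  out
}
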