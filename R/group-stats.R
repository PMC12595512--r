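# One-way ANOVA with Scheffe post hoc comparisons and a compact letter
# display, from raw replicates or from published summary statistics
# (mean, SD, n), plus divergent-selection response statistics.

#' Build group summaries from raw replicates
#'
#' @param data data.frame with columns \code{label} and \code{value} (one
#'   row per replicate).
#' @return data.frame with one row per label: \code{label}, \code{mean},
#'   \code{sd}, \code{n}, in first-appearance order.
#' @export
summarizeGroups <- function(data) {
  data <- as.data.frame(data)
  stopifnot(all(c("label", "value") %in% names(data)))
  labs <- unique(as.character(data$label))
  out <- do.call(rbind, lapply(labs, function(l) {
    v <- data$value[data$label == l]
    data.frame(label = l, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.check_summaries <- function(summaries) {
  summaries <- as.data.frame(summaries)
  stopifnot(all(c("label", "mean", "sd", "n") %in% names(summaries)))
  if (nrow(summaries) < 2L) stop("need at least two groups")
  if (anyDuplicated(summaries$label)) stop("group labels must be unique")
  if (any(summaries$n < 2L))
    stop("insufficient replication: every group needs n >= 2")
  if (any(!is.finite(summaries$mean)) || any(!is.finite(summaries$sd)))
    stop("summaries must have finite mean and sd")
  if (any(summaries$sd < 0)) stop("sd must be >= 0")
  if (any(summaries$sd == 0))
    warning("group(s) with sd = 0: printed summaries are often rounded; ",
            "inference treats them at face value")
  summaries
}

#' One-way fixed-effects ANOVA from raw replicates
#'
#' Classical one-way ANOVA via [stats::aov()]; the p value comes from the F
#' distribution.
#'
#' @param data data.frame with columns \code{label} and \code{value}, each
#'   group with n >= 2.
#' @return list of class \code{"AnovaResult"}: \code{f_stat},
#'   \code{df_between}, \code{df_within}, \code{p_value}, \code{ms_within}.
#' @export
anovaOneway <- function(data) {
  data <- as.data.frame(data)
  stopifnot(all(c("label", "value") %in% names(data)))
  ns <- table(data$label)
  if (length(ns) < 2L) stop("need at least two groups")
  if (any(ns < 2L))
    stop("insufficient replication: every group needs n >= 2")
  if (stats::var(data$value) == 0) {
    k <- length(ns)
    res <- list(f_stat = 0, df_between = k - 1L,
                df_within = nrow(data) - k, p_value = 1, ms_within = 0)
    class(res) <- "AnovaResult"
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  fit <- stats::aov(value ~ label,
                    data = data.frame(label = factor(data$label),
                                      value = data$value))
  tab <- summary(fit)[[1]]
  res <- list(f_stat = tab[["F value"]][1],
              df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
              p_value = tab[["Pr(>F)"]][1], ms_within = tab[["Mean Sq"]][2])
  class(res) <- "AnovaResult"
  res
}

#' One-way ANOVA from summary statistics
#'
#' Reconstructs the ANOVA decomposition from per-group (mean, SD, n):
#' SS_between = sum n_i (xbar_i - xbar)^2, SS_within = sum (n_i - 1) s_i^2.
#' Identical contract to [anovaOneway()]; lets published tables reporting
#' only mean +/- SD be analysed.
#'
#' @param summaries data.frame with columns \code{label}, \code{mean},
#'   \code{sd}, \code{n} (n >= 2 per group).
#' @return list of class \code{"AnovaResult"} as in [anovaOneway()].
#' @export
anovaFromSummary <- function(summaries) {
  s <- .check_summaries(summaries)
  k <- nrow(s)
  N <- sum(s$n)
  grand <- sum(s$n * s$mean) / N
  ss_b <- sum(s$n * (s$mean - grand)^2)
  ss_w <- sum((s$n - 1) * s$sd^2)
  df_b <- k - 1L
  df_w <- N - k
  if (ss_w == 0 && ss_b == 0) {
    res <- list(f_stat = 0, df_between = df_b, df_within = df_w,
                p_value = 1, ms_within = 0)
    class(res) <- "AnovaResult"
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  ms_w <- ss_w / df_w
  f <- if (ms_w == 0) Inf else (ss_b / df_b) / ms_w
  res <- list(f_stat = f, df_between = df_b, df_within = df_w,
              p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
              ms_within = ms_w)
  class(res) <- "AnovaResult"
  res
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (MS within = %.4g)\n",
              x$df_between, x$df_within, x$f_stat, x$p_value, x$ms_within))
  invisible(x)
}

#' Scheffe post hoc pairwise comparisons
#'
#' Pair (i, j) is significant iff |xbar_i - xbar_j| exceeds
#' sqrt((k - 1) F_crit(alpha, k - 1, df_within)) *
#' sqrt(MS_within (1/n_i + 1/n_j)). Scheffe's criterion protects the whole
#' family of contrasts, so no pair can be significant when the omnibus
#' ANOVA is not.
#'
#' @param summaries data.frame with columns \code{label}, \code{mean},
#'   \code{sd}, \code{n}.
#' @param alpha family significance level (default 0.05).
#' @return list of class \code{"ScheffeResult"}: \code{significant} (logical
#'   k x k matrix), \code{diff} (mean differences), \code{critical}
#'   (threshold matrix), \code{anova}, \code{alpha}, \code{means}.
#' @export
scheffePairwise <- function(summaries, alpha = 0.05) {
  s <- .check_summaries(summaries)
  stopifnot(alpha > 0, alpha < 1)
  an <- anovaFromSummary(s)
  k <- nrow(s)
  f_crit <- stats::qf(1 - alpha, an$df_between, an$df_within)
  scale <- sqrt((k - 1) * f_crit)
  dmat <- abs(outer(s$mean, s$mean, "-"))
  semat <- sqrt(an$ms_within * outer(1 / s$n, 1 / s$n, "+"))
  crit <- scale * semat
  sig <- dmat > crit
  diag(sig) <- FALSE
  dimnames(sig) <- dimnames(dmat) <- dimnames(crit) <-
    list(s$label, s$label)
  res <- list(significant = sig, diff = dmat, critical = crit,
              anova = an, alpha = alpha,
              means = stats::setNames(s$mean, s$label))
  class(res) <- "ScheffeResult"
  res
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: start with all groups sharing one letter;
#' for each significant pair, split every letter column containing both
#' members; absorb columns that are subsets of others. Two groups share a
#' letter iff their comparison is non-significant. Letters are assigned to
#' columns in the order groups are ranked.
#'
#' @param pairwise a \code{ScheffeResult} from [scheffePairwise()], or a
#'   symmetric logical matrix with group labels as dimnames (TRUE =
#'   significantly different).
#' @param means named numeric vector of group means used for letter
#'   ordering; taken from the \code{ScheffeResult} when available.
#' @param order \code{"decreasing"} (default; largest mean gets "a"),
#'   \code{"increasing"}, or \code{"given"} (input order).
#' @return list of class \code{"LetterDisplay"}: \code{letters} (named
#'   character vector, possibly multi-letter), \code{groups} (list of
#'   label sets per letter).
#' @export
letterGroups <- function(pairwise, means = NULL, order = "decreasing") {
  if (inherits(pairwise, "ScheffeResult")) {
    if (is.null(means)) means <- pairwise$means
    pairwise <- pairwise$significant
  }
  stopifnot(is.matrix(pairwise), isSymmetric(unname(pairwise * 1)))
  labs <- rownames(pairwise)
  if (is.null(labs)) labs <- paste0("g", seq_len(nrow(pairwise)))
  k <- length(labs)
  order <- match.arg(order, c("decreasing", "increasing", "given"))
  ord <- switch(order,
    decreasing = if (is.null(means)) seq_len(k)
                 else order(means[labs], decreasing = TRUE),
    increasing = if (is.null(means)) seq_len(k)
                 else order(means[labs], decreasing = FALSE),
    given = seq_len(k))

  # columns: list of logical membership vectors over groups
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!pairwise[labs[i], labs[j]]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] <= cols[[b]]) && any(cols[[a]] < cols[[b]]))
        keep[a] <- FALSE
      else if (a < b && keep[a] && keep[b] &&
               identical(cols[[a]], cols[[b]]))
        keep[b] <- FALSE
    }
    cols <- cols[keep]
  }

  # order letters: a column's rank is the best rank of its members under ord
  rank_of <- integer(k); rank_of[ord] <- seq_len(k)
  col_rank <- vapply(cols, function(col) min(rank_of[col]), numeric(1))
  cols <- cols[order(col_rank)]
  letter_of <- letters[seq_along(cols)]
  lets <- vapply(seq_len(k), function(g)
    paste(letter_of[vapply(cols, `[`, logical(1), g)], collapse = ""),
    character(1))
  names(lets) <- labs
  groups <- lapply(cols, function(col) labs[col])
  names(groups) <- letter_of
  res <- list(letters = lets, groups = groups)
  class(res) <- "LetterDisplay"
  res
}

#' @export
print.LetterDisplay <- function(x, ...) {
  cat("Compact letter display:\n")
  for (l in names(x$letters))
    cat(sprintf("  %-20s %s\n", l, x$letters[[l]]))
  invisible(x)
}

#' Selection response between a base and an advanced generation
#'
#' R = mean(advanced) - mean(base). The relative response is expressed
#' against the advanced-generation mean, 100 * R / mean(advanced), the
#' denominator that reproduces published percentages of this design
#' (2.03/4.07 ~ 50 percent and 0.02/1.12 ~ 1.8 percent).
#'
#' @param mean_advanced advanced-generation mean (trait units).
#' @param mean_base base-generation mean (trait units).
#' @return list of class \code{"SelectionSummary"}: \code{mean_base},
#'   \code{mean_advanced}, \code{r}, \code{relative_percent}.
#' @examples
#' selectionResponse(4.07, 4.07 - 2.03)$relative_percent  # ~ 50
#' @export
selectionResponse <- function(mean_advanced, mean_base) {
  stopifnot(is.finite(mean_advanced), is.finite(mean_base))
  r <- mean_advanced - mean_base
  if (mean_advanced == 0)
    stop("undefined relative response: advanced-generation mean is zero")
  res <- list(mean_base = mean_base, mean_advanced = mean_advanced,
              r = r, relative_percent = 100 * r / mean_advanced)
  class(res) <- "SelectionSummary"
  res
}

#' @export
print.SelectionSummary <- function(x, ...) {
  cat(sprintf("Selection response R = %.4g (base %.4g -> advanced %.4g), relative %.3g%%\n",
              x$r, x$mean_base, x$mean_advanced, x$relative_percent))
  invisible(x)
}

#' Read group summaries from CSV
#'
#' Expects the header \code{label,mean,sd,n}.
#'
#' @param path path to the summary CSV.
#' @return data.frame of group summaries.
#' @export
readGroupSummaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "mean", "sd", "n") %in% names(df)))
  df
}
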