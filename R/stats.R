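# Repeated-measurements comparison across the four conditions: normality
# screening, one-way ANOVA per index, Bonferroni-corrected paired pairwise
# tests, and a mean +/- SD report with significance markers.

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' Standardizes the values by their sample mean/SD and tests against the
#' standard normal. Note this uses estimated parameters (the classical
#' anti-conservative variant, cf. Lilliefors); a warning notes this once
#' per session.
#'
#' @param values Numeric vector, n >= 8.
#' @param alpha Significance level.
#' @return List with `statistic`, `p_value`, `normal` (logical pass at
#'   `alpha`).
#' @export
ks_normality <- function(values, alpha = 0.05) {
  if (length(values) < 8) stop("ks_normality: need n >= 8")
  s <- stats::sd(values)
  if (s < 1e-12)
    return(list(statistic = NA_real_, p_value = NA_real_, normal = FALSE,
                note = "zero variance: normality test undefined"))
  z <- (values - mean(values)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  if (!isTRUE(.stats_state$lilliefors_warned)) {
    warning("ks_normality: test uses estimated mean/SD; ",
            "p-values are anti-conservative (Lilliefors situation)",
            call. = FALSE)
    .stats_state$lilliefors_warned <- TRUE
  }
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       normal = kt$p.value >= alpha)
}

.stats_state <- new.env(parent = emptyenv())

#' One-way ANOVA across the four conditions
#'
#' Classical one-way F test of equal condition means. If every value is
#' identical (no between- or within-group variation), F is reported as 0
#' and p as 1 by convention.
#'
#' @param values Numeric vector.
#' @param groups Factor/character of condition labels, same length.
#' @return List with `F`, `p_value`, `df`, and per-group `n`.
#' @export
anova_conditions <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("anova_conditions: need >= 2 groups")
  counts <- table(groups)
  if (any(counts < 2))
    stop("anova_conditions: every group needs n >= 2")
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (ssw < 1e-300) {
    if (ssb < 1e-300)
      return(list(F = 0, p_value = 1, df = c(df1, df2),
                  n = as.integer(counts)))
    return(list(F = Inf, p_value = 0, df = c(df1, df2),
                n = as.integer(counts)))
  }
  Fst <- (ssb / df1) / (ssw / df2)
  list(F = Fst, p_value = stats::pf(Fst, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), n = as.integer(counts))
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' All C(4,2) = 6 pairwise paired t-tests between conditions, with subjects
#' matched across conditions (the repeated-measurements design); a pair is
#' significant iff its raw p-value is below `alpha / 6`. The correction
#' spans the pairs within one index (configurable via `m`).
#'
#' @param data data.frame with columns `subject_id`, `condition`, `value`.
#' @param alpha Family-wise level.
#' @param m Correction factor (defaults to the number of pairs).
#' @return data.frame, one row per pair: `cond_a`, `cond_b`, `t`,
#'   `p_value`, `significant`.
#' @export
pairwise_bonferroni <- function(data, alpha = 0.05, m = NULL) {
  stopifnot(all(c("subject_id", "condition", "value") %in% names(data)))
  conds <- intersect(condition_levels(), unique(as.character(data$condition)))
  if (length(conds) < 2) stop("pairwise_bonferroni: need >= 2 conditions")
  wide <- stats::reshape(
    data[, c("subject_id", "condition", "value")],
    idvar = "subject_id", timevar = "condition", direction = "wide")
  vcols <- paste0("value.", conds)
  if (!all(vcols %in% names(wide)) || anyNA(wide[, vcols]))
    stop("pairwise_bonferroni: subjects are not matched across conditions")
  pairs <- utils::combn(conds, 2)
  if (is.null(m)) m <- ncol(pairs)
  out <- apply(pairs, 2, function(pr) {
    a <- wide[[paste0("value.", pr[1])]]
    b <- wide[[paste0("value.", pr[2])]]
    d <- a - b
    if (stats::sd(d) < 1e-12) {
      tt <- list(statistic = 0, p.value = 1)
    } else tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(cond_a = pr[1], cond_b = pr[2],
               t = unname(tt$statistic), p_value = tt$p.value,
               significant = tt$p.value < alpha / m)
  })
  out <- do.call(rbind, out)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  out
}

#' Condition-comparison report for all eight indices
#'
#' For each index: condition means and SDs, KS normality screen, one-way
#' ANOVA F/p, and Bonferroni-corrected paired pairwise markers in the
#' conventional footnote style (`*` vs baseline, `†` vs PVT, `‡`
#' vs n-back).
#'
#' @param features Labelled feature table (one trial's worth; typically
#'   trial 1).
#' @param alpha Family-wise level per index.
#' @return List of class `comparison_report`: `table` (data.frame, one row
#'   per index x condition with mean, sd, markers), `anova` (per index),
#'   `pairwise` (per index), `normality` (per index), `alpha`, `m`.
#' @export
comparison_report <- function(features, alpha = 0.05) {
  idx <- feature_names()
  stopifnot(all(idx %in% names(features)))
  conds <- condition_levels()
  marker_for <- c(BL = "*", PVT = "†", NBACK = "‡")
  anv <- list(); pw <- list(); nrm <- list(); rows <- list()
  for (f in idx) {
    v <- features[[f]]
    g <- as.character(features$condition)
    nrm[[f]] <- ks_normality(v)
    anv[[f]] <- anova_conditions(v, g)
    pw[[f]] <- pairwise_bonferroni(
      data.frame(subject_id = features$subject_id, condition = g,
                 value = v), alpha = alpha)
    for (cn in conds) {
      sig <- pw[[f]][pw[[f]]$significant &
                       (pw[[f]]$cond_a == cn | pw[[f]]$cond_b == cn), ]
      other <- ifelse(sig$cond_a == cn, sig$cond_b, sig$cond_a)
      marks <- paste(marker_for[other[other %in% names(marker_for)]],
                     collapse = "")
      rows[[paste(f, cn)]] <- data.frame(
        index = f, condition = cn,
        mean = mean(v[g == cn]), sd = stats::sd(v[g == cn]),
        markers = marks)
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 anova = anv, pairwise = pw, normality = nrm,
                 alpha = alpha, m = 6),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format_comparison_report(x), sep = "\n")
  invisible(x)
}

#' Text rendering of a comparison report
#'
#' Mean +/- SD per condition with significance-marker suffixes, one line
#' per index.
#'
#' @param x A `comparison_report`.
#' @return Character vector of lines.
#' @export
format_comparison_report <- function(x) {
  conds <- condition_levels()
  header <- sprintf("%-8s %s", "Index", paste(sprintf("%-18s", conds),
                                              collapse = ""))
  lines <- header
  for (f in unique(x$table$index)) {
    cells <- vapply(conds, function(cn) {
      r <- x$table[x$table$index == f & x$table$condition == cn, ]
      sprintf("%-18s", sprintf("%.3g ± %.2g %s", r$mean, r$sd,
                               r$markers))
    }, "")
    lines <- c(lines, sprintf("%-8s %s", f, paste(cells, collapse = "")))
  }
  c(lines,
    "* vs baseline; † vs PVT; ‡ vs n-back (paired t, Bonferroni)")
}
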