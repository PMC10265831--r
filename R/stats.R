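# The statistical decision tree: Lilliefors-corrected Kolmogorov-Smirnov
# normality gate, ANOVA / Kruskal-Wallis omnibus, t-test / Mann-Whitney
# post-hoc pairs, and boxplot summaries.

LILLIEFORS_C <- c(`0.2` = 0.741, `0.15` = 0.775, `0.1` = 0.819,
                  `0.05` = 0.895, `0.01` = 1.035)

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' SD estimated from the sample, compared to small-sample-corrected critical
#' values (Stephens' approximation
#' `D_crit = c_alpha / (sqrt(n) - 0.01 + 0.85 / sqrt(n))`). Estimating the
#' parameters makes the plain KS test anti-conservative; the corrected
#' critical values restore the nominal level.
#'
#' @param x Numeric sample, length >= 3.
#' @param alpha Significance level: one of 0.2, 0.15, 0.1, 0.05, 0.01.
#' @return List with `statistic` (D), `critical`, `reject`, `n`, and
#'   `degenerate` (TRUE for zero-variance samples, which are reported as
#'   rejections).
#' @export
lilliefors_test <- function(x, alpha = 0.05) {
  ca <- LILLIEFORS_C[as.character(alpha)]
  if (is.na(ca)) stop("alpha must be one of ",
                      paste(names(LILLIEFORS_C), collapse = ", "))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, critical = NA_real_, reject = TRUE,
                n = n, degenerate = TRUE))
  }
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  d_plus <- max(seq_len(n) / n - p)
  d_minus <- max(p - (seq_len(n) - 1L) / n)
  d <- max(d_plus, d_minus)
  crit <- unname(ca) / (sqrt(n) - 0.01 + 0.85 / sqrt(n))
  list(statistic = d, critical = crit, reject = d > crit, n = n,
       degenerate = FALSE)
}

as_group_table <- function(table) {
  if (is.data.frame(table)) {
    stop("pass a named list of numeric vectors (one per group)")
  }
  if (is.null(names(table)) || any(!nzchar(names(table)))) {
    names(table) <- paste0("group", seq_along(table))
  }
  table
}

#' Normality gate over a set of groups
#'
#' A parameter counts as normally distributed only when no supplied group
#' (across all conditions and regions) rejects the Lilliefors test at
#' `alpha`. Groups with fewer than 3 values are excluded with a warning.
#'
#' @param table Named list of numeric vectors (condition -> values), or a
#'   list of such lists (e.g. one per region).
#' @param alpha Significance level for each group's test.
#' @return List with `normal` (logical verdict), `per_group` (data frame of
#'   group, n, D, critical, reject), and `excluded` group names.
#' @export
normality_gate <- function(table, alpha = 0.05) {
  if (is.list(table) && length(table) && is.list(table[[1]]) &&
      !is.data.frame(table[[1]])) {
    flat <- list()
    for (nm in names(table)) {
      sub <- as_group_table(table[[nm]])
      names(sub) <- paste(nm, names(sub), sep = ".")
      flat <- c(flat, sub)
    }
    table <- flat
  } else {
    table <- as_group_table(table)
  }
  excluded <- names(table)[vapply(table, length, 0L) < 3L]
  if (length(excluded)) {
    warning("groups with < 3 values excluded: ",
            paste(excluded, collapse = ", "))
  }
  keep <- setdiff(names(table), excluded)
  per <- do.call(rbind, lapply(keep, function(nm) {
    r <- lilliefors_test(table[[nm]], alpha)
    data.frame(group = nm, n = r$n, D = r$statistic, critical = r$critical,
               reject = r$reject, stringsAsFactors = FALSE)
  }))
  list(normal = length(keep) > 0 && !any(per$reject), per_group = per,
       excluded = excluded)
}

#' Omnibus group comparison
#'
#' One-way ANOVA (equal-variance F test) when the normality verdict is
#' normal, Kruskal-Wallis otherwise.
#'
#' @param table Named list of numeric vectors, >= 2 groups.
#' @param normal Logical normality verdict (see [normality_gate()]).
#' @return List with `method`, `statistic`, `p.value`.
#' @export
omnibus_test <- function(table, normal) {
  table <- as_group_table(table)
  if (length(table) < 2L) stop("omnibus test needs at least 2 groups")
  values <- unlist(table, use.names = FALSE)
  grp <- factor(rep(names(table), lengths(table)))
  if (normal) {
    r <- stats::oneway.test(values ~ grp, var.equal = TRUE)
    list(method = "ANOVA", statistic = unname(r$statistic),
         p.value = r$p.value)
  } else {
    r <- stats::kruskal.test(values, grp)
    list(method = "Kruskal-Wallis", statistic = unname(r$statistic),
         p.value = r$p.value)
  }
}

#' Pairwise post-hoc comparisons
#'
#' Every unordered pair of groups is compared two-tailed with an unpaired
#' equal-variance Student's t-test (normal verdict) or a Mann-Whitney U
#' test (otherwise). No multiplicity correction is applied by default,
#' matching the study design; set `p_adjust` to a [stats::p.adjust()]
#' method to correct.
#'
#' @param table Named list of numeric vectors, >= 2 groups.
#' @param normal Logical normality verdict.
#' @param p_adjust Multiplicity-correction method (default "none").
#' @return Data frame: `group1`, `group2`, `test`, `statistic`, `p`,
#'   `stars`.
#' @export
posthoc_pairs <- function(table, normal, p_adjust = "none") {
  table <- as_group_table(table)
  nms <- names(table)
  if (length(nms) < 2L) stop("need at least 2 groups")
  if (anyDuplicated(nms)) stop("duplicated group names")
  pairs <- utils::combn(nms, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    if (normal) {
      r <- stats::t.test(x, y, var.equal = TRUE)
      data.frame(group1 = pr[1], group2 = pr[2], test = "t-test",
                 statistic = unname(r$statistic), p = r$p.value,
                 stringsAsFactors = FALSE)
    } else {
      r <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
      data.frame(group1 = pr[1], group2 = pr[2], test = "Mann-Whitney",
                 statistic = unname(r$statistic), p = r$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$stars <- significance_stars(out$p)
  out
}

#' Boxplot summary statistics
#'
#' Median, mean, 25th/75th percentiles (box edges) and 5th/95th percentiles
#' (whiskers), using linear-interpolation quantiles (type 7).
#'
#' @param values Numeric vector, length >= 1.
#' @return Named list: `median`, `mean`, `q25`, `q75`, `p5`, `p95`, `n`.
#' @export
boxplot_summary <- function(values) {
  if (!length(values)) stop("need at least one value")
  q <- stats::quantile(values, c(0.05, 0.25, 0.75, 0.95), type = 7,
                       names = FALSE)
  list(median = stats::median(values), mean = mean(values),
       q25 = q[2], q75 = q[3], p5 = q[1], p95 = q[4], n = length(values))
}

#' Full group comparison: gate, omnibus and post-hocs
#'
#' @param table Named list of numeric vectors (condition -> values).
#' @param alpha Normality-gate level.
#' @param gate_posthoc Run post-hocs only when the omnibus p is below
#'   `posthoc_alpha`? Default FALSE (post-hocs always reported).
#' @param posthoc_alpha Omnibus threshold used when `gate_posthoc = TRUE`.
#' @return A `comparison_result`: `normality`, `omnibus`, `pairwise`,
#'   `summaries` (per group [boxplot_summary()]).
#' @export
compare_groups <- function(table, alpha = 0.05, gate_posthoc = FALSE,
                           posthoc_alpha = 0.05) {
  table <- as_group_table(table)
  gate <- normality_gate(table, alpha)
  omn <- omnibus_test(table, gate$normal)
  pw <- NULL
  if (!gate_posthoc || omn$p.value < posthoc_alpha) {
    pw <- posthoc_pairs(table, gate$normal)
  }
  structure(list(normality = gate, omnibus = omn, pairwise = pw,
                 summaries = lapply(table, boxplot_summary)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("normality verdict:", if (x$normality$normal) "normal" else "non-normal",
      "\n")
  cat(sprintf("omnibus %s: statistic = %.4g, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p.value))
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise))) {
      r <- x$pairwise[i, ]
      cat(sprintf("  %s vs %s (%s): p = %.4g %s\n", r$group1, r$group2,
                  r$test, r$p, r$stars))
    }
  }
  invisible(x)
}
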