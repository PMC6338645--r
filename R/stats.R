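# The study's statistical procedures on grouped data: independent 2-sample
# Student's t tests (pooled variance) with Bonferroni correction, and
# one-way ANOVA with Tukey's HSD post hoc test. Thin wrappers around
# stats::t.test / stats::aov / stats::TukeyHSD / stats::p.adjust.

check_grouped <- function(data, min_groups = 2) {
  stopifnot(is.list(data), !is.null(names(data)))
  if (length(data) < min_groups) {
    stop("need at least ", min_groups, " groups")
  }
  small <- names(data)[vapply(data, length, integer(1)) < 2]
  if (length(small) > 0) {
    stop("groups with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }
  invisible(data)
}

#' Pairwise Student's t tests with Bonferroni correction
#'
#' Independent two-sample pooled-variance (Student) t tests over the
#' requested group pairs, two-sided, with Bonferroni adjustment
#' \code{p_adj = min(1, p_raw * m)} over the m comparisons; significance is
#' called at adjusted p < 0.05.
#'
#' @param data Named list of numeric vectors (one per group, each >= 2
#'   observations).
#' @param comparisons List of length-2 character vectors naming the pairs to
#'   test; default all pairs.
#' @param welch Use Welch's unequal-variance test instead of the pooled test.
#' @return data.frame with \code{group1}, \code{group2}, \code{t}, \code{df},
#'   \code{p_raw}, \code{p_adj}, \code{significant}.
#' @export
t_test_bonferroni <- function(data, comparisons = NULL, welch = FALSE) {
  check_grouped(data)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(data), 2, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(pair) {
    stopifnot(length(pair) == 2, all(pair %in% names(data)))
    tt <- stats::t.test(data[[pair[1]]], data[[pair[2]]],
                        var.equal = !welch)
    data.frame(group1 = pair[1], group2 = pair[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out$significant <- out$p_adj < 0.05
  out
}

#' One-way ANOVA with Tukey's HSD post hoc test
#'
#' Fixed-effects one-way ANOVA followed by Tukey's honest-significant-
#' difference pairwise comparisons (studentized range; Tukey-Kramer for
#' unbalanced designs). Zero within-group variance with unequal means is
#' flagged and reported as F = Inf, p = 0.
#'
#' @param data Named list of numeric vectors (one per group, each >= 2
#'   observations).
#' @return List with \code{F}, \code{df_between}, \code{df_within}, \code{p},
#'   \code{degenerate} flag, and \code{tukey}, a data.frame of pairwise
#'   differences with adjusted p-values.
#' @export
anova_tukey <- function(data) {
  check_grouped(data)
  long <- data.frame(
    group = factor(rep(names(data), vapply(data, length, integer(1)))),
    value = unlist(data, use.names = FALSE))
  means <- tapply(long$value, long$group, mean)
  ssw <- sum((long$value - means[long$group])^2)
  df_b <- nlevels(long$group) - 1L
  df_w <- nrow(long) - nlevels(long$group)
  if (ssw == 0 && stats::var(means) == 0) {
    # every observation identical: no variance anywhere
    pairs <- utils::combn(names(data), 2, simplify = FALSE)
    tukey <- do.call(rbind, lapply(pairs, function(pr) {
      data.frame(group1 = pr[1], group2 = pr[2], diff = 0,
                 lwr = 0, upr = 0, p_adj = 1)
    }))
    return(list(F = 0, df_between = df_b, df_within = df_w, p = 1,
                degenerate = TRUE, tukey = tukey))
  }
  if (ssw == 0 && stats::var(means) > 0) {
    pairs <- utils::combn(names(data), 2, simplify = FALSE)
    tukey <- do.call(rbind, lapply(pairs, function(pr) {
      data.frame(group1 = pr[1], group2 = pr[2],
                 diff = means[[pr[2]]] - means[[pr[1]]],
                 lwr = NA_real_, upr = NA_real_, p_adj = 0)
    }))
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0,
                degenerate = TRUE, tukey = tukey))
  }
  fit <- stats::aov(value ~ group, data = long)
  an <- stats::anova(fit)
  th <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(
    group1 = sub("^(.*)-(.*)$", "\\2", rownames(th)),
    group2 = sub("^(.*)-(.*)$", "\\1", rownames(th)),
    diff = th[, "diff"], lwr = th[, "lwr"], upr = th[, "upr"],
    p_adj = th[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(F = an[["F value"]][1], df_between = an[["Df"]][1],
       df_within = an[["Df"]][2], p = an[["Pr(>F)"]][1],
       degenerate = FALSE, tukey = tukey)
}
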