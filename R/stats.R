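#' Nonparametric rank tests on metric groups
#'
#' Wraps the standard nonparametric battery used for behavioral metric
#' tables: Mann-Whitney U (`"mw"`, two-sample or one-sample against a null
#' median), two-sample Kolmogorov-Smirnov (`"ks"`), and Kruskal-Wallis
#' (`"kw"`, any number of groups). Paired comparisons (same individual or
#' interacting pair measured twice) are supported for `"mw"`.
#'
#' @param groups List of numeric vectors (named names become group
#'   labels). A single group with `mu` runs the one-sample test.
#' @param kind `"mw"`, `"ks"` or `"kw"`.
#' @param paired Logical, `"mw"` only; group lengths must match.
#' @param mu Null median for the one-sample Mann-Whitney test.
#' @param alternative Passed to the underlying test (default
#'   `"two.sided"`).
#' @return One-row tibble: `method`, `statistic`, `p_value`,
#'   `p_adjusted` (`NA`; fill via [bh_adjust()] across a table), `n`
#'   (list of group sizes), `paired`, `effect_size` (Cohen's d for
#'   two-group comparisons, else `NA`).
#' @export
rank_tests <- function(groups, kind = c("mw", "ks", "kw"), paired = FALSE,
                       mu = NULL, alternative = "two.sided") {
  kind <- match.arg(kind)
  if (is.numeric(groups)) groups <- list(groups)
  ns <- lengths(groups)
  if (kind == "mw") {
    if (length(groups) == 1) {
      if (is.null(mu)) stop("one-sample test needs a null median mu")
      ht <- stats::wilcox.test(groups[[1]], mu = mu, exact = FALSE,
                               alternative = alternative)
    } else if (length(groups) == 2) {
      if (paired && ns[1] != ns[2]) {
        stop("paired comparison requires equal group lengths")
      }
      ht <- stats::wilcox.test(groups[[1]], groups[[2]], paired = paired,
                               exact = !paired &&
                                 !anyDuplicated(unlist(groups)),
                               alternative = alternative)
    } else stop("Mann-Whitney takes one or two groups")
  } else if (kind == "ks") {
    if (length(groups) != 2) stop("KS test takes exactly two groups")
    ht <- suppressWarnings(stats::ks.test(groups[[1]], groups[[2]],
                                          alternative = alternative))
  } else {
    if (length(groups) < 2) stop("Kruskal-Wallis needs >= 2 groups")
    ht <- stats::kruskal.test(groups)
  }
  es <- if (length(groups) == 2 && !paired && all(ns >= 2) &&
            stats::sd(unlist(groups)) > 0) {
    cohens_d(groups[[1]], groups[[2]])$d
  } else NA_real_
  tibble::tibble(method = ht$method, statistic = unname(ht$statistic),
                 p_value = ht$p.value, p_adjusted = NA_real_,
                 n = list(unname(ns)), paired = paired, effect_size = es)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction of a p-value vector:
#' `adj_i = min over {j : p_j >= p_i} of m * p_j / rank_j`, capped at 1
#' and order-preserving.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d with confidence interval
#'
#' Standardized mean difference `(mean_A - mean_B) / s_pooled`, pooling
#' variances with `n - 1` weights; 95% CI from the normal approximation
#' to the sampling variance of d.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble `d`, `conf_low`, `conf_high`, `n1`, `n2`.
#' @export
cohens_d <- function(a, b, conf_level = 0.95) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  d <- (mean(a) - mean(b)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(d = d, conf_low = d - z * se, conf_high = d + z * se,
                 n1 = n1, n2 = n2)
}

#' Exact binomial comparisons
#'
#' One-sample: exact binomial test of an empirical frequency against a
#' null probability. Two-sample: exact conditional comparison of two
#' frequencies (Fisher's test on the 2x2 table), chosen for determinism.
#'
#' @param successes,n Successes and trials of the first sample.
#' @param null_p Null probability (one-sample form).
#' @param successes2,n2 Second sample (two-sample form).
#' @param alternative Test sidedness (default `"two.sided"`).
#' @return One-row tibble `method`, `estimate`, `p_value`, `n`.
#' @examples
#' binomial_compare(8, 9, null_p = 0.5)
#' @export
binomial_compare <- function(successes, n, null_p = NULL, successes2 = NULL,
                             n2 = NULL, alternative = "two.sided") {
  if (n <= 0 || successes < 0 || successes > n) stop("invalid counts")
  if (!is.null(successes2)) {
    if (is.null(n2) || n2 <= 0 || successes2 < 0 || successes2 > n2) {
      stop("invalid counts for second sample")
    }
    tab <- matrix(c(successes, n - successes, successes2, n2 - successes2),
                  nrow = 2)
    ht <- stats::fisher.test(tab, alternative = alternative)
    return(tibble::tibble(method = "two-sample exact (conditional)",
                          estimate = successes / n - successes2 / n2,
                          p_value = ht$p.value, n = list(c(n, n2))))
  }
  if (is.null(null_p)) stop("supply null_p or a second sample")
  ht <- stats::binom.test(successes, n, p = null_p,
                          alternative = alternative)
  tibble::tibble(method = "one-sample exact binomial",
                 estimate = successes / n, p_value = ht$p.value,
                 n = list(n))
}

#' Tukey outlier fences
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` using
#' linear-interpolation quartiles (R quantile type 7). Flags only:
#' outliers are excluded from box whiskers for display but retained in
#' every quantification and statistical test.
#'
#' @param x Numeric sample (n >= 1).
#' @return Tibble `value`, `is_outlier`, with attributes `q1`, `q3`,
#'   `lower_fence`, `upper_fence`.
#' @examples
#' outlier_fences(c(1, 2, 3, 4, 100))  # 100 flagged
#' @export
outlier_fences <- function(x) {
  stopifnot(length(x) >= 1)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE,
                       na.rm = TRUE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[2] + 1.5 * iqr
  out <- tibble::tibble(value = x, is_outlier = x < lo | x > hi)
  attr(out, "q1") <- q[1]; attr(out, "q3") <- q[2]
  attr(out, "lower_fence") <- lo; attr(out, "upper_fence") <- hi
  out
}

#' Dunn's post-hoc test with compact letter display
#'
#' Pairwise Dunn z-tests on the pooled ranks (with tie correction) after
#' Kruskal-Wallis, Benjamini-Hochberg adjusted; groups receive letters
#' such that two groups share a letter if and only if they are not
#' significantly different at `alpha`. Letters come from the maximal
#' cliques of the non-significance graph, ordered by mean rank.
#'
#' @param groups Named list of numeric vectors (>= 3 groups).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class `dunn_letters`: list with `pairwise` (tibble
#'   `group1`, `group2`, `z`, `p_value`, `p_adjusted`), `letters` (tibble
#'   `group`, `letters`, `mean_rank`, `n`), `kruskal` (the
#'   [rank_tests()] row) and `alpha`.
#' @export
dunn_letters <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) == 0)) stop("empty group")
  if (length(groups) < 3) stop("need at least 3 groups")
  kw <- rank_tests(groups, kind = "kw")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  mr <- tapply(r, g, mean)[names(groups)]
  mean_rank <- stats::setNames(as.numeric(mr), names(mr))
  n <- lengths(groups)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(names(groups), 2)
  pw <- purrr::map_dfr(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    tibble::tibble(group1 = i, group2 = j, z = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
  })
  pw$p_adjusted <- bh_adjust(pw$p_value)
  # letters: maximal cliques of the graph whose edges join
  # not-significantly-different groups
  gr <- igraph::make_empty_graph(n = length(groups), directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = names(groups))
  ns_pairs <- pw[pw$p_adjusted >= alpha, c("group1", "group2")]
  if (nrow(ns_pairs)) {
    gr <- igraph::add_edges(gr, t(as.matrix(ns_pairs)))
  }
  cliques <- igraph::max_cliques(gr)
  ord <- order(vapply(cliques, function(cl) {
    -mean(mean_rank[names(groups)[as.integer(cl)]])
  }, numeric(1)))
  cliques <- cliques[ord]
  letter_of <- stats::setNames(rep("", length(groups)), names(groups))
  for (k in seq_along(cliques)) {
    members <- names(groups)[as.integer(cliques[[k]])]
    letter_of[members] <- paste0(letter_of[members], letters[k])
  }
  lett <- tibble::tibble(group = names(groups),
                         letters = unname(letter_of[names(groups)]),
                         mean_rank = unname(mean_rank[names(groups)]),
                         n = unname(n))
  structure(list(pairwise = pw, letters = lett, kruskal = kw,
                 alpha = alpha),
            class = "dunn_letters")
}

#' @export
print.dunn_letters <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis p = %.3g; Dunn post-hoc (BH), alpha = %g\n",
              x$kruskal$p_value, x$alpha))
  print(x$letters)
  invisible(x)
}

#' Tidy the pairwise Dunn table
#'
#' @param x A `dunn_letters` object.
#' @param ... Unused.
#' @return The pairwise tibble.
#' @export
tidy.dunn_letters <- function(x, ...) x$pairwise

#' One-row Dunn summary
#'
#' @param x A `dunn_letters` object.
#' @param ... Unused.
#' @return Tibble `kw_p`, `n_groups`, `n_distinct_letters`.
#' @export
glance.dunn_letters <- function(x, ...) {
  tibble::tibble(kw_p = x$kruskal$p_value, n_groups = nrow(x$letters),
                 n_distinct_letters = length(unique(x$letters$letters)))
}

#' Significance stars
#'
#' The conventional star labels: `*` < 0.05, `**` < 0.01, `***` < 0.001,
#' `ns` otherwise.
#'
#' @param p P-value vector.
#' @return Character vector of labels.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Publication-style statistics report
#'
#' Binds test rows into the standard report schema: sample sizes, sample
#' units, test used, whether a correction was applied, adjusted p-value
#' and effect size.
#'
#' @param tests Tibble of [rank_tests()]/[binomial_compare()] rows with an
#'   added `comparison` column.
#' @param units Sample-unit label (e.g. `"flies"`, `"pairs"`).
#' @param adjust If `TRUE` (default), BH-adjust the p-value column across
#'   rows.
#' @return Tibble `comparison`, `test`, `n`, `units`, `corrected`,
#'   `p_value`, `p_adjusted`, `stars`, `effect_size`.
#' @export
stats_report <- function(tests, units = "flies", adjust = TRUE) {
  tests <- tibble::as_tibble(tests)
  stopifnot("comparison" %in% names(tests))
  p_adj <- if (adjust) bh_adjust(tests$p_value) else tests$p_value
  tibble::tibble(comparison = tests$comparison, test = tests$method,
                 n = vapply(tests$n, function(v) paste(v, collapse = "/"),
                            character(1)),
                 units = units, corrected = adjust,
                 p_value = tests$p_value, p_adjusted = p_adj,
                 stars = p_stars(p_adj),
                 effect_size = if ("effect_size" %in% names(tests))
                   tests$effect_size else NA_real_)
}
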