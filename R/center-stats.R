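#' Kruskal-Wallis comparison of a QC metric across sequencing centers
#'
#' Rank-based test of whether a per-sample quality metric differs across
#' centers, with the standard tie correction; the statistic is referred to
#' a chi-square distribution with (number of centers - 1) degrees of
#' freedom.  When all values are identical the statistic is 0 and the
#' p-value 1.
#'
#' @param data Data frame with one value per (sample, center).
#' @param value,center Column names (unquoted) of the metric value and the
#'   grouping center.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `method`.
#' @export
#' @examples
#' d <- tibble::tibble(center = rep(c("A", "B", "C"), each = 3),
#'                     value = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
#' kruskal_by_center(d, value, center)
kruskal_by_center <- function(data, value, center) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ center }}))
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    abort("need at least two non-empty center groups.")
  }
  if (length(unique(v)) == 1L) {
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                          method = "Kruskal-Wallis rank sum test"))
  }
  kw <- stats::kruskal.test(v, g)
  tibble::tibble(statistic = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p_value = kw$p.value,
                 method = "Kruskal-Wallis rank sum test")
}

#' Randomized-block ANOVA for a center effect on shared samples
#'
#' Two-way decomposition with the sequencing center as the (fixed) factor
#' of interest and the individual sample as the blocking factor, on the
#' complete-block subset: every shared sample must be measured in every
#' center.  For a balanced design this F-test for the center effect is
#' identical to the one from a mixed model with a random sample effect,
#' without any mixed-model machinery.
#'
#' @param data Data frame of metric values.
#' @param value,center,sample Unquoted column names.
#' @return A one-row tibble: `statistic` (F for the center effect), `df1`,
#'   `df2`, `p_value`.
#' @export
#' @examples
#' d <- tidyr::crossing(sample = paste0("s", 1:6), center = c("A", "B", "C"))
#' d$value <- stats::rnorm(nrow(d))
#' block_anova(d, value, center, sample)
block_anova <- function(data, value, center, sample) {
  d <- dplyr::transmute(data,
                        value = {{ value }},
                        center = factor({{ center }}),
                        sample = factor({{ sample }}))
  tab <- table(d$sample, d$center)
  if (any(tab != 1)) {
    abort(paste0("incomplete block design: every shared sample must be ",
                 "measured exactly once in every center; subset `data` ",
                 "to the complete cases first."))
  }
  fit <- stats::aov(value ~ sample + center, data = d)
  sm <- summary(fit)[[1]]
  i <- trimws(rownames(sm)) == "center"
  r <- trimws(rownames(sm)) == "Residuals"
  f <- sm[i, "F value"]
  p <- sm[i, "Pr(>F)"]
  # a numerically zero center sum of squares is no center effect at all
  ss_tot <- sum((d$value - mean(d$value))^2)
  if (!is.finite(f) || sm[i, "Sum Sq"] <= 1e-10 * max(ss_tot, 1)) {
    f <- 0; p <- 1
  }
  tibble::tibble(statistic = f, df1 = sm[i, "Df"], df2 = sm[r, "Df"],
                 p_value = p)
}

#' Pairwise center comparison of a metric on shared samples
#'
#' Paired t-test on per-sample differences between two centers, with the
#' 95% confidence interval of the mean difference
#' (`mean +/- t_{0.975, n-1} * se`); a paired Wilcoxon signed-rank
#' p-value is reported alongside since either test may be preferred for
#' small non-normal samples.
#'
#' @param data Data frame of metric values.
#' @param value,center,sample Unquoted column names.
#' @param a,b The two center labels to compare (difference is `a - b`).
#' @param conf_level Confidence level of the interval.
#' @return A one-row tibble: `mean_diff`, `conf_low`, `conf_high`,
#'   `p_value` (paired t), `p_wilcoxon`, `n`, `degenerate` (TRUE when the
#'   differences have zero variance, making the interval a point).
#' @export
paired_center_comparison <- function(data, value, center, sample, a, b,
                                     conf_level = 0.95) {
  d <- dplyr::transmute(data, value = {{ value }},
                        center = as.character({{ center }}),
                        sample = as.character({{ sample }}))
  wide <- d |>
    dplyr::filter(.data$center %in% c(a, b)) |>
    tidyr::pivot_wider(names_from = "center", values_from = "value") |>
    tidyr::drop_na()
  if (nrow(wide) < 2) abort("need at least two samples shared by both centers.")
  diffs <- wide[[a]] - wide[[b]]
  n <- length(diffs)
  m <- mean(diffs)
  if (sd(diffs) == 0) {
    return(tibble::tibble(mean_diff = m, conf_low = m, conf_high = m,
                          p_value = NA_real_, p_wilcoxon = NA_real_,
                          n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(diffs, conf.level = conf_level)
  wx <- suppressWarnings(stats::wilcox.test(diffs))
  tibble::tibble(mean_diff = m,
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                 p_value = tt$p.value, p_wilcoxon = wx$p.value,
                 n = n, degenerate = FALSE)
}

#' Compare QC metrics across sequencing centers
#'
#' Runs, for each metric in a long metric table, the Kruskal-Wallis test
#' over all measured samples, the randomized-block ANOVA over the
#' complete-block (shared-sample) subset, and all pairwise center
#' comparisons of per-sample differences.  This is the statistical
#' framework used to decide whether centers differ on any raw-read QC
#' parameter.
#'
#' @param data Long tibble with columns `sample`, `center`, `metric`,
#'   `value`.
#' @return An object of class `center_comparison`: a list with tibbles
#'   `kruskal`, `anova` and `pairwise` (one row per metric or metric/pair),
#'   supporting [generics::tidy()] and [generics::glance()].
#' @export
compare_centers <- function(data) {
  stopifnot(all(c("sample", "center", "metric", "value") %in% names(data)))
  metrics <- unique(data$metric)
  centers <- sort(unique(data$center))

  # complete-block subset: samples measured in every center
  shared <- data |>
    dplyr::distinct(.data$sample, .data$center) |>
    dplyr::count(.data$sample) |>
    dplyr::filter(.data$n == length(centers)) |>
    dplyr::pull(.data$sample)

  kw <- purrr::map_dfr(metrics, function(mt) {
    d <- dplyr::filter(data, .data$metric == mt)
    dplyr::mutate(kruskal_by_center(d, value, center),
                  metric = mt, .before = 1)
  })
  an <- purrr::map_dfr(metrics, function(mt) {
    d <- dplyr::filter(data, .data$metric == mt, .data$sample %in% shared)
    dplyr::mutate(block_anova(d, value, center, sample),
                  metric = mt, .before = 1)
  })
  pairs <- utils::combn(centers, 2, simplify = FALSE)
  pw <- purrr::map_dfr(metrics, function(mt) {
    d <- dplyr::filter(data, .data$metric == mt, .data$sample %in% shared)
    purrr::map_dfr(pairs, function(p) {
      dplyr::mutate(
        paired_center_comparison(d, value, center, sample, p[1], p[2]),
        metric = mt, center_a = p[1], center_b = p[2], .before = 1)
    })
  })
  structure(list(kruskal = kw, anova = an, pairwise = pw,
                 centers = centers, shared_samples = shared),
            class = "center_comparison")
}

#' @export
print.center_comparison <- function(x, ...) {
  cat("Center comparison over", length(x$centers), "centers;",
      length(x$shared_samples), "shared samples\n\n")
  cat("Kruskal-Wallis:\n"); print(x$kruskal)
  cat("\nRandomized-block ANOVA (center effect):\n"); print(x$anova)
  invisible(x)
}
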