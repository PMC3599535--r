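#' Relative dN/dS difference between a young and an old domain
#'
#' The dN/dS of the young domain minus that of the old domain, divided by the
#' higher of the two, so the value is bounded in \[-1, 1\]: positive when the
#' young domain evolves faster. When both are 0 the difference is 0 by
#' convention.
#'
#' @param omega_young,omega_old Non-negative dN/dS values (vectorised).
#' @return Numeric vector in \[-1, 1\].
#' @examples
#' relative_difference(0.4, 0.1) # 0.75
#' @export
relative_difference <- function(omega_young, omega_old) {
  if (anyNA(omega_young) || anyNA(omega_old)) {
    stop("undefined omega in relative_difference()", call. = FALSE)
  }
  if (any(omega_young < 0) || any(omega_old < 0)) {
    stop("omega must be non-negative", call. = FALSE)
  }
  hi <- pmax(omega_young, omega_old)
  ifelse(hi == 0, 0, (omega_young - omega_old) / hi)
}

#' Binomial test comparing substitution spectra of two domains in one protein
#'
#' Tests whether the young domain's split of substitutions into nonsynonymous
#' vs synonymous differs from what the old domain's per-site rates would
#' predict on the young domain's sites. Counts are rounded (half up) to
#' integers; the null success probability is the site-adjusted expectation
#' p0 = (N_y * Nd_o/N_o) / (N_y * Nd_o/N_o + S_y * Sd_o/S_o), or the
#' unadjusted Nd_o/(Nd_o + Sd_o) with `site_adjusted = FALSE`.
#'
#' @param young,old One-row data frames (or lists) with `Nd`, `Sd`, `N_sites`,
#'   `S_sites` (as returned by [estimate_dnds()]).
#' @param alpha Significance level for the verdict (default 0.01).
#' @param site_adjusted Use the site-adjusted null (default) or the raw old
#'   substitution split.
#' @return One-row tibble: `successes`, `trials`, `p0`, `p_value`, `verdict`
#'   (`young_faster` / `old_faster` / `no_difference`) and `degenerate`
#'   (TRUE when the test could not be performed: zero trials, or a null
#'   probability of exactly 0 or 1 contradicted by the observations).
#' @export
paired_binomial_test <- function(young, old, alpha = 0.01,
                                 site_adjusted = TRUE) {
  x <- round_half_up(young$Nd)
  n <- round_half_up(young$Nd + young$Sd)
  p0 <- if (site_adjusted) {
    rn <- if (old$N_sites > 0) old$Nd / old$N_sites else 0
    rs <- if (old$S_sites > 0) old$Sd / old$S_sites else 0
    num <- young$N_sites * rn
    den <- num + young$S_sites * rs
    if (den > 0) num / den else NA_real_
  } else {
    tot <- old$Nd + old$Sd
    if (tot > 0) old$Nd / tot else NA_real_
  }
  degenerate <- n == 0 || is.na(p0) ||
    (p0 == 0 && x > 0) || (p0 == 1 && x < n)
  if (degenerate) {
    return(tibble(successes = x, trials = n, p0 = p0, p_value = NA_real_,
                  verdict = "no_difference", degenerate = TRUE))
  }
  # base binom.test returns a logical p.value when p0 is exactly 0 or 1
  p <- as.numeric(stats::binom.test(x, n, p = p0,
                                    alternative = "two.sided")$p.value)
  verdict <- if (p > alpha) "no_difference"
             else if (x / n > p0) "young_faster" else "old_faster"
  tibble(successes = x, trials = n, p0 = p0, p_value = p,
         verdict = verdict, degenerate = FALSE)
}

#' Compare dN/dS distributions between age groups
#'
#' Runs pairwise two-sample Kolmogorov–Smirnov tests between independent age
#' groups, reports medians and quartiles per group, and, when within-protein
#' young/old pairs are supplied, a paired Wilcoxon signed-rank test. With
#' `by_type = TRUE` each domain type is first collapsed to its median omega,
#' removing the weight of very abundant types.
#'
#' @param rates Data frame with an age-group column and an omega column; rows
#'   with `NA` omega are dropped.
#' @param pairs Optional data frame of within-protein comparisons with columns
#'   `omega_young` and `omega_old`.
#' @param group_col,value_col Column names (defaults `age_class_merged`,
#'   `omega`).
#' @param by_type Collapse to per-domain-type medians first (needs
#'   `type_col`).
#' @param type_col Domain-type column used when `by_type = TRUE`.
#' @return Object of class `age_group_comparison`: list with tibbles `groups`,
#'   `ks` and (possibly NULL) `wilcoxon`.
#' @export
compare_age_groups <- function(rates, pairs = NULL,
                               group_col = "age_class_merged",
                               value_col = "omega",
                               by_type = FALSE,
                               type_col = "domain_type_id") {
  stopifnot(is.data.frame(rates))
  df <- tibble(group = as.character(rates[[group_col]]),
               value = rates[[value_col]])
  if (by_type) {
    df$type <- rates[[type_col]]
    df <- df |>
      dplyr::group_by(.data$group, .data$type) |>
      dplyr::summarise(value = median(.data$value, na.rm = TRUE),
                       .groups = "drop")
  }
  df <- df[!is.na(df$value), ]
  if (dplyr::n_distinct(df$group) < 2) {
    stop("need at least two age groups with omega values", call. = FALSE)
  }
  groups <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$value),
      q1 = unname(quantile(.data$value, 0.25)),
      q3 = unname(quantile(.data$value, 0.75)),
      .groups = "drop"
    )
  gl <- split(df$value, df$group)
  cmb <- utils::combn(names(gl), 2, simplify = FALSE)
  ks <- purrr::map_dfr(cmb, function(pr) {
    a <- gl[[pr[1]]]; b <- gl[[pr[2]]]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(group1 = pr[1], group2 = pr[2], statistic = NA_real_,
                    p_value = NA_real_, skipped = TRUE))
    }
    kt <- suppressWarnings(stats::ks.test(a, b))
    tibble(group1 = pr[1], group2 = pr[2],
           statistic = unname(kt$statistic), p_value = kt$p.value,
           skipped = FALSE)
  })
  wil <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    ok <- !is.na(pairs$omega_young) & !is.na(pairs$omega_old)
    if (sum(ok) >= 2) {
      wt <- suppressWarnings(
        stats::wilcox.test(pairs$omega_young[ok], pairs$omega_old[ok],
                           paired = TRUE)
      )
      wil <- tibble(n_pairs = sum(ok), statistic = unname(wt$statistic),
                    p_value = wt$p.value)
    } else {
      wil <- tibble(n_pairs = sum(ok), statistic = NA_real_,
                    p_value = NA_real_)
    }
  }
  structure(list(groups = groups, ks = ks, wilcoxon = wil),
            class = "age_group_comparison")
}

#' @export
print.age_group_comparison <- function(x, ...) {
  cat("<age_group_comparison>\nGroup summaries:\n")
  print(x$groups)
  cat("\nPairwise Kolmogorov-Smirnov tests:\n")
  print(x$ks)
  if (!is.null(x$wilcoxon)) {
    cat("\nPaired Wilcoxon (within-protein young vs old):\n")
    print(x$wilcoxon)
  }
  invisible(x)
}

#' Tidy an age-group comparison
#'
#' @param x An `age_group_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the pairwise KS test tibble; `glance()`: one row with the
#'   number of groups, total observations and the paired Wilcoxon p-value (NA
#'   when no pairs were supplied).
#' @export
tidy.age_group_comparison <- function(x, ...) x$ks

#' @rdname tidy.age_group_comparison
#' @export
glance.age_group_comparison <- function(x, ...) {
  tibble(
    n_groups = nrow(x$groups),
    n_obs = sum(x$groups$n),
    wilcoxon_p = if (is.null(x$wilcoxon)) NA_real_ else x$wilcoxon$p_value
  )
}

#' Turn a result object into a tidy tibble
#'
#' Broom-style generics for the package's result objects.
#'
#' @param x A result object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
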