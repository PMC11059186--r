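#' Descriptive summary of a numeric sample
#'
#' Mean, sample (n-1) standard deviation, median, quartiles (linear
#' interpolation between order statistics, the type-7 convention) and range.
#' A singleton sample reports sd = 0 with `sd_flag = TRUE` rather than
#' aborting, so summary tables never fail on a single observation.
#'
#' @param values Non-empty numeric vector.
#' @return A list: `n`, `mean`, `sd`, `median`, `q1`, `q3`, `min`, `max`,
#'   `sd_flag`.
#' @export
summarize_values <- function(values) {
  if (length(values) == 0L) stop("need at least one value", call. = FALSE)
  stopifnot(is.numeric(values), all(is.finite(values)))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  singleton <- length(values) == 1L
  list(n = length(values),
       mean = mean(values),
       sd = if (singleton) 0 else stats::sd(values),
       median = q[2L], q1 = q[1L], q3 = q[3L],
       min = min(values), max = max(values),
       sd_flag = singleton)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param groups Named list of non-empty numeric vectors (>= 2 groups, total
#'   n >= 3).
#' @return A list: `statistic` (H), `df`, `p_value`, `method`.
#' @export
kw_test <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  if (sum(lengths(groups)) < 3L) stop("need total n >= 3", call. = FALSE)
  # every observation tied: zero rank variance, H defined as 0
  if (length(unique(unlist(groups))) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                method = "Kruskal-Wallis rank sum test"))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "Kruskal-Wallis rank sum test")
}

#' Pairwise rank-sum post-hoc comparisons with Bonferroni correction
#'
#' Two-sided Mann-Whitney rank-sum tests across all k(k-1)/2 group pairs,
#' with p-values multiplied by the number of pairs (capped at 1). Run only
#' after a significant global test: when `global_p` exceeds `alpha` the
#' returned table is empty.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Family-wise significance level (default 0.05).
#' @param global_p P-value of the global test; if omitted, [kw_test()] is run
#'   internally.
#' @return A tibble: `group1`, `group2`, `p_raw`, `p_adj`, `significant`.
#'   Zero rows when the global test is not significant.
#' @export
pairwise_posthoc <- function(groups, alpha = 0.05, global_p = NULL) {
  if (is.null(global_p)) global_p <- kw_test(groups)$p_value
  empty <- tibble::tibble(group1 = character(), group2 = character(),
                          p_raw = numeric(), p_adj = numeric(),
                          significant = logical())
  if (global_p > alpha) return(empty)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- suppressWarnings(
      stats::wilcox.test(groups[[i]], groups[[j]], exact = FALSE,
                         correct = TRUE)$p.value)
    tibble::tibble(group1 = nms[i], group2 = nms[j], p_raw = p,
                   p_adj = min(1, p * n_pairs))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj <= alpha
  out
}

#' Fisher exact test on a contingency table of accuracy counts
#'
#' Two-sided exact test. Small tables (total count <= `exact_max`) use full
#' conditional enumeration; larger ones fall back to a seeded Monte-Carlo
#' p-value (1e5 table permutations).
#'
#' @param table A matrix of non-negative integer counts (e.g. catheters x
#'   in/out of the accuracy band). All row and column margins must be
#'   positive.
#' @param exact_max Largest total count for which the exact path is used
#'   (default 200).
#' @param mc_B Number of Monte-Carlo replicates on the fallback path.
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @return A list: `p_value`, `method`.
#' @export
fisher_exact_test <- function(table, exact_max = 200, mc_B = 1e5, seed = NULL) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(table != round(table))) stop("counts must be integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margin: every row and column needs a positive total",
         call. = FALSE)
  if (sum(table) <= exact_max) {
    ft <- stats::fisher.test(table)
    list(p_value = ft$p.value, method = "Fisher exact (enumeration)")
  } else {
    if (!is.null(seed)) set.seed(seed)
    ft <- stats::fisher.test(table, simulate.p.value = TRUE, B = mc_B)
    list(p_value = ft$p.value,
         method = sprintf("Fisher exact (Monte-Carlo, B = %d)", as.integer(mc_B)))
  }
}

#' Group statistics for a study metric
#'
#' Convenience wrapper running the global Kruskal-Wallis test and, when
#' significant, the Bonferroni-corrected pairwise post-hoc layer for one
#' metric grouped by catheter.
#'
#' @param values Numeric vector of the metric.
#' @param group Vector of group labels, same length.
#' @param alpha Family-wise significance level.
#' @return A list: `global` (from [kw_test()]), `pairwise` (tibble), and
#'   `summaries` (per-group [summarize_values()] rows as a tibble).
#' @export
group_comparison <- function(values, group, alpha = 0.05) {
  stopifnot(length(values) == length(group))
  keep <- !is.na(values)
  groups <- split(values[keep], factor(group[keep], levels = unique(group[keep])))
  global <- kw_test(groups)
  summaries <- do.call(rbind, lapply(names(groups), function(nm) {
    s <- summarize_values(groups[[nm]])
    tibble::tibble(group = nm, n = s$n, mean = s$mean, sd = s$sd,
                   median = s$median, q1 = s$q1, q3 = s$q3,
                   min = s$min, max = s$max)
  }))
  list(global = global,
       pairwise = pairwise_posthoc(groups, alpha, global$p_value),
       summaries = summaries)
}
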