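#' Kruskal-Wallis test over groups
#'
#' Rank-based nonparametric one-way ANOVA with tie correction; p-value from
#' the chi-square approximation with g - 1 degrees of freedom. The unit of
#' analysis is intended to be per-specimen summary statistics, not pooled
#' per-vessel values.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 1 value)
#' @return list with `H`, `p`, `df`, `degenerate`
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = NA_real_, df = length(groups) - 1L,
                degenerate = TRUE))
  kt <- kruskal.test(values, labels)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Compare cohorts of per-specimen summaries
#'
#' For each requested quantity: group means with SD, and the Kruskal-Wallis
#' p-value over the per-specimen values (the specimen, not the vessel, is the
#' unit of analysis; no multiple-testing correction is applied, and single
#' specimens per group yield an undefined p).
#'
#' @param summaries data.frame with a `group` column and one numeric column
#'   per quantity, one row per specimen
#' @param quantities character vector of column names to compare (default:
#'   all numeric columns)
#' @return data.frame with one row per quantity and group
#' @export
compare_cohorts <- function(summaries, quantities = NULL) {
  stopifnot(is.data.frame(summaries), "group" %in% names(summaries))
  if (is.null(quantities))
    quantities <- names(summaries)[vapply(summaries, is.numeric, TRUE)]
  groups <- split(summaries, summaries$group)
  rows <- list()
  for (q in quantities) {
    if (!q %in% names(summaries)) { warning("missing quantity: ", q); next }
    vals <- lapply(groups, function(gdf) gdf[[q]][is.finite(gdf[[q]])])
    p <- if (any(lengths(vals) < 2)) NA_real_ else kruskal_wallis(vals)$p
    for (gn in names(groups)) {
      v <- vals[[gn]]
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = q, group = gn, n = length(v), mean = mean(v),
        sd = if (length(v) > 1) sd(v) else NA_real_, p_kw = p)
    }
  }
  do.call(rbind, rows)
}
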