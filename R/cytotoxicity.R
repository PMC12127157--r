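# NK killing assays: efficiency from flow counts (CFSE+ 7-AAD+ over
# CFSE+), per-E:T-ratio curves and curve comparison. No spontaneous-death
# subtraction is applied: the raw ratio is the assay's stated readout.

#' Killing efficiency from flow-count events
#'
#' `100 * n_dead / n_target_total`, with CFSE-stained target cells as the
#' 100% reference. Vectorised.
#'
#' @param n_dead CFSE+ 7-AAD+ event count(s).
#' @param n_target_total CFSE+ event count(s), > 0.
#' @return Efficiency in percent.
#' @export
killing_efficiency <- function(n_dead, n_target_total) {
  if (any(n_dead < 0) || any(n_target_total < 0)) stop("counts must be non-negative")
  if (any(n_target_total == 0)) stop("n_target_total must be positive")
  if (any(n_dead > n_target_total)) stop("n_dead cannot exceed n_target_total")
  100 * n_dead / n_target_total
}

#' Build a killing curve across E:T ratios
#'
#' @param assays Data frame with columns `target`, `ratio`, `replicate`,
#'   `n_total`, `n_dead`. All replicates of a target must cover the same
#'   set of ratios.
#' @return A tibble per (target, ratio): `mean_efficiency`,
#'   `sd_efficiency` (sample SD; 0 for a single replicate) and
#'   `n_replicates`.
#' @export
build_killing_curve <- function(assays) {
  need <- c("target", "ratio", "replicate", "n_total", "n_dead")
  stopifnot(all(need %in% names(assays)))
  assays <- tibble::as_tibble(assays)
  assays$efficiency <- killing_efficiency(assays$n_dead, assays$n_total)

  for (tg in unique(assays$target)) {
    sub <- assays[assays$target == tg, ]
    sets <- lapply(split(sub$ratio, sub$replicate), sort)
    if (length(unique(sets)) > 1) {
      stop(sprintf("target '%s': replicates cover different E:T ratio sets", tg))
    }
  }

  assays |>
    dplyr::group_by(.data$target, .data$ratio) |>
    dplyr::summarise(
      mean_efficiency = mean(.data$efficiency),
      sd_efficiency = ifelse(dplyr::n() > 1, stats::sd(.data$efficiency), 0),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$target, .data$ratio)
}

#' Compare two killing curves across E:T ratios
#'
#' Reports the per-ratio difference of mean efficiencies (`a - b`) and a
#' one-sided paired test across ratios of the hypothesis that curve `a`
#' kills more efficiently: a Wilcoxon signed-rank test when five or more
#' ratios are available, otherwise (the usual four-ratio design) a paired
#' t-test. With so few ratios the test is underpowered; the per-ratio sign
#' pattern of `difference` is the primary readout.
#'
#' @param curve_a,curve_b Curves from [build_killing_curve()] (single
#'   target each) with identical ratio sets.
#' @return A list: `differences` (tibble `ratio`, `difference`),
#'   `statistic`, `p_value`, `method`.
#' @export
compare_killing_curves <- function(curve_a, curve_b) {
  need <- c("ratio", "mean_efficiency")
  stopifnot(all(need %in% names(curve_a)), all(need %in% names(curve_b)))
  a <- dplyr::arrange(tibble::as_tibble(curve_a), .data$ratio)
  b <- dplyr::arrange(tibble::as_tibble(curve_b), .data$ratio)
  if (!identical(a$ratio, b$ratio)) stop("curves cover different E:T ratio sets")

  d <- a$mean_efficiency - b$mean_efficiency
  if (all(d == 0)) {
    stat <- 0; p <- 1; method <- "degenerate (identical curves)"
  } else if (stats::sd(d) == 0) {
    # uniform shift: no within-curve variability to test against
    stat <- sign(d[1]) * Inf
    p <- if (d[1] > 0) 0 else 1
    method <- "degenerate (constant difference)"
  } else if (length(d) >= 5) {
    ht <- stats::wilcox.test(d, alternative = "greater", exact = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
    method <- "wilcoxon signed-rank (one-sided)"
  } else {
    ht <- stats::t.test(d, alternative = "greater")
    stat <- unname(ht$statistic); p <- ht$p.value
    method <- "paired t (one-sided)"
  }
  list(
    differences = tibble::tibble(ratio = a$ratio, difference = d),
    statistic = stat, p_value = p, method = method
  )
}
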