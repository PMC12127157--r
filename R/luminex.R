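# Single-antigen-bead (Luminex) MFI panels under the two-type partition:
# grouped summaries, reagent concordance, and an Otsu-style bimodal split.

# Average replicate wells per allele (panel statistics are across alleles,
# not wells).
collapse_panel <- function(panel) {
  stopifnot(all(c("allele", "mfi") %in% names(panel)))
  if (any(panel$mfi < 0, na.rm = TRUE)) stop("MFI values must be >= 0")
  panel |>
    dplyr::group_by(.data$allele) |>
    dplyr::summarise(mfi = mean(.data$mfi), .groups = "drop")
}

# Welch two-sample t as in stats::t.test, with the degenerate zero-variance
# case defined: identical constant groups give t = 0, p = 1; constant
# groups with different means give |t| = Inf, p = 0.
welch_test <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(d) * Inf, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Summarise an MFI panel by MICA type
#'
#' Replicate wells are averaged per allele, alleles are grouped by their
#' type call, and per-type mean and sample SD (n-1) are reported with a
#' Welch two-sample t-test (default) or Mann-Whitney U comparing the two
#' groups. `unclassified` alleles are excluded from the comparison.
#'
#' @param panel Long tibble with columns `allele`, `mfi` and optionally
#'   `reagent` and `replicate`. Summaries are per reagent when a `reagent`
#'   column is present.
#' @param calls Type calls from [classify_alleles()] (columns `allele`,
#'   `type`) covering every panel allele.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#'
#' @return A tibble, one row per reagent: `reagent`, `mean_I`, `sd_I`,
#'   `n_I`, `mean_II`, `sd_II`, `n_II`, `statistic`, `p_value`, `method`,
#'   `test_available`. The statistic is signed as Type-I minus Type-II;
#'   with fewer than two alleles in a group the summary is returned with
#'   the test marked unavailable.
#' @export
summarize_by_type <- function(panel, calls, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(all(c("allele", "mfi") %in% names(panel)))
  panel <- tibble::as_tibble(panel)
  if (!"reagent" %in% names(panel)) panel$reagent <- NA_character_

  missing <- setdiff(unique(panel$allele), calls$allele)
  if (length(missing) > 0) {
    stop("panel allele(s) without a type call: ", paste(missing, collapse = ", "))
  }

  purrr::map_dfr(split(panel, factor(panel$reagent, exclude = NULL)), function(sub) {
    avg <- collapse_panel(sub)
    avg$type <- calls$type[match(avg$allele, calls$allele)]
    g1 <- avg$mfi[avg$type == "type_I"]
    g2 <- avg$mfi[avg$type == "type_II"]
    out <- tibble::tibble(
      reagent = sub$reagent[1],
      mean_I = mean(g1), sd_I = stats::sd(g1), n_I = length(g1),
      mean_II = mean(g2), sd_II = stats::sd(g2), n_II = length(g2),
      statistic = NA_real_, p_value = NA_real_,
      method = test, test_available = length(g1) >= 2 && length(g2) >= 2
    )
    if (out$test_available) {
      res <- if (test == "welch") {
        welch_test(g1, g2)
      } else {
        ht <- stats::wilcox.test(g1, g2, exact = FALSE)
        list(statistic = unname(ht$statistic), p_value = ht$p.value)
      }
      out$statistic <- res$statistic
      out$p_value <- res$p_value
    }
    out
  })
}

#' Reactivity-pattern concordance between two reagents
#'
#' Pearson correlation of per-allele mean MFI over the alleles shared by
#' two panels. Strongly negative values indicate opposite reactivity
#' patterns (the two-epitope structure seen with reciprocal allosera).
#'
#' @param panel_a,panel_b Long tibbles with columns `allele`, `mfi`.
#' @return Pearson r in `[-1, 1]`.
#' @export
pattern_concordance <- function(panel_a, panel_b) {
  a <- collapse_panel(panel_a)
  b <- collapse_panel(panel_b)
  shared <- intersect(a$allele, b$allele)
  if (length(shared) < 3) stop("need at least 3 shared alleles")
  x <- a$mfi[match(shared, a$allele)]
  y <- b$mfi[match(shared, b$allele)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a panel: correlation undefined")
  }
  stats::cor(x, y)
}

#' Split a panel into high/low reactivity groups (Otsu threshold)
#'
#' Scans every midpoint between consecutive distinct sorted per-allele MFI
#' values and picks the threshold maximising the between-group variance
#' `w_lo * w_hi * (mean_hi - mean_lo)^2` — the 1-D Otsu criterion.
#'
#' @param panel Long tibble with columns `allele`, `mfi` (>= 4 alleles).
#' @return A list: `high` and `low` (character vectors of allele names)
#'   and `threshold`.
#' @export
bimodal_split <- function(panel) {
  avg <- collapse_panel(panel)
  if (nrow(avg) < 4) stop("need at least 4 alleles to split")
  v <- sort(unique(avg$mfi))
  if (length(v) < 2) stop("all MFI values are equal: no split exists")
  cand <- (v[-length(v)] + v[-1]) / 2
  crit <- vapply(cand, function(th) {
    lo <- avg$mfi[avg$mfi <= th]
    hi <- avg$mfi[avg$mfi > th]
    (length(lo) / nrow(avg)) * (length(hi) / nrow(avg)) *
      (mean(hi) - mean(lo))^2
  }, numeric(1))
  threshold <- cand[which.max(crit)]
  list(
    high = avg$allele[avg$mfi > threshold],
    low = avg$allele[avg$mfi <= threshold],
    threshold = threshold
  )
}
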