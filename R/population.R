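# Population-level arithmetic: allele-class frequency aggregation, diploid
# carrier coverage, Hardy-Weinberg phenotype groups. Frequencies are kept
# in percent, as printed in population tables, and converted to fractions
# only at the probability boundary.

#' Read a population allele-frequency table
#'
#' Expects a TSV with classes/alleles as rows and populations as columns
#' (first column = class label), frequencies in percent.
#'
#' @param path Path to the TSV file.
#' @return A long tibble: `population`, `class`, `frequency_pct`.
#' @export
read_frequency_table <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    class = readr::col_character()
  ))
  tidyr::pivot_longer(wide, -"class", names_to = "population",
                      values_to = "frequency_pct")[
    , c("population", "class", "frequency_pct")]
}

#' Packaged population frequencies of the three MICA allele classes
#'
#' Published percent frequencies of (i) the 29 common expressed MICA
#' alleles combined (`common_29`), (ii) the non-expressed `MICA*010`
#' allele, and (iii) all `other` alleles, in five regional populations.
#'
#' @return A long tibble: `population`, `class`, `frequency_pct`.
#' @export
mica_frequencies <- function() {
  read_frequency_table(extdata("mica_population_frequencies.tsv"))
}

#' Summed frequency of a set of allele classes
#'
#' @param x A long frequency tibble (`population`, `class`,
#'   `frequency_pct`), e.g. from [mica_frequencies()].
#' @param classes Character vector of class labels to sum; every label
#'   must be present for every population.
#'
#' @return A tibble `population`, `total_pct` (label order is irrelevant).
#' @export
class_total <- function(x, classes) {
  stopifnot(all(c("population", "class", "frequency_pct") %in% names(x)))
  sub <- x[x$class %in% classes, ]
  found <- split(sub$class, sub$population)
  bad <- vapply(found, function(cl) !all(classes %in% cl), logical(1))
  if (length(found) == 0 || any(bad)) {
    stop("class label(s) missing from table: ",
         paste(setdiff(classes, unique(sub$class)), collapse = ", "))
  }
  sub |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(total_pct = sum(.data$frequency_pct), .groups = "drop")
}

#' Probability that a diploid individual carries a class allele
#'
#' For a class with summed allele frequency `p` (fraction, not percent),
#' the probability of carrying one or two class alleles is
#' `1 - (1 - p)^2` under the Hardy-Weinberg binomial model, or
#' `1 - exp(-2p)` under a Poisson approximation of the allele count. The
#' binomial model is the default; the Poisson form is a close lower
#' approximation for small `p` (they differ by at most `p^2`).
#'
#' @param p Allele-class frequency as a fraction in `[0, 1]` (vectorised).
#' @param model `"binomial"` (default) or `"poisson"`.
#' @return Carrier probability in `[0, 1]`.
#' @export
carrier_probability <- function(p, model = c("binomial", "poisson")) {
  model <- match.arg(model)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("allele frequency p must be within [0, 1]")
  }
  switch(model,
    binomial = 1 - (1 - p)^2,
    poisson  = 1 - exp(-2 * p)
  )
}

#' Hardy-Weinberg phenotype groups for the two-type partition
#'
#' With Type-I and Type-II allele frequencies `f_I` and `f_II` (fractions),
#' individuals fall into Type-I homozygotes (`f_I^2`), Type-II homozygotes
#' (`f_II^2`) and Type-I/Type-II heterozygotes (`2 f_I f_II`).
#'
#' @param f_I,f_II Type allele frequencies, fractions with
#'   `f_I + f_II <= 1`.
#' @return A one-row tibble: `f_homo_I`, `f_homo_II`, `f_hetero`.
#' @export
phenotype_groups <- function(f_I, f_II) {
  if (any(!is.finite(c(f_I, f_II))) || any(c(f_I, f_II) < 0) ||
      any(c(f_I, f_II) > 1) || f_I + f_II > 1 + 1e-12) {
    stop("f_I and f_II must be fractions with f_I + f_II <= 1")
  }
  tibble::tibble(
    f_homo_I = f_I^2,
    f_homo_II = f_II^2,
    f_hetero = 2 * f_I * f_II
  )
}
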