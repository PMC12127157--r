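# The six-linked-site Type-I / Type-II classifier: the computational core.
#
# Type-I MICA carries C36+M129+K173+G206+W210+S215, Type-II carries
# Y36+V129+E173+S206+R210+T215. Published alignments contain alleles that
# match neither haplotype fully, so the call is a majority vote over the
# six sites with the tightly linked position 129 (M/V dimorphism) breaking
# 3-3 ties; this reproduces the published grouping for all 29 panel
# alleles.

#' The six-site Type-I/Type-II signature
#'
#' @param tiebreak_site Position whose residue decides tied votes
#'   (default 129, the M/V dimorphism linked to the other five sites).
#'
#' @return A tibble with columns `position`, `type_I` and `type_II`
#'   (the residue each type carries at that position), carrying the
#'   tie-break site as an attribute.
#' @export
mica_signature <- function(tiebreak_site = 129L) {
  sig <- tibble::tibble(
    position = c(36L, 129L, 173L, 206L, 210L, 215L),
    type_I   = c("C", "M", "K", "G", "W", "S"),
    type_II  = c("Y", "V", "E", "S", "R", "T")
  )
  validate_signature(sig, tiebreak_site)
  attr(sig, "tiebreak_site") <- as.integer(tiebreak_site)
  sig
}

validate_signature <- function(sig, tiebreak_site) {
  stopifnot(all(c("position", "type_I", "type_II") %in% names(sig)))
  if (any(sig$type_I == sig$type_II)) {
    stop("signature residue tuples must differ at every site")
  }
  if (!tiebreak_site %in% sig$position) {
    stop("tiebreak_site must be one of the signature sites")
  }
  invisible(sig)
}

sig_tiebreak <- function(sig) attr(sig, "tiebreak_site") %||% 129L

#' Classify alleles into Type-I / Type-II from the six-site signature
#'
#' Counts, over the signature sites, how many residues match the Type-I
#' tuple (`score_I`) and how many the Type-II tuple (`score_II`); residues
#' matching neither, and unknowns (`X`), count for neither, so novel
#' alleles remain classifiable. The call is the majority type; a tie is
#' broken by the residue at the tie-break site (position 129: M is Type-I,
#' V is Type-II), and an allele still tied after that is `unclassified` —
#' a first-class outcome, never coerced.
#'
#' @param x A [site_table()] or a data frame with columns `allele`,
#'   `position`, `residue`. Every allele must provide a residue at all six
#'   signature sites.
#' @param signature A signature tibble, by default [mica_signature()].
#'
#' @return A tibble of class `mica_type_calls` with one row per allele:
#'   `allele`, `type` (`"type_I"`, `"type_II"` or `"unclassified"`),
#'   `score_I`, `score_II` (0-6) and `tiebroken`. Partition counts are
#'   available via [type_counts()] / [glance()].
#' @examples
#' calls <- classify_alleles(mica_alignment())
#' type_counts(calls)
#' @export
classify_alleles <- function(x, signature = mica_signature()) {
  validate_signature(signature, sig_tiebreak(signature))
  tbl <- as_residue_tbl(x)
  tbl <- tbl[tbl$position %in% signature$position, ]
  allele_order <- if (inherits(x, "mica_site_table")) st_alleles(x) else unique(as_residue_tbl(x)$allele)

  calls <- purrr::map_dfr(allele_order, function(nm) {
    rows <- tbl[tbl$allele == nm, ]
    res <- rows$residue[match(signature$position, rows$position)]
    if (anyNA(res)) {
      missing <- signature$position[is.na(res)]
      stop(sprintf("allele '%s' lacks residue(s) at signature site(s): %s",
                   nm, paste(missing, collapse = ", ")))
    }
    score_I <- sum(res == signature$type_I)
    score_II <- sum(res == signature$type_II)
    tiebroken <- FALSE
    if (score_I > score_II) {
      type <- "type_I"
    } else if (score_II > score_I) {
      type <- "type_II"
    } else {
      tb <- match(sig_tiebreak(signature), signature$position)
      type <- if (res[tb] == signature$type_I[tb]) {
        tiebroken <- TRUE; "type_I"
      } else if (res[tb] == signature$type_II[tb]) {
        tiebroken <- TRUE; "type_II"
      } else {
        "unclassified"
      }
    }
    tibble::tibble(allele = nm, type = type, score_I = score_I,
                   score_II = score_II, tiebroken = tiebroken)
  })
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(allele = character(), type = character(),
                            score_I = integer(), score_II = integer(),
                            tiebroken = logical())
  }
  class(calls) <- c("mica_type_calls", class(calls))
  calls
}

#' @rdname classify_alleles
#' @param residues Named character vector: residue per position, covering
#'   the six signature sites.
#' @param name Allele name for the returned call.
#' @export
classify_allele <- function(residues, signature = mica_signature(),
                            name = "allele") {
  tbl <- tibble::tibble(allele = name,
                        position = as.integer(names(residues)),
                        residue = as.character(residues))
  classify_alleles(tbl, signature)
}

#' Partition summary of a set of type calls
#'
#' @param calls A `mica_type_calls` tibble from [classify_alleles()].
#' @return A one-row tibble with `n_type_I`, `n_type_II`,
#'   `n_unclassified`.
#' @export
type_counts <- function(calls) {
  stopifnot(all(c("allele", "type") %in% names(calls)))
  tibble::tibble(
    n_type_I = sum(calls$type == "type_I"),
    n_type_II = sum(calls$type == "type_II"),
    n_unclassified = sum(calls$type == "unclassified")
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @method glance mica_type_calls
#' @export
glance.mica_type_calls <- function(x, ...) type_counts(x)

#' Fraction of alleles on which two type partitions agree
#'
#' @param calls,labels Data frames with columns `allele` and `type`; they
#'   must cover the same (non-empty) set of alleles.
#' @return A fraction in `[0, 1]`; 1 means identical partitions.
#' @export
signature_concordance <- function(calls, labels) {
  stopifnot(all(c("allele", "type") %in% names(calls)),
            all(c("allele", "type") %in% names(labels)))
  if (nrow(calls) == 0 || nrow(labels) == 0) {
    stop("cannot compute concordance on empty partitions")
  }
  if (!setequal(calls$allele, labels$allele) ||
      anyDuplicated(calls$allele) || anyDuplicated(labels$allele)) {
    stop("partitions must cover the same set of alleles exactly once")
  }
  m <- match(calls$allele, labels$allele)
  mean(calls$type == labels$type[m])
}
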