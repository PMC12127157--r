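# Long-form container for a polymorphic-site alignment: one row per
# (allele, position, residue), with the reference sequence carried as
# attributes so dash-notation files round-trip losslessly.

AA_CODES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
UNKNOWN_CODE <- "X"

#' Build a polymorphic-site table
#'
#' A site table holds the residues of a set of alleles at an ordered set of
#' 1-based mature-protein positions, together with a reference sequence
#' (conventionally MICA*001). It is a long-format tibble with columns
#' `allele`, `position` and `residue`; the reference residues and name are
#' stored as attributes and available through [st_reference()] and
#' [st_reference_name()].
#'
#' @param alleles A data frame with columns `allele` (character),
#'   `position` (integer) and `residue` (single upper-case amino-acid letter
#'   or `"X"` for unknown). Every allele must cover every position.
#' @param reference Named character vector of reference residues; names are
#'   the positions. Must cover the same positions as `alleles` and contain
#'   no `"X"`.
#' @param reference_name Name of the reference allele.
#'
#' @return A tibble of class `mica_site_table`.
#' @seealso [read_site_table()], [mica_alignment()]
#' @export
site_table <- function(alleles, reference, reference_name = "MICA*001") {
  stopifnot(is.data.frame(alleles))
  alleles <- tibble::as_tibble(alleles)[, c("allele", "position", "residue")]
  alleles$position <- as.integer(alleles$position)

  positions <- as.integer(names(reference))
  if (anyNA(positions) || any(positions <= 0L) || any(diff(positions) <= 0L)) {
    stop("reference positions must be strictly increasing positive integers")
  }
  reference <- as.character(reference)
  names(reference) <- positions
  if (!all(reference %in% AA_CODES)) {
    stop("reference residues must be standard one-letter amino-acid codes (no 'X')")
  }

  check_residues(alleles$residue, context = "site table")
  split_pos <- split(alleles$position, alleles$allele)
  bad <- names(split_pos)[!vapply(
    split_pos, function(p) identical(sort(p), positions), logical(1)
  )]
  if (length(bad) > 0) {
    stop("allele(s) do not cover the reference positions exactly: ",
         paste(bad, collapse = ", "))
  }

  structure(
    alleles,
    positions = positions,
    reference = reference,
    reference_name = reference_name,
    class = c("mica_site_table", class(tibble::tibble()))
  )
}

check_residues <- function(residues, context = "input") {
  ok <- residues %in% c(AA_CODES, UNKNOWN_CODE)
  if (!all(ok)) {
    stop(sprintf(
      "invalid residue code(s) in %s: %s",
      context, paste(unique(residues[!ok]), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' @rdname site_table
#' @param x A `mica_site_table`.
#' @export
st_positions <- function(x) attr(x, "positions")

#' @rdname site_table
#' @export
st_reference <- function(x) attr(x, "reference")

#' @rdname site_table
#' @export
st_reference_name <- function(x) attr(x, "reference_name")

#' @rdname site_table
#' @export
st_alleles <- function(x) unique(x$allele)

#' @export
print.mica_site_table <- function(x, ...) {
  cat(sprintf(
    "<mica_site_table> %d alleles x %d positions (reference: %s)\n",
    length(st_alleles(x)), length(st_positions(x)), st_reference_name(x)
  ))
  NextMethod()
}

# Coerce acceptable inputs (site table or plain long data frame) to a long
# residue tibble; used by the classifier and polymorphism scans.
as_residue_tbl <- function(x) {
  if (inherits(x, "mica_site_table")) {
    tibble::as_tibble(unclass_site_table(x))
  } else if (is.data.frame(x)) {
    need <- c("allele", "position", "residue")
    if (!all(need %in% names(x))) {
      stop("expected columns allele, position, residue")
    }
    out <- tibble::as_tibble(x)[, need]
    out$position <- as.integer(out$position)
    check_residues(out$residue)
    out
  } else {
    stop("expected a mica_site_table or a data frame of allele residues")
  }
}

unclass_site_table <- function(x) {
  attr(x, "positions") <- NULL
  attr(x, "reference") <- NULL
  attr(x, "reference_name") <- NULL
  class(x) <- class(tibble::tibble())
  x
}
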