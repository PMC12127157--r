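# Positional comparison of allele sets against the reference: polymorphic
# site discovery and per-allele diffs.

#' Extract polymorphic positions from an allele set
#'
#' A position is polymorphic when at least two distinct residues occur
#' across the alleles at that position. Unknown residues (`X`) are ignored
#' when building the spectrum, so partial sequences never create spurious
#' polymorphisms. For a [site_table()] the reference sequence is included
#' in the scan.
#'
#' Alleles must be positionally comparable (same position coverage, e.g.
#' equal-length mature-protein sequences); no gap or indel handling is
#' attempted.
#'
#' @param x A [site_table()] or a long data frame (`allele`, `position`,
#'   `residue`) of at least two alleles.
#'
#' @return A tibble with one row per polymorphic position: `position`,
#'   `n_residues`, and `residues` (list column of the observed spectrum,
#'   sorted).
#' @export
polymorphic_sites <- function(x) {
  tbl <- as_residue_tbl(x)
  if (inherits(x, "mica_site_table")) {
    ref <- tibble::tibble(
      allele = st_reference_name(x),
      position = st_positions(x),
      residue = unname(st_reference(x))
    )
    # the reference may legitimately also be an allele row (identical
    # residues); including it twice does not change any spectrum
    tbl <- dplyr::bind_rows(ref, tbl)
  }
  alleles <- unique(tbl$allele)
  if (length(alleles) < 2) stop("need at least two alleles (or a site table)")

  cover <- split(tbl$position, tbl$allele)
  common <- sort(unique(tbl$position))
  bad <- names(cover)[!vapply(cover, function(p) setequal(p, common), logical(1))]
  if (length(bad) > 0) {
    stop("allele(s) with mismatched position coverage: ",
         paste(bad, collapse = ", "))
  }

  tbl <- tbl[tbl$residue != UNKNOWN_CODE, ]
  spec <- tbl |>
    dplyr::distinct(.data$position, .data$residue) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(residues = list(sort(.data$residue)), .groups = "drop") |>
    dplyr::mutate(n_residues = lengths(.data$residues)) |>
    dplyr::filter(.data$n_residues >= 2) |>
    dplyr::arrange(.data$position)
  spec[, c("position", "n_residues", "residues")]
}

#' Positional differences of one allele against a reference
#'
#' @param x A [site_table()] (the reference is its reference sequence) or a
#'   long data frame containing both `allele` and `reference` as allele
#'   names.
#' @param allele Name of the allele to compare.
#' @param reference Name of the reference allele when `x` is a plain data
#'   frame; ignored for site tables.
#'
#' @return A tibble with one row per differing position: `position`,
#'   `ref_residue`, `alt_residue`. Zero rows means sequence-identical.
#' @export
diff_to_reference <- function(x, allele, reference = NULL) {
  tbl <- as_residue_tbl(x)
  rows <- tbl[tbl$allele == allele, ]
  if (nrow(rows) == 0) stop("allele not found: ", allele)

  if (inherits(x, "mica_site_table")) {
    ref_res <- st_reference(x)
    ref_pos <- st_positions(x)
  } else {
    if (is.null(reference)) stop("a reference allele name is required")
    ref_rows <- tbl[tbl$allele == reference, ]
    if (nrow(ref_rows) == 0) stop("reference allele not found: ", reference)
    ref_pos <- ref_rows$position
    ref_res <- ref_rows$residue
    names(ref_res) <- ref_pos
  }
  if (!setequal(rows$position, ref_pos)) {
    stop(sprintf("allele '%s' does not cover the reference positions", allele))
  }
  pos <- sort(rows$position)
  alt <- rows$residue[match(pos, rows$position)]
  ref <- unname(ref_res[as.character(pos)])
  differ <- alt != ref
  tibble::tibble(position = pos[differ], ref_residue = ref[differ],
                 alt_residue = alt[differ])
}
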