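# Readers/writers for allele sequences and the dash-notation alignment
# table, plus the packaged 29-allele alignment.

#' Read mature-protein allele sequences from a FASTA file
#'
#' Each record is taken to be a mature-protein sequence: position 1 is the
#' first residue after signal-peptide cleavage (the numbering behind the
#' field's "MICA-129" convention). No signal-peptide trimming is attempted.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#'
#' @return A long tibble with columns `allele` (header text up to the first
#'   whitespace), `position` (1-based) and `residue`. Records of unequal
#'   length are returned as-is; positional comparability is checked later,
#'   at site extraction.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records found in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  purrr::map2_dfr(names(seqs), as.character(seqs), function(nm, s) {
    if (nm == "") stop("FASTA record with empty name")
    res <- strsplit(toupper(s), "")[[1]]
    check_residues(res, context = sprintf("FASTA record '%s'", nm))
    tibble::tibble(allele = nm, position = seq_along(res), residue = res)
  })
}

normalise_dashes <- function(x) gsub("[–—−]", "-", x)

#' Read a dash-notation polymorphic-site table
#'
#' The format mirrors published polymorphic-site alignments: the first row
#' carries the 1-based mature-protein positions, the second the reference
#' allele (name + explicit residues), and each following row one allele,
#' where `-` (hyphen, en or em dash all accepted) means "identical to the
#' reference at this position".
#'
#' @param path Path to a tab-separated dash-notation file.
#'
#' @return A [site_table()] with all dashes expanded to explicit residues.
#' @export
read_site_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("site table needs a position row and a reference row")
  cells <- lapply(lines, function(l) normalise_dashes(strsplit(l, "\t", fixed = TRUE)[[1]]))

  header <- cells[[1]]
  positions <- suppressWarnings(as.integer(header[-1]))
  if (anyNA(positions)) stop("first row must be the position header")
  n_pos <- length(positions)

  ref_row <- cells[[2]]
  if (length(ref_row) != n_pos + 1L) {
    stop("reference row length does not match the position header")
  }
  reference_name <- ref_row[1]
  reference <- ref_row[-1]
  if (any(reference == "-")) {
    stop("reference row may not contain dashes: explicit residues required")
  }
  check_residues(reference, context = "reference row")
  if (any(reference == UNKNOWN_CODE)) stop("reference row may not contain 'X'")
  names(reference) <- positions

  allele_rows <- cells[-(1:2)]
  alleles <- purrr::map_dfr(allele_rows, function(row) {
    if (length(row) != n_pos + 1L) {
      stop(sprintf("row '%s' has %d cells, expected %d",
                   row[1], length(row) - 1L, n_pos))
    }
    res <- row[-1]
    res[res == "-"] <- reference[res == "-"]
    check_residues(res, context = sprintf("row '%s'", row[1]))
    tibble::tibble(allele = row[1], position = positions, residue = res)
  })
  if (nrow(alleles) == 0) {
    alleles <- tibble::tibble(allele = character(), position = integer(),
                              residue = character())
  }
  site_table(alleles, reference, reference_name)
}

#' Write a site table in dash notation
#'
#' Residues equal to the reference are emitted as `-`; the reference row is
#' always explicit. `read_site_table(write_site_table(x, p))` reproduces
#' `x` exactly.
#'
#' @param x A [site_table()].
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  stopifnot(inherits(x, "mica_site_table"))
  positions <- st_positions(x)
  reference <- st_reference(x)
  lines <- c(
    paste(c("position", positions), collapse = "\t"),
    paste(c(st_reference_name(x), reference), collapse = "\t")
  )
  tbl <- as_residue_tbl(x)
  for (nm in st_alleles(x)) {
    rows <- tbl[tbl$allele == nm, ]
    res <- rows$residue[match(positions, rows$position)]
    res[res == reference] <- "-"
    lines <- c(lines, paste(c(nm, res), collapse = "\t"))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

extdata <- function(file) {
  system.file("extdata", file, package = "micatype", mustWork = TRUE)
}

#' Packaged 29-allele polymorphic-site alignment
#'
#' The published alignment of the 29 common MICA protein variants over the
#' 27 polymorphic positions of the ectodomain, with MICA*001 as the
#' reference. MICA*001 appears both as the reference and as an allele row
#' (it is one of the 29 panel molecules), so the table classifies to the
#' published 18 Type-I / 11 Type-II split.
#'
#' @return `mica_alignment()`: a [site_table()] with 27 positions and 29
#'   allele rows. `mica_type_labels()`: a tibble with columns `allele` and
#'   `type` (`"type_I"`/`"type_II"`) holding the published grouping.
#' @export
mica_alignment <- function() {
  read_site_table(extdata("mica_panel_alignment.tsv"))
}

#' @rdname mica_alignment
#' @export
mica_type_labels <- function() {
  readr::read_tsv(extdata("mica_type_labels.tsv"),
                  col_types = readr::cols(.default = readr::col_character()))
}
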