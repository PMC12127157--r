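# Small in-code fixtures shared across test files.

# minimal three-position site table: two alleles, one differing at 3
tiny_site_table <- function() {
  site_table(
    tibble::tibble(
      allele = rep(c("A1", "A2"), each = 3),
      position = rep(c(2L, 5L, 9L), 2),
      residue = c("A", "C", "G", "A", "C", "T")
    ),
    reference = c(`2` = "A", `5` = "C", `9` = "G"),
    reference_name = "REF"
  )
}

# long residue tibble for plain sequences, positions 1..nchar
seq_tbl <- function(...) {
  seqs <- list(...)
  purrr::imap_dfr(seqs, function(s, nm) {
    res <- strsplit(s, "")[[1]]
    tibble::tibble(allele = nm, position = seq_along(res), residue = res)
  })
}

write_temp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(unlist(purrr::imap(records, function(s, nm) c(paste0(">", nm), s))),
             path)
  path
}

# residues at the six signature sites, as a named vector ready for
# classify_allele()
sig_residues <- function(r36, r129, r173, r206, r210, r215) {
  stats::setNames(c(r36, r129, r173, r206, r210, r215),
                  c(36, 129, 173, 206, 210, 215))
}
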