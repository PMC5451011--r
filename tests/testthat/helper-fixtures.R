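# Write a small ProteinPilot-style summary file and return its path.
write_pp_file <- function(rows, path = withr::local_tempfile(
                            fileext = ".txt", .local_envir = parent.frame())) {
  header <- paste(names(rows), collapse = "\t")
  body <- do.call(paste, c(rows, sep = "\t"))
  writeLines(c(header, body), path)
  path
}

pp_rows <- function(N, Accession, Name = "Protein", Gene = "GENE1",
                    ...) {
  c(list(N = N, Accession = Accession, Name = Name, Gene = Gene),
    list(...))
}

# A summary object straight from in-memory rows (proteinpilot layout).
pp_summary <- function(N, Accession, Gene = "GENE1", run_id = "runX",
                       ...) {
  raw <- tibble::tibble(N = as.character(N), Accession = Accession,
                        Name = "Protein", Gene = Gene, ...)
  pgclink:::parse_protein_summary(
    raw, pgclink:::dialect_presets()$proteinpilot, run_id
  )
}
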