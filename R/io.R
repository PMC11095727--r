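#' Write / read an assay dataset as delimited text
#'
#' The on-disk layout is the conventional variant-table format: a `mutant`
#' column of colon-separated substitution strings (empty string for the
#' wildtype row), a real-valued `fitness` column, and an optional integer
#' `round` column recording the acquisition round.
#'
#' @param ds an `assay_dataset`.
#' @param path output CSV path.
#' @export
write_assay_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @param wildtype optional wildtype sequence to attach to the dataset.
#' @return `read_assay_csv` returns an `assay_dataset`.
#' @export
read_assay_csv <- function(path, wildtype = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mutant = "character"))
  if (!all(c("mutant", "fitness") %in% names(df))) {
    stop("variant table must have columns 'mutant' and 'fitness'")
  }
  df$mutant[is.na(df$mutant)] <- ""
  new_assay_dataset(df$mutant, df$fitness,
                    round_index = if ("round" %in% names(df)) df$round else NULL,
                    wildtype = wildtype)
}

#' Write a wildtype sequence as FASTA
#' @param wildtype amino-acid sequence.
#' @param path output path.
#' @param name FASTA record name.
#' @export
write_wildtype_fasta <- function(wildtype, path, name = "wildtype") {
  seqinr::write.fasta(sequences = strsplit(wildtype, "")[[1L]],
                      names = name, file.out = path)
  invisible(path)
}

#' Read a single-record FASTA wildtype
#' @rdname write_wildtype_fasta
#' @export
read_wildtype_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  toupper(as.character(recs[[1L]]))
}

#' Write an embedding matrix as delimited text (row order = variant CSV order)
#' @param E numeric matrix.
#' @param path output path.
#' @param sep field separator.
#' @export
write_embedding <- function(E, path, sep = ",") {
  utils::write.table(E, path, sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
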