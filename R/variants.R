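#' Amino-acid alphabet used throughout the package
#'
#' The 20 canonical amino acids in a fixed, documented order, optionally
#' extended by the gap symbol `-` and the unknown symbol `X`. The order is
#' frozen because one-hot column indices (and hence any downstream linear model
#' coefficients) depend on it.
#'
#' @param extended logical; include gap and unknown symbols (default `TRUE`,
#'   giving 22 symbols per site).
#' @return character vector of single-letter residue symbols.
#' @export
#' @examples
#' aa_alphabet()          # 22 symbols
#' aa_alphabet(FALSE)     # the 20 canonical amino acids
aa_alphabet <- function(extended = TRUE) {
  canonical <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (extended) c(canonical, "-", "X") else canonical
}

#' Parse a mutation string into a substitution table
#'
#' Variants are written in the conventional substitution notation used by
#' ProteinGym-style variant tables: colon-separated tokens of
#' `<wildtype AA><1-based position><mutant AA>`, e.g. `"A23G:T45K"`. The empty
#' string denotes the wildtype itself (degree 0).
#'
#' @param mutant a single mutation string.
#' @return data.frame with columns `wt_aa`, `pos` (integer), `mut_aa`, ordered
#'   by position; zero rows for the wildtype.
#' @export
parse_mutations <- function(mutant) {
  stopifnot(is.character(mutant), length(mutant) == 1L, !is.na(mutant))
  if (!nzchar(mutant)) {
    return(data.frame(wt_aa = character(), pos = integer(),
                      mut_aa = character(), stringsAsFactors = FALSE))
  }
  toks <- strsplit(mutant, ":", fixed = TRUE)[[1L]]
  m <- regmatches(toks, regexec("^([A-Z\\-])([0-9]+)([A-Z\\-])$", toks))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed substitution token(s): ", paste(toks[bad], collapse = ", "))
  }
  out <- data.frame(
    wt_aa  = vapply(m, `[`, "", 2L),
    pos    = as.integer(vapply(m, `[`, "", 3L)),
    mut_aa = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  out[order(out$pos), , drop = FALSE]
}

#' Format a substitution table back into a mutation string
#' @param subs data.frame as returned by [parse_mutations()].
#' @return a single mutation string (empty for the wildtype).
#' @export
format_mutations <- function(subs) {
  if (nrow(subs) == 0L) return("")
  subs <- subs[order(subs$pos), , drop = FALSE]
  paste(paste0(subs$wt_aa, subs$pos, subs$mut_aa), collapse = ":")
}

#' Mutation degree of each variant
#' @param variants character vector of mutation strings.
#' @return integer vector; 0 for the wildtype.
#' @export
variant_degree <- function(variants) {
  ifelse(nzchar(variants),
         lengths(strsplit(variants, ":", fixed = TRUE)),
         0L)
}

#' Validate variants against a wildtype sequence
#'
#' Checks, for every variant, that positions are within `[1, L]` and strictly
#' increasing, that the recorded wildtype residue matches the sequence, and
#' that the mutant residue differs from the wildtype residue.
#'
#' @param variants character vector of mutation strings.
#' @param wildtype wildtype amino-acid sequence (single string).
#' @return invisibly `TRUE`; stops on the first invalid variant.
#' @export
validate_variants <- function(variants, wildtype) {
  wt <- strsplit(wildtype, "")[[1L]]
  L <- length(wt)
  for (v in variants) {
    subs <- parse_mutations(v)
    if (nrow(subs) == 0L) next
    if (any(subs$pos < 1L | subs$pos > L)) {
      stop("variant '", v, "': position outside [1, ", L, "]")
    }
    if (anyDuplicated(subs$pos)) {
      stop("variant '", v, "': repeated position")
    }
    if (any(wt[subs$pos] != subs$wt_aa)) {
      stop("variant '", v, "': wildtype residue mismatch")
    }
    if (any(subs$mut_aa == subs$wt_aa)) {
      stop("variant '", v, "': mutant residue equals wildtype")
    }
  }
  invisible(TRUE)
}

#' Apply a variant's substitutions to the wildtype sequence
#' @param variants character vector of mutation strings.
#' @param wildtype wildtype sequence.
#' @return character vector of full mutated sequences.
#' @export
mutate_sequence <- function(variants, wildtype) {
  wt <- strsplit(wildtype, "")[[1L]]
  vapply(variants, function(v) {
    s <- wt
    subs <- parse_mutations(v)
    if (nrow(subs)) s[subs$pos] <- subs$mut_aa
    paste(s, collapse = "")
  }, "", USE.NAMES = FALSE)
}
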