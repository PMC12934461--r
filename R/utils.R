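`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce reference sequences to a named DNAStringSet
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector, or a path
#' to a FASTA file. Sequences are uppercased; only A/C/G/T/N are permitted.
#'
#' @param refs reference sequences in any of the accepted forms.
#' @return a named `DNAStringSet`.
#' @export
as_reference_set <- function(refs) {
  if (methods::is(refs, "DNAStringSet")) {
    out <- refs
  } else if (is.character(refs) && length(refs) == 1L && file.exists(refs)) {
    out <- Biostrings::readDNAStringSet(refs)
    # FASTA headers may carry descriptions after the first token
    names(out) <- vapply(strsplit(names(out), "\\s+"), `[`, "", 1L)
  } else if (is.character(refs)) {
    if (is.null(names(refs))) {
      names(refs) <- paste0("chr", seq_along(refs))
    }
    out <- Biostrings::DNAStringSet(toupper(refs))
  } else {
    stop("unsupported reference input; give a DNAStringSet, named character vector or FASTA path")
  }
  bad <- grepl("[^ACGTN]", as.character(out))
  if (any(bad)) {
    stop("reference sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(out)[bad], collapse = ", "))
  }
  if (any(Biostrings::width(out) < 1L)) stop("empty reference sequence")
  out
}

# Stop unless all named conditions hold; names become the error message.
stopifnot_named <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(all(conds[[nm]]))) stop(nm, call. = FALSE)
  }
  invisible(TRUE)
}
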