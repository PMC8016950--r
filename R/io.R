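# File-format helpers shared across modules.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Serialize a numbered V-region to JSON
#'
#' The JSON form is a list of `[label, aa]` pairs plus chain kind and source,
#' and round-trips through [vregion_from_json()].
#'
#' @param region a [numbered_vregion()].
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
vregion_to_json <- function(region, path = NULL) {
  stopifnot(inherits(region, "numbered_vregion"))
  obj <- list(
    chain_kind = region$chain_kind,
    source_id = region$source_id,
    residues = Map(function(l, a) list(l, a), region$labels, region$aa)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a numbered V-region from JSON
#' @param x JSON string or path to a JSON file.
#' @return a [numbered_vregion()].
#' @export
vregion_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  numbered_vregion(
    chain_kind = obj$chain_kind,
    labels = unname(vapply(obj$residues, `[[`, "", 1L)),
    aa = unname(vapply(obj$residues, `[[`, "", 2L)),
    source_id = obj$source_id
  )
}
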