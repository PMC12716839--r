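#' @include AllClasses.R utils.R
NULL

#' Construct a Proteome from sequences
#'
#' @param seqs an \code{AAStringSet} or named character vector of amino-acid
#'   sequences. Stop characters (\code{*}) are stripped, lowercase letters
#'   uppercased, and non-canonical residues (B, Z, U, O) mapped to X with a
#'   warning.
#' @param species species label.
#' @param source \code{"genome"} or \code{"transcriptome"}.
#' @return a \linkS4class{Proteome}.
#' @export
Proteome <- function(seqs, species, source = c("genome", "transcriptome")) {
  source <- match.arg(source)
  if (!is(seqs, "AAStringSet")) {
    nm <- names(seqs)
    seqs <- Biostrings::AAStringSet(unname(as.character(seqs)))
    names(seqs) <- nm
  }
  chars <- as.character(seqs)
  chars <- toupper(gsub("*", "", chars, fixed = TRUE))
  out <- Biostrings::AAStringSet(chars)
  names(out) <- names(seqs)
  out <- canonicalizeAA(out)
  new("Proteome", out, speciesName = species, provenance = source)
}

#' Read a predicted proteome from a FASTA file
#'
#' One record per FASTA entry, order preserved. Headers are truncated at the
#' first whitespace token; duplicate headers are a hard error naming the
#' offending header. Stop characters are stripped and lowercase residues
#' uppercased.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param species species label for all records.
#' @param source \code{"genome"} or \code{"transcriptome"}.
#' @return a \linkS4class{Proteome}; an empty file yields an empty Proteome
#'   with a warning.
#' @export
readProteome <- function(path, species, source = c("genome", "transcriptome")) {
  source <- match.arg(source)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    warning("no sequences in ", path, call. = FALSE)
    return(new("Proteome", Biostrings::AAStringSet(),
               speciesName = species, provenance = source))
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", "))
  Proteome(seqs, species, source)
}

#' Write a Proteome (or any AAStringSet) as wrapped FASTA
#'
#' @param x sequences to write.
#' @param path output path; lines wrapped at 60 columns.
#' @export
writeProteome <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(as.character(x)),
                              path, width = 60L)
  invisible(path)
}

#' Collapse exact duplicate records across screens
#'
#' Records with identical (species, sequence) are collapsed to the
#' first-seen id; every collapse is logged. This is how candidates recovered
#' independently by the family-profile screen and the topology screen are
#' merged into a unique candidate set. Identical sequences from different
#' species are never merged. With \code{key = "id"} duplicates are matched
#' on (species, id) instead, a fallback for records whose sequences differ
#' by trailing ambiguity characters.
#'
#' @param seqs an \code{AAStringSet} with unique names.
#' @param species character vector, one species per record.
#' @param key \code{"sequence"} (default) or \code{"id"}.
#' @return list with \code{kept} (AAStringSet), \code{species} (for the kept
#'   records) and \code{mergedPairs} (data.frame duplicate_id, kept_id).
#' @export
dedupExact <- function(seqs, species, key = c("sequence", "id")) {
  key <- match.arg(key)
  stopifnot(length(seqs) == length(species))
  tag <- if (key == "sequence") paste0(species, "\r", as.character(seqs))
         else paste0(species, "\r", names(seqs))
  first <- !duplicated(tag)
  keptIdOf <- names(seqs)[first][match(tag, tag[first])]
  mergedPairs <- data.frame(duplicate_id = names(seqs)[!first],
                            kept_id = keptIdOf[!first],
                            stringsAsFactors = FALSE)
  list(kept = seqs[first], species = species[first],
       mergedPairs = mergedPairs)
}
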