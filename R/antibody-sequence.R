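#' Create an antibody variable-domain sequence
#'
#' Lightweight container for a single variable-domain amino-acid sequence.
#' The alphabet is restricted to the twenty standard one-letter codes plus
#' \code{X} for nonstandard residues.
#'
#' @param id Character identifier.
#' @param chain_class One of \code{"heavy"}, \code{"kappa"}, \code{"lambda"}.
#' @param residues One-letter amino-acid string (uppercase).
#' @param source_tag Optional free-text provenance tag.
#' @return An object of class \code{AntibodySequence}.
#' @export
#' @examples
#' antibody_sequence("toy", "kappa", "DIQMTQSPSS")
antibody_sequence <- function(id, chain_class = c("heavy", "kappa", "lambda"),
                              residues, source_tag = "") {
  chain_class <- match.arg(chain_class)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(residues)
  validate_residues(residues, paste0("sequence '", id, "'"))
  structure(list(id = id, chain_class = chain_class, residues = residues,
                 source_tag = source_tag),
            class = "AntibodySequence")
}

#' @export
print.AntibodySequence <- function(x, ...) {
  cat(sprintf("AntibodySequence %s [%s], %d aa\n", x$id, x$chain_class,
              nchar(x$residues)))
  cat(" ", x$residues, "\n")
  invisible(x)
}

#' Read antibody sequences from FASTA
#'
#' Headers are parsed as \code{id|chain_class|source_tag}; a header without
#' the pipe-delimited fields must be accompanied by an explicit
#' \code{chain_class} argument.
#'
#' @param path FASTA file.
#' @param chain_class Fallback chain class when not encoded in the header.
#' @return A list of \code{AntibodySequence} objects.
#' @export
read_antibody_fasta <- function(path, chain_class = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    cls <- if (length(parts) >= 2L) parts[2] else chain_class
    if (is.null(cls))
      stop("header '", header, "' does not encode a chain class and none ",
           "was supplied", call. = FALSE)
    antibody_sequence(id = trimws(parts[1]), chain_class = trimws(cls),
                      residues = as.character(set[[i]]),
                      source_tag = if (length(parts) >= 3L)
                        trimws(paste(parts[-(1:2)], collapse = "|")) else "")
  })
}

#' Write antibody sequences to FASTA
#'
#' @param seqs A list of \code{AntibodySequence} objects.
#' @param path Output file.
#' @export
write_antibody_fasta <- function(seqs, path) {
  if (inherits(seqs, "AntibodySequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, function(s)
    paste(s$id, s$chain_class, s$source_tag, sep = "|"), "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load the bundled synthetic parental antibody chains
#'
#' The bundled parental heavy/light pair is a synthetic stand-in for a
#' murine anti-HLA-DR antibody: an IGHV2-type heavy framework carrying
#' Kabat H-K71/H-V78 and an IGKV9-type kappa framework carrying L-K60/L-R66,
#' the framework residues whose reversion this toolkit is designed to
#' propose. See the package README for provenance caveats.
#'
#' @return A list with elements \code{heavy} and \code{light}.
#' @export
parental_antibody <- function() {
  seqs <- read_antibody_fasta(extdata_path("parental_synthetic.fasta"))
  list(heavy = seqs[[1]], light = seqs[[2]])
}
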