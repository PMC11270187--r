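# Framework ranking, CDR grafting and back-mutation bookkeeping.

#' Read a germline framework library from FASTA
#'
#' Headers are parsed as \code{gene_name|chain_class|source_tag}. The
#' bundled default carries the three human heavy (IGHV4-59, IGHV2-26,
#' IGHV4-4) and three human kappa (IGKV1-16, IGKV1-39, IGKV1-6) genes used
#' as acceptor scaffolds, plus two murine-type entries; the bundled
#' sequences are curated approximations / synthetic stand-ins (see README)
#' and users should supply their own verified library for real campaigns.
#'
#' @param path FASTA file; default is the bundled library.
#' @return A list of \code{AntibodySequence} entries with unique ids.
#' @export
read_germline_library <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("germline_library_synthetic.fasta")
  lib <- read_antibody_fasta(path)
  ids <- vapply(lib, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate gene names in germline library: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lib
}

#' Rank germline frameworks by framework-region identity
#'
#' Identity is computed over framework positions only (CDRs excluded under
#' the scheme's boundary table), with the denominator being the aligned
#' framework positions present in both chains. Ties are broken by more
#' aligned positions, then lexicographic gene name.
#'
#' @param parental A \code{NumberedChain} for the parental chain.
#' @param library List of \code{AntibodySequence} germline entries
#'   (see \code{\link{read_germline_library}}).
#' @param top_k Number of entries to return (default: all).
#' @return A \code{FrameworkRanking} data frame: \code{gene_name},
#'   \code{framework_identity}, \code{aligned_length}, \code{source_tag},
#'   sorted descending by identity.
#' @export
#' @examples
#' p <- parental_antibody()
#' nc <- number_sequence(p$heavy, "imgt")
#' rank_frameworks(nc, read_germline_library())
rank_frameworks <- function(parental, library, top_k = NULL) {
  stopifnot(inherits(parental, "NumberedChain"))
  cls <- parental$source$chain_class
  library <- Filter(function(e) e$chain_class == cls, library)
  if (length(library) == 0L)
    stop("library holds no entries of chain class ", cls, call. = FALSE)
  pfr <- parental$positions[!is_cdr(parental$positions$region), ]
  rows <- lapply(library, function(entry) {
    nc <- number_sequence(entry, parental$scheme)
    efr <- nc$positions[!is_cdr(nc$positions$region), ]
    common <- merge(pfr[, c("label", "aa")], efr[, c("label", "aa")],
                    by = "label", suffixes = c("_p", "_e"))
    data.frame(gene_name = entry$id,
               framework_identity = mean(common$aa_p == common$aa_e),
               aligned_length = nrow(common),
               source_tag = entry$source_tag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$framework_identity, -out$aligned_length, out$gene_name)
  out <- out[ord, , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  structure(out, parental = parental$source$id, scheme = parental$scheme,
            class = c("FrameworkRanking", "data.frame"))
}

fr4_consensus <- function(chain_class) {
  j <- read_bundled_csv("j_consensus.csv")
  j$fr4[j$chain_class == chain_class]
}

#' Graft parental CDRs onto an acceptor framework
#'
#' Builds the humanized chain: framework regions from the acceptor, CDRs
#' (under the supplied boundary table's scheme) from the parental chain.
#' Germline V genes end before FR4; when the acceptor lacks FR4 a curated
#' human J-segment consensus for the chain class is used.
#'
#' @param parental \code{NumberedChain} donating the CDRs.
#' @param acceptor \code{AntibodySequence} (e.g., a germline library entry)
#'   donating the framework.
#' @param table \code{CdrBoundaryTable} defining the CDRs to transplant;
#'   its scheme must match \code{parental$scheme}.
#' @return A \code{NumberedChain} for the grafted chain, numbered in the
#'   table's scheme, with attribute \code{acceptor_gene}.
#' @export
graft <- function(parental, acceptor, table = NULL) {
  stopifnot(inherits(parental, "NumberedChain"),
            inherits(acceptor, "AntibodySequence"))
  if (is.null(table))
    table <- cdr_boundary_table(parental$scheme, parental$source$chain_class)
  if (attr(table, "scheme") != parental$scheme)
    stop("boundary table scheme does not match parental scheme", call. = FALSE)
  donor <- extract_regions(parental, table)
  acc_nc <- number_sequence(acceptor, parental$scheme)
  acc_reg <- region_of(acc_nc$positions$number, acc_nc$positions$ins, table)
  acc <- lapply(REGIONS, function(r)
    paste(acc_nc$positions$aa[acc_reg == r], collapse = ""))
  names(acc) <- REGIONS
  if (!nzchar(acc$FR4)) acc$FR4 <- fr4_consensus(acceptor$chain_class)
  for (fr in c("FR1", "FR2", "FR3", "FR4"))
    if (!nzchar(acc[[fr]]))
      stop("acceptor '", acceptor$id, "' is missing framework region ", fr,
           call. = FALSE)
  seq <- paste0(acc$FR1, donor$CDR1, acc$FR2, donor$CDR2, acc$FR3,
                donor$CDR3, acc$FR4)
  out <- number_sequence(
    antibody_sequence(paste0(parental$source$id, "/", acceptor$id),
                      acceptor$chain_class, seq,
                      source_tag = paste0("graft of ", parental$source$id,
                                          " CDRs (", parental$scheme,
                                          ") onto ", acceptor$id)),
    parental$scheme)
  attr(out, "acceptor_gene") <- acceptor$id
  out
}

#' Build a combinatorial panel of humanized candidates
#'
#' Pairs every grafted heavy chain with every grafted light chain in
#' heavy-major order with deterministic version tags
#' \code{{prefix}H{i}L{j}}.
#'
#' @param heavy_variants,light_variants Non-empty lists of
#'   \code{NumberedChain} grafts (see \code{\link{graft}}).
#' @param tag_prefix Version tag prefix.
#' @return List of \code{GraftCandidate} objects: \code{version_tag},
#'   \code{heavy}, \code{light}, \code{cdr_scheme_used},
#'   \code{acceptor_genes}, \code{back_mutations} (empty ledger).
#' @export
build_panel <- function(heavy_variants, light_variants, tag_prefix = "V") {
  if (length(heavy_variants) == 0L || length(light_variants) == 0L)
    stop("heavy and light variant lists must be non-empty", call. = FALSE)
  out <- list()
  for (i in seq_along(heavy_variants)) {
    for (j in seq_along(light_variants)) {
      h <- heavy_variants[[i]]; l <- light_variants[[j]]
      stopifnot(inherits(h, "NumberedChain"), inherits(l, "NumberedChain"))
      cand <- structure(
        list(version_tag = sprintf("%sH%dL%d", tag_prefix, i, j),
             heavy = h, light = l,
             cdr_scheme_used = h$scheme,
             acceptor_genes = c(heavy = attr(h, "acceptor_gene") %||% h$source$id,
                                light = attr(l, "acceptor_gene") %||% l$source$id),
             back_mutations = empty_back_mutations()),
        class = "GraftCandidate")
      out[[cand$version_tag]] <- cand
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_back_mutations <- function() {
  data.frame(chain = character(), position = character(),
             from_aa = character(), to_aa = character(),
             stringsAsFactors = FALSE)
}

#' Describe a framework back-mutation
#'
#' @param chain \code{"heavy"} or \code{"light"}.
#' @param position Scheme position label (e.g., \code{"71"}, \code{"82A"}).
#' @param from_aa Residue expected in the humanized candidate.
#' @param to_aa Parental residue to restore.
#' @return One-row back-mutation data frame.
#' @export
back_mutation <- function(chain = c("heavy", "light"), position, from_aa, to_aa) {
  chain <- match.arg(chain)
  data.frame(chain = chain, position = as.character(position),
             from_aa = toupper(from_aa), to_aa = toupper(to_aa),
             stringsAsFactors = FALSE)
}

#' Apply framework back-mutations to a graft candidate
#'
#' Each mutation's \code{from_aa} must match the candidate's current residue
#' at that scheme position; residues are replaced and the candidate's
#' back-mutation ledger is appended, preserving full provenance.
#'
#' @param candidate A \code{GraftCandidate}.
#' @param mutations Data frame of rows from \code{\link{back_mutation}}
#'   (may be empty).
#' @return The modified \code{GraftCandidate}.
#' @export
apply_back_mutations <- function(candidate, mutations) {
  stopifnot(inherits(candidate, "GraftCandidate"))
  if (is.null(mutations) || nrow(mutations) == 0L) return(candidate)
  for (k in seq_len(nrow(mutations))) {
    mut <- mutations[k, ]
    slot <- if (mut$chain == "heavy") "heavy" else "light"
    nc <- candidate[[slot]]
    hit <- which(nc$positions$label == mut$position)
    if (length(hit) != 1L)
      stop("position ", mut$position, " not found in ", slot,
           " chain of ", candidate$version_tag, call. = FALSE)
    found <- nc$positions$aa[hit]
    if (found != mut$from_aa)
      stop("back-mutation mismatch at ", slot, " position ", mut$position,
           ": expected ", mut$from_aa, ", found ", found, call. = FALSE)
    nc$positions$aa[hit] <- mut$to_aa
    nc$source$residues <- chain_sequence(nc)
    candidate[[slot]] <- nc
  }
  candidate$back_mutations <- rbind(candidate$back_mutations, mutations)
  candidate
}

#' @export
print.GraftCandidate <- function(x, ...) {
  cat(sprintf("GraftCandidate %s (%s CDRs; acceptors %s / %s; %d back-mutation%s)\n",
              x$version_tag, x$cdr_scheme_used, x$acceptor_genes[["heavy"]],
              x$acceptor_genes[["light"]], nrow(x$back_mutations),
              if (nrow(x$back_mutations) == 1L) "" else "s"))
  invisible(x)
}

#' Write a candidate panel to FASTA
#'
#' One record per chain; headers carry the version tag, chain class,
#' acceptor gene and back-mutation ledger.
#'
#' @param panel List of \code{GraftCandidate}s from \code{\link{build_panel}}.
#' @param path Output FASTA.
#' @export
write_panel_fasta <- function(panel, path) {
  seqs <- list()
  for (cand in panel) {
    for (slot in c("heavy", "light")) {
      nc <- cand[[slot]]
      bm <- cand$back_mutations[cand$back_mutations$chain == slot, ]
      ledger <- if (nrow(bm)) paste(sprintf("%s%s%s", bm$from_aa, bm$position,
                                            bm$to_aa), collapse = ",")
                else "none"
      seqs[[length(seqs) + 1L]] <- antibody_sequence(
        paste0(cand$version_tag, "_", slot), nc$source$chain_class,
        chain_sequence(nc),
        source_tag = paste0("acceptor=", cand$acceptor_genes[[slot]],
                            ";cdr_scheme=", cand$cdr_scheme_used,
                            ";back_mutations=", ledger))
    }
  }
  write_antibody_fasta(seqs, path)
}
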