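# The decision procedure: combine framework sequence differences with
# interface evidence (per-residue BSA, typed contacts) and Vernier-zone
# annotation to propose back-mutations, flagging sterically coupled
# position pairs.

#' Bundled Vernier-zone position table
#'
#' Framework positions (Kabat numbering) that underlie the CDR loops and
#' indirectly shape the paratope; the canonical published list, shipped as
#' packaged data with its citation.
#'
#' @param chain_class \code{"heavy"}, \code{"kappa"} or \code{"lambda"}.
#' @return A \code{VernierTable} data frame: \code{position},
#'   \code{scheme}, \code{chain_class}, \code{provenance}.
#' @export
vernier_table <- function(chain_class = c("heavy", "kappa", "lambda")) {
  chain_class <- match.arg(chain_class)
  all <- read_bundled_csv("vernier_zone.csv")
  out <- all[all$chain_class == chain_class, ]
  rownames(out) <- NULL
  structure(out, class = c("VernierTable", "data.frame"))
}

#' Framework differences between a parental and a humanized chain
#'
#' Positions are compared by scheme label; only framework positions present
#' in both chains and carrying different residues are returned. CDR
#' differences are excluded by construction.
#'
#' @param parental,humanized \code{NumberedChain}s in the same scheme and
#'   chain class.
#' @return Data frame: \code{position}, \code{region},
#'   \code{parental_aa}, \code{humanized_aa}.
#' @export
diff_framework <- function(parental, humanized) {
  stopifnot(inherits(parental, "NumberedChain"),
            inherits(humanized, "NumberedChain"))
  if (parental$scheme != humanized$scheme)
    stop("scheme mismatch: ", parental$scheme, " vs ", humanized$scheme,
         call. = FALSE)
  if (parental$source$chain_class != humanized$source$chain_class)
    stop("chain class mismatch", call. = FALSE)
  p <- parental$positions[!is_cdr(parental$positions$region), ]
  h <- humanized$positions[!is_cdr(humanized$positions$region), ]
  m <- merge(p[, c("label", "region", "aa")], h[, c("label", "aa")],
             by = "label", suffixes = c("_p", "_h"))
  m <- m[m$aa_p != m$aa_h, ]
  pp <- parse_position_label(m$label)
  m <- m[order(position_key(pp$number, pp$ins)), ]
  out <- data.frame(position = m$label, region = m$region,
                    parental_aa = m$aa_p, humanized_aa = m$aa_h,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Cbeta (Calpha for glycine) coordinate per scheme position, using a
# region-annotated structure chain mapping (see map_chain_regions)
cbeta_by_label <- function(model, chain_id, numbered, map_by = "sequence") {
  mp <- map_chain_regions(model, chain_id, numbered, by = map_by)
  a <- model$atoms[model$atoms$chain == chain_id, ]
  out <- matrix(NA_real_, nrow(mp), 3,
                dimnames = list(mp$label, c("x", "y", "z")))
  for (i in seq_len(nrow(mp))) {
    sel <- a$resno == mp$resno[i] & a$ins == mp$ins[i]
    cb <- a[sel & a$elety == "CB", c("x", "y", "z")]
    if (nrow(cb) == 0L) cb <- a[sel & a$elety == "CA", c("x", "y", "z")]
    if (nrow(cb) >= 1L) out[i, ] <- as.numeric(cb[1L, ])
  }
  out
}

#' Propose framework back-mutations
#'
#' A framework difference becomes a proposal if (a) the parental residue
#' buries at least \code{bsa_threshold} Angstrom^2 at the antigen interface
#' or makes at least one cross-interface contact (evidence
#' \code{direct_contact}), or (b) its position is in the Vernier-zone table
#' (evidence \code{vernier}); positions satisfying both are classed
#' \code{contact_and_vernier}. When a parental structure is supplied,
#' Vernier proposals within \code{couple_dist} (Cbeta-Cbeta) of another
#' differing framework position pull that position in as a coupled partner
#' (the heavy-chain 71/78 steric-pair effect), recorded in
#' \code{partner_note}.
#'
#' Proposals are ranked contact_and_vernier first, then direct_contact by
#' BSA, then vernier.
#'
#' @param parental,humanized \code{NumberedChain}s (same chain class).
#'   Non-Kabat chains are renumbered to Kabat internally, since the Vernier
#'   table is defined in Kabat numbering.
#' @param report Optional \code{InterfaceReport} of the parental
#'   antibody-antigen complex, region-annotated so its residues map to
#'   parental scheme labels (see \code{\link{interface_bsa}}).
#' @param vernier A \code{VernierTable}; default bundled table for the
#'   chain class.
#' @param bsa_threshold Direct-contact BSA threshold, Angstrom^2
#'   (default 10).
#' @param structure,chain_id Optional parental structure and the chain id
#'   of this chain in it, for coupled-position detection.
#' @param couple_dist Cbeta-Cbeta coupling cutoff, Angstrom (default 8).
#' @param map_by Residue correspondence mode for \code{structure}.
#' @return A \code{BackMutationProposalSet} data frame: \code{position},
#'   \code{parental_aa}, \code{humanized_aa}, \code{evidence}, \code{bsa},
#'   \code{n_contacts}, \code{partner_note}, \code{rank}.
#' @export
propose_back_mutations <- function(parental, humanized, report = NULL,
                                   vernier = NULL, bsa_threshold = 10,
                                   structure = NULL, chain_id = NULL,
                                   couple_dist = 8, map_by = "sequence") {
  if (parental$scheme != "kabat") parental <- renumber(parental, "kabat")
  if (humanized$scheme != "kabat") humanized <- renumber(humanized, "kabat")
  cls <- parental$source$chain_class
  if (is.null(vernier)) vernier <- vernier_table(cls)
  diffs <- diff_framework(parental, humanized)

  bsa_of <- function(label) {
    if (is.null(report)) return(NA_real_)
    pr <- report$per_residue
    if (is.null(pr$label)) return(NA_real_)
    hit <- which(!is.na(pr$label) & pr$label == label)
    if (!length(hit)) return(NA_real_)
    sum(pr$bsa[hit])
  }
  ncontacts_of <- function(label) {
    if (is.null(report) || is.null(report$contacts)) return(NA_integer_)
    pr <- report$per_residue
    hit <- which(!is.na(pr$label) & pr$label == label)
    if (!length(hit)) return(NA_integer_)
    sum(vapply(hit, function(i)
      nrow(contacts_for_residue(report$contacts, pr$chain[i], pr$resno[i],
                                pr$ins[i])), integer(1)))
  }

  rows <- lapply(seq_len(nrow(diffs)), function(i) {
    d <- diffs[i, ]
    bsa <- bsa_of(d$position)
    nct <- ncontacts_of(d$position)
    direct <- (!is.na(bsa) && bsa >= bsa_threshold) ||
      (!is.na(nct) && nct >= 1L)
    in_vz <- d$position %in% vernier$position
    if (!direct && !in_vz) return(NULL)
    evidence <- if (direct && in_vz) "contact_and_vernier"
                else if (direct) "direct_contact" else "vernier"
    data.frame(position = d$position, parental_aa = d$parental_aa,
               humanized_aa = d$humanized_aa, evidence = evidence,
               bsa = bsa, n_contacts = nct, partner_note = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = character(), parental_aa = character(),
                      humanized_aa = character(), evidence = character(),
                      bsa = numeric(), n_contacts = integer(),
                      partner_note = character(), rank = integer(),
                      stringsAsFactors = FALSE)

  # coupled-position notes: Vernier-evidence proposals near another
  # differing framework position in the parental structure
  if (nrow(out) && !is.null(structure) && !is.null(chain_id)) {
    cb <- cbeta_by_label(structure, chain_id, parental, map_by = map_by)
    vz_rows <- which(out$evidence %in% c("vernier", "contact_and_vernier"))
    for (i in vz_rows) {
      p1 <- out$position[i]
      if (!p1 %in% rownames(cb) || anyNA(cb[p1, ])) next
      for (p2 in setdiff(diffs$position, p1)) {
        if (!p2 %in% rownames(cb) || anyNA(cb[p2, ])) next
        if (sqrt(sum((cb[p1, ] - cb[p2, ])^2)) <= couple_dist) {
          note <- paste0("coupled with position ", p1,
                         " (Cbeta within ", couple_dist, " A)")
          j <- which(out$position == p2)
          if (length(j)) {
            out$partner_note[j] <- note
          } else {
            d <- diffs[diffs$position == p2, ]
            out <- rbind(out, data.frame(
              position = d$position, parental_aa = d$parental_aa,
              humanized_aa = d$humanized_aa, evidence = "vernier",
              bsa = bsa_of(d$position), n_contacts = ncontacts_of(d$position),
              partner_note = note, stringsAsFactors = FALSE))
          }
        }
      }
    }
  }

  if (nrow(out)) {
    ev_rank <- match(out$evidence,
                     c("contact_and_vernier", "direct_contact", "vernier"))
    ord <- order(ev_rank, -ifelse(is.na(out$bsa), -Inf, out$bsa),
                 position_key(parse_position_label(out$position)$number,
                              parse_position_label(out$position)$ins))
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
  }
  rownames(out) <- NULL
  structure(out, chain_class = cls, bsa_threshold = bsa_threshold,
            vernier_provenance = unique(vernier$provenance),
            class = c("BackMutationProposalSet", "data.frame"))
}

#' Convert proposals to applicable back-mutations
#'
#' @param proposals A \code{BackMutationProposalSet}.
#' @param chain \code{"heavy"} or \code{"light"}: which chain of a
#'   \code{GraftCandidate} these apply to.
#' @return Data frame accepted by \code{\link{apply_back_mutations}}
#'   (reverting humanized residues to parental).
#' @export
as_back_mutations <- function(proposals, chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  if (nrow(proposals) == 0L) return(empty_back_mutations())
  do.call(rbind, lapply(seq_len(nrow(proposals)), function(i)
    back_mutation(chain, proposals$position[i], proposals$humanized_aa[i],
                  proposals$parental_aa[i])))
}

#' Write a proposal report as JSON
#'
#' @param proposals A \code{BackMutationProposalSet}.
#' @param path Output file.
#' @export
write_proposals_json <- function(proposals, path) {
  obj <- list(chain_class = attr(proposals, "chain_class"),
              bsa_threshold = attr(proposals, "bsa_threshold"),
              vernier_provenance = attr(proposals, "vernier_provenance"),
              boundary_table = "bundled cdr_boundaries.csv (canonical Kabat definitions)",
              proposals = as.data.frame(proposals))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
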