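# Geometric contact detection across a chain partition: salt bridges,
# hydrogen bonds, hydrophobic contacts and van der Waals contacts, typed
# with precedence salt_bridge > hbond > hydrophobic > vdw.

#' Contact detection cutoffs
#'
#' Defaults follow common practice for heavy-atom geometric criteria:
#' hydrogen bond donor-acceptor distance <= 3.5 A (with a >= 100 degree
#' donor angle when hydrogens are present; distance-only otherwise), salt
#' bridge charged-group centroid distance <= 4.5 A, apolar carbon-carbon
#' contacts <= 4.0 A, van der Waals contacts within the radius sum + 0.5 A.
#'
#' @param hbond_dist,salt_dist,hydrophobic_dist Cutoffs in Angstrom.
#' @param vdw_slack Added to the van der Waals radius sum, Angstrom.
#' @param hbond_angle Minimum donor angle in degrees (used only when
#'   hydrogens are present in the model).
#' @return Named list of cutoffs.
#' @export
default_contact_config <- function(hbond_dist = 3.5, salt_dist = 4.5,
                                   hydrophobic_dist = 4.0, vdw_slack = 0.5,
                                   hbond_angle = 100) {
  list(hbond_dist = hbond_dist, salt_dist = salt_dist,
       hydrophobic_dist = hydrophobic_dist, vdw_slack = vdw_slack,
       hbond_angle = hbond_angle)
}

# charged side-chain groups (heavy atoms)
CHARGED_GROUPS <- list(
  LYS = list(atoms = "NZ", sign = +1),
  ARG = list(atoms = c("NE", "NH1", "NH2"), sign = +1),
  HIS = list(atoms = c("ND1", "NE2"), sign = +1),
  ASP = list(atoms = c("OD1", "OD2"), sign = -1),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1))

# hydrogen-bond capable heavy atoms: donors carry at least one polar H,
# acceptors carry a lone pair; several atoms are both
HB_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG")
HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD",
  CYS = "SG")

# apolar carbons: side-chain carbons bonded only to carbon/hydrogen
APOLAR_CARBONS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  PRO = c("CB", "CG", "CD"), MET = "CB",
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), ASP = "CB", GLN = c("CB", "CG"), ASN = "CB",
  THR = "CG2", HIS = "CB")

atom_in_set <- function(resid, elety, set, include_backbone = FALSE) {
  out <- logical(length(resid))
  if (include_backbone && !is.null(set$backbone))
    out <- out | elety %in% set$backbone
  for (rn in setdiff(names(set), "backbone"))
    out <- out | (resid == rn & elety %in% set[[rn]])
  out
}

is_backbone_n_donor <- function(resid, elety) elety == "N" & resid != "PRO"

#' Detect typed contacts across the chain partition
#'
#' All heavy-atom pairs with one atom on each side of the partition are
#' examined. Each atom pair is assigned the first matching type in the
#' precedence order salt_bridge > hbond > hydrophobic > vdw; salt bridges
#' are detected at the charged-group level (centroid distance) and reported
#' on the closest atom pair of the two groups. Output order is
#' deterministic (by side-A chain/residue/atom, then side-B).
#'
#' @param model A \code{StructureModel} with a two-group chain partition.
#' @param config Cutoffs from \code{\link{default_contact_config}}.
#' @return Data frame of contacts: \code{type}, atom descriptors for both
#'   sides, \code{distance} (Angstrom).
#' @export
detect_contacts <- function(model, config = default_contact_config()) {
  stopifnot(inherits(model, "StructureModel"))
  ca <- side_chains(model, 1L)
  cb <- side_chains(model, 2L)
  a <- model$atoms
  a <- a[!a$element %in% c("H", "D"), ]
  ia <- which(a$chain %in% ca)
  ib <- which(a$chain %in% cb)
  empty <- data.frame(type = character(),
                      chain_a = character(), resno_a = integer(),
                      ins_a = character(), resid_a = character(),
                      atom_a = character(),
                      chain_b = character(), resno_b = integer(),
                      ins_b = character(), resid_b = character(),
                      atom_b = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(ia) || !length(ib)) return(empty)
  max_cut <- max(config$salt_dist, config$hbond_dist,
                 config$hydrophobic_dist, 2 * max(a$radius) + config$vdw_slack)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # all cross pairs within the largest cutoff
  d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
              rowSums(xyz[ib, , drop = FALSE]^2), "+") -
    2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
  hit <- which(d2 <= max_cut^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  pi_ <- ia[hit[, 1]]
  pj_ <- ib[hit[, 2]]
  dist <- sqrt(pmax(d2[hit], 0))

  type <- rep(NA_character_, length(pi_))

  # --- salt bridges at group level ---
  grp_of <- function(idx) {
    res <- a[idx, ]
    g <- rep(NA_character_, length(idx))
    for (rn in names(CHARGED_GROUPS))
      g[res$resid == rn & res$elety %in% CHARGED_GROUPS[[rn]]$atoms] <-
        paste(res$chain, res$resno, res$ins, rn, sep = "|")[
          res$resid == rn & res$elety %in% CHARGED_GROUPS[[rn]]$atoms]
    g
  }
  sign_of <- function(resid) {
    s <- rep(0L, length(resid))
    for (rn in names(CHARGED_GROUPS))
      s[resid == rn] <- CHARGED_GROUPS[[rn]]$sign
    s
  }
  ga <- grp_of(pi_); gb <- grp_of(pj_)
  charged_pair <- !is.na(ga) & !is.na(gb) &
    sign_of(a$resid[pi_]) * sign_of(a$resid[pj_]) == -1L
  if (any(charged_pair)) {
    pair_id <- paste(ga, gb)
    for (pid in unique(pair_id[charged_pair])) {
      rows <- which(pair_id == pid & charged_pair)
      gA <- ga[rows[1]]; gB <- gb[rows[1]]
      partsA <- strsplit(gA, "|", fixed = TRUE)[[1]]
      partsB <- strsplit(gB, "|", fixed = TRUE)[[1]]
      selA <- a$chain == partsA[1] & a$resno == as.integer(partsA[2]) &
        a$ins == partsA[3] & a$resid == partsA[4] &
        a$elety %in% CHARGED_GROUPS[[partsA[4]]]$atoms
      selB <- a$chain == partsB[1] & a$resno == as.integer(partsB[2]) &
        a$ins == partsB[3] & a$resid == partsB[4] &
        a$elety %in% CHARGED_GROUPS[[partsB[4]]]$atoms
      cenA <- colMeans(xyz[selA, , drop = FALSE])
      cenB <- colMeans(xyz[selB, , drop = FALSE])
      if (sqrt(sum((cenA - cenB)^2)) <= config$salt_dist) {
        best <- rows[which.min(dist[rows])]
        type[best] <- "salt_bridge"
        type[setdiff(rows, best)] <- "consumed"
      }
    }
  }

  # --- hydrogen bonds (heavy-atom criteria) ---
  don_a <- atom_in_set(a$resid[pi_], a$elety[pi_], HB_DONORS) |
    is_backbone_n_donor(a$resid[pi_], a$elety[pi_])
  acc_a <- atom_in_set(a$resid[pi_], a$elety[pi_], HB_ACCEPTORS, TRUE)
  don_b <- atom_in_set(a$resid[pj_], a$elety[pj_], HB_DONORS) |
    is_backbone_n_donor(a$resid[pj_], a$elety[pj_])
  acc_b <- atom_in_set(a$resid[pj_], a$elety[pj_], HB_ACCEPTORS, TRUE)
  hb <- is.na(type) & dist <= config$hbond_dist &
    ((don_a & acc_b) | (don_b & acc_a))
  type[hb] <- "hbond"

  # --- hydrophobic ---
  apol_a <- atom_in_set(a$resid[pi_], a$elety[pi_], APOLAR_CARBONS)
  apol_b <- atom_in_set(a$resid[pj_], a$elety[pj_], APOLAR_CARBONS)
  hp <- is.na(type) & dist <= config$hydrophobic_dist & apol_a & apol_b
  type[hp] <- "hydrophobic"

  # --- van der Waals ---
  vw <- is.na(type) &
    dist <= a$radius[pi_] + a$radius[pj_] + config$vdw_slack
  type[vw] <- "vdw"

  keep <- !is.na(type) & type != "consumed"
  out <- data.frame(type = type[keep],
                    chain_a = a$chain[pi_][keep], resno_a = a$resno[pi_][keep],
                    ins_a = a$ins[pi_][keep], resid_a = a$resid[pi_][keep],
                    atom_a = a$elety[pi_][keep],
                    chain_b = a$chain[pj_][keep], resno_b = a$resno[pj_][keep],
                    ins_b = a$ins[pj_][keep], resid_b = a$resid[pj_][keep],
                    atom_b = a$elety[pj_][keep],
                    distance = round(dist[keep], 4),
                    stringsAsFactors = FALSE)
  ord <- order(out$chain_a, out$resno_a, out$ins_a, out$atom_a,
               out$chain_b, out$resno_b, out$ins_b, out$atom_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# contacts touching one residue
contacts_for_residue <- function(contacts, chain, resno, ins = "") {
  if (is.null(contacts) || nrow(contacts) == 0L) return(contacts)
  contacts[(contacts$chain_a == chain & contacts$resno_a == resno &
              contacts$ins_a == ins) |
             (contacts$chain_b == chain & contacts$resno_b == resno &
                contacts$ins_b == ins), , drop = FALSE]
}
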