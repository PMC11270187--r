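# independent all-pairs brute-force contact oracle: nested loops over every
# cross-partition heavy-atom pair, applying the documented geometric rules
brute_force_contacts <- function(model, cfg = default_contact_config()) {
  a <- model$atoms
  ia <- which(a$chain %in% model$partition[[1]])
  ib <- which(a$chain %in% model$partition[[2]])
  charged <- list(LYS = c("NZ"), ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"), ASP = c("OD1", "OD2"),
                  GLU = c("OE1", "OE2"))
  sign_of <- function(res) {
    if (res %in% c("LYS", "ARG", "HIS")) 1L
    else if (res %in% c("ASP", "GLU")) -1L else 0L
  }
  is_charged_atom <- function(i)
    a$resid[i] %in% names(charged) && a$elety[i] %in% charged[[a$resid[i]]]
  group_centroid <- function(i) {
    sel <- a$chain == a$chain[i] & a$resno == a$resno[i] & a$ins == a$ins[i] &
      a$resid == a$resid[i] & a$elety %in% charged[[a$resid[i]]]
    colMeans(a[sel, c("x", "y", "z")])
  }
  donors <- abgraft:::HB_DONORS; acceptors <- abgraft:::HB_ACCEPTORS
  is_don <- function(i)
    (a$elety[i] == "N" && a$resid[i] != "PRO") ||
      (a$resid[i] %in% names(donors) && a$elety[i] %in% donors[[a$resid[i]]])
  is_acc <- function(i)
    a$elety[i] %in% acceptors$backbone ||
      (a$resid[i] %in% names(acceptors) &&
         a$elety[i] %in% acceptors[[a$resid[i]]])
  apol <- abgraft:::APOLAR_CARBONS
  is_apol <- function(i)
    a$resid[i] %in% names(apol) && a$elety[i] %in% apol[[a$resid[i]]]
  out <- NULL
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((a[i, c("x", "y", "z")] - a[j, c("x", "y", "z")])^2))
    type <- NA_character_
    if (is_charged_atom(i) && is_charged_atom(j) &&
        sign_of(a$resid[i]) * sign_of(a$resid[j]) == -1L &&
        sqrt(sum((group_centroid(i) - group_centroid(j))^2)) <= cfg$salt_dist)
      type <- "salt_bridge"
    else if (d <= cfg$hbond_dist &&
             ((is_don(i) && is_acc(j)) || (is_don(j) && is_acc(i))))
      type <- "hbond"
    else if (d <= cfg$hydrophobic_dist && is_apol(i) && is_apol(j))
      type <- "hydrophobic"
    else if (d <= a$radius[i] + a$radius[j] + cfg$vdw_slack)
      type <- "vdw"
    if (!is.na(type))
      out <- rbind(out, data.frame(
        type = type, chain_a = a$chain[i], resno_a = a$resno[i],
        atom_a = a$elety[i], chain_b = a$chain[j], resno_b = a$resno[j],
        atom_b = a$elety[j], stringsAsFactors = FALSE))
  }
  out
}

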