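# Deterministic synthetic fixtures with machine-readable ground truth:
# template-derived antibody sequences with known scheme labels, toy
# multi-chain structures with analytic SASA / planted contacts, and
# Gaussian-jittered coordinate ensembles with known per-residue variance.
# Every generator returns list(<payload>, truth = <ground truth>) and is
# byte-reproducible given its seed.

#' Generate template-derived antibody sequences with ground-truth labels
#'
#' Sequences are derived from the bundled numbering template for the chain
#' class: point mutations at non-anchor positions at \code{mutation_rate}
#' per residue, and up to two CDR indels per sequence at \code{indel_rate}
#' per CDR (an insertion duplicates a loop residue, a deletion removes
#' one). The truth payload records each sequence's scheme labels and
#' regions, computed from the template bookkeeping and the scheme's
#' canonical CDR length rules, independently of the alignment-based
#' numbering engine.
#'
#' @param n Number of sequences.
#' @param indel_rate Per-CDR indel probability, in [0, 0.1].
#' @param mutation_rate Per-residue substitution probability, in [0, 0.1].
#' @param seed Integer seed.
#' @param chain_class Template to derive from.
#' @param scheme Scheme for the truth labels.
#' @return List: \code{sequences} (list of \code{AntibodySequence}),
#'   \code{truth} (per-sequence data frames \code{label}, \code{region},
#'   \code{aa}).
#' @export
make_sequence_set <- function(n, indel_rate = 0, mutation_rate = 0, seed = 1,
                              chain_class = "heavy", scheme = "kabat") {
  if (indel_rate < 0 || indel_rate > 0.1 || mutation_rate < 0 ||
      mutation_rate > 0.1)
    stop("rates must lie in [0, 0.1]", call. = FALSE)
  tmpl <- numbering_template(scheme, chain_class)
  anchors <- anchor_labels(scheme, chain_class)
  set.seed(seed)
  sequences <- vector("list", n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    aa <- tmpl$aa
    region <- tmpl$region
    label <- tmpl$label
    # substitutions away from anchors (anchor residues are scheme-defining)
    mutable <- which(!(label %in% anchors))
    hit <- mutable[stats::runif(length(mutable)) < mutation_rate]
    for (i in hit) aa[i] <- sample(setdiff(AA_LETTERS, aa[i]), 1L)
    # CDR indels: at most 2 per sequence
    n_indels <- 0L
    for (r in c("CDR1", "CDR2", "CDR3")) {
      if (n_indels >= 2L || stats::runif(1) >= indel_rate) next
      idx <- which(region == r)
      if (length(idx) < 4L) next
      if (stats::runif(1) < 0.5) { # deletion
        drop <- sample(idx, 1L)
        aa <- aa[-drop]; region <- region[-drop]; label <- label[-drop]
      } else {                     # insertion: duplicate a loop residue
        at <- sample(idx[-length(idx)], 1L)
        aa <- append(aa, aa[at], after = at)
        region <- append(region, r, after = at)
        label <- append(label, NA_character_, after = at)
      }
      n_indels <- n_indels + 1L
    }
    # relabel CDRs by the scheme's canonical length rules
    for (r in c("CDR1", "CDR2", "CDR3")) {
      idx <- which(region == r)
      if (length(idx))
        label[idx] <- cdr_labels(scheme, chain_class, r, length(idx))
    }
    id <- sprintf("synth_%s_%03d", chain_class, k)
    sequences[[k]] <- antibody_sequence(id, chain_class,
                                        paste(aa, collapse = ""),
                                        source_tag = "synthetic fixture")
    truth[[k]] <- data.frame(label = label, region = region, aa = aa,
                             stringsAsFactors = FALSE)
    names(truth)[k] <- id
  }
  list(sequences = sequences, truth = truth)
}

bead_atoms <- function(chain, resno, resid, elety, xyz, element = NULL) {
  data.frame(chain = chain, resno = resno, ins = "", resid = resid,
             elety = elety,
             element = if (is.null(element)) substr(elety, 1, 1) else element,
             x = xyz[1], y = xyz[2], z = xyz[3], o = 1,
             stringsAsFactors = FALSE)
}

#' Two-sphere fixture with analytic SASA truth
#'
#' Two atoms at separation \code{d}; the truth payload carries the exact
#' two-sphere spherical-cap SASA for each.
#'
#' @param r1,r2 van der Waals radii (Angstrom); element override is used so
#'   arbitrary radii are honoured.
#' @param d Center separation (Angstrom).
#' @param probe_radius Probe radius used for the analytic truth.
#' @return List: \code{model} (\code{StructureModel}), \code{truth}
#'   (numeric length-2: exact SASA per atom).
#' @export
make_two_sphere <- function(r1 = 1.7, r2 = 1.7, d = 2.0, probe_radius = 1.4) {
  atoms <- rbind(
    bead_atoms("A", 1, "GLY", "C1", c(0, 0, 0), "C"),
    bead_atoms("A", 1, "GLY", "C2", c(d, 0, 0), "C"))
  model <- structure_model(atoms, model_id = "two_sphere")
  model$atoms$radius <- c(r1, r2)  # arbitrary per-atom radii for the sweep
  R1 <- r1 + probe_radius; R2 <- r2 + probe_radius
  sasa <- function(Ri, Rj) {
    if (d >= Ri + Rj) return(4 * pi * Ri^2)
    if (d + Ri <= Rj) return(0)           # fully engulfed
    h <- Ri - (d^2 + Ri^2 - Rj^2) / (2 * d) # cap height removed
    4 * pi * Ri^2 - 2 * pi * Ri * h
  }
  list(model = model, truth = c(sasa(R1, R2), sasa(R2, R1)))
}

#' Shell fixture: a buried central atom
#'
#' One carbon enclosed by a tight shell of \code{n_shell} atoms placed on a
#' sphere; the central atom's SASA is exactly zero.
#'
#' @param n_shell Number of shell atoms (default 30).
#' @param shell_radius Shell placement radius (Angstrom).
#' @return List: \code{model}, \code{truth} (central-atom SASA, 0).
#' @export
make_shell <- function(n_shell = 30, shell_radius = 3.0) {
  pts <- sphere_points(n_shell) * shell_radius
  atoms <- bead_atoms("A", 1, "GLY", "C", c(0, 0, 0), "C")
  for (i in seq_len(n_shell))
    atoms <- rbind(atoms, bead_atoms("B", i, "GLY", "C", pts[i, ], "C"))
  list(model = structure_model(atoms, model_id = "shell"), truth = 0)
}

# planted cross-interface pairs, one per contact type
plant_pair <- function(type, y) {
  # returns atoms for side A (chain A) and side B (chain B) forming exactly
  # one typed contact at the given lateral offset
  switch(type,
    salt_bridge = list(
      a = bead_atoms("A", NA, "LYS", "NZ", c(0, y, 0), "N"),
      b = bead_atoms("B", NA, "GLU", "OE1", c(3.0, y, 0), "O"),
      distance = 3.0),
    hbond = list(
      a = bead_atoms("A", NA, "SER", "OG", c(0, y, 0), "O"),
      b = bead_atoms("B", NA, "GLY", "O", c(2.9, y, 0), "O"),
      distance = 2.9),
    hydrophobic = list(
      a = bead_atoms("A", NA, "LEU", "CD1", c(0, y, 0), "C"),
      b = bead_atoms("B", NA, "ALA", "CB", c(3.8, y, 0), "C"),
      distance = 3.8),
    vdw = list(
      a = bead_atoms("A", NA, "GLY", "CA", c(0, y, 0), "C"),
      b = bead_atoms("B", NA, "GLY", "CA", c(3.6, y, 0), "C"),
      distance = 3.6))
}

#' Toy two-chain interface with planted typed contacts
#'
#' Builds two mini-chains of glycine/alanine/lysine/glutamate/serine/
#' leucine beads so that exactly \code{n_contacts} typed contacts exist
#' under the default cutoffs (types cycle salt_bridge, hbond, hydrophobic,
#' vdw); planted pairs are spaced far enough apart not to interact, and
#' \code{separation} places additional non-contacting filler beads.
#'
#' @param n_contacts Number of planted contacts (>= 0).
#' @param separation Distance of the filler beads (Angstrom); must exceed
#'   every cutoff (> 10 A) for the zero-contact guarantee.
#' @param seed Unused randomness guard (construction is deterministic);
#'   kept so fixture specs are uniform.
#' @return List: \code{model} (partition A vs B), \code{truth} (data frame
#'   of planted contacts: type, atoms, distance).
#' @export
make_toy_interface <- function(n_contacts = 0, separation = 30, seed = 1) {
  if (n_contacts < 0) stop("n_contacts must be >= 0", call. = FALSE)
  if (separation <= 12)
    stop("infeasible geometry: separation must exceed 12 A so filler beads ",
         "cannot contact", call. = FALSE)
  types <- rep(c("salt_bridge", "hbond", "hydrophobic", "vdw"),
               length.out = max(n_contacts, 0))
  atoms <- NULL
  truth <- NULL
  resno <- 0L
  for (i in seq_len(n_contacts)) {
    p <- plant_pair(types[i], y = 12 * (i - 1))
    resno <- resno + 1L
    p$a$resno <- resno
    p$b$resno <- resno
    atoms <- rbind(atoms, p$a, p$b)
    truth <- rbind(truth, data.frame(
      type = types[i], chain_a = "A", resno_a = resno, resid_a = p$a$resid,
      atom_a = p$a$elety, chain_b = "B", resno_b = resno,
      resid_b = p$b$resid, atom_b = p$b$elety, distance = p$distance,
      stringsAsFactors = FALSE))
  }
  # filler beads, far along z so they bury nothing and contact nothing
  resno <- resno + 1L
  atoms <- rbind(atoms,
                 bead_atoms("A", resno, "GLY", "CA", c(0, 0, separation), "C"),
                 bead_atoms("B", resno, "GLY", "CA",
                            c(separation, 0, separation), "C"))
  model <- structure_model(atoms,
                           partition = list(left = "A", right = "B"),
                           model_id = sprintf("toy_interface_%d", n_contacts))
  if (is.null(truth))
    truth <- data.frame(type = character(), chain_a = character(),
                        resno_a = integer(), resid_a = character(),
                        atom_a = character(), chain_b = character(),
                        resno_b = integer(), resid_b = character(),
                        atom_b = character(), distance = numeric(),
                        stringsAsFactors = FALSE)
  list(model = model, truth = truth)
}

#' Gaussian-jittered coordinate ensemble with known per-atom variance
#'
#' Each frame adds isotropic Gaussian jitter (per-axis SD sigma) to the
#' base coordinates; sigma may be a scalar or per-atom vector (e.g., an
#' elevated-loop profile). The expected RMSF is sigma * sqrt(3).
#'
#' @param base A \code{StructureModel}.
#' @param sigma Per-axis jitter SD, Angstrom (scalar or per-atom).
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @return List: \code{frames} (list of \code{StructureModel}s),
#'   \code{truth} (per-atom sigma and expected RMSF).
#' @export
make_jittered_ensemble <- function(base, sigma = 0.5, n_frames = 100,
                                   seed = 1) {
  stopifnot(inherits(base, "StructureModel"), n_frames >= 2L,
            all(sigma >= 0))
  n <- nrow(base$atoms)
  sigma <- rep(sigma, length.out = n)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(m) {
    f <- base
    f$atoms$x <- f$atoms$x + stats::rnorm(n, sd = sigma)
    f$atoms$y <- f$atoms$y + stats::rnorm(n, sd = sigma)
    f$atoms$z <- f$atoms$z + stats::rnorm(n, sd = sigma)
    f$model_id <- sprintf("%s#%d", base$model_id, m)
    f
  })
  list(frames = frames,
       truth = data.frame(chain = base$atoms$chain, resno = base$atoms$resno,
                          sigma = sigma, rmsf_expected = sigma * sqrt(3),
                          stringsAsFactors = FALSE))
}

#' Toy Fab-like antibody-antigen complex with planted paratope contacts
#'
#' Builds a bead model of one full numbered antibody chain (one C-alpha per
#' residue on a straight trace) plus a small antigen chain, planting typed
#' cross-interface contacts at chosen scheme positions: side-chain atoms of
#' those residues are placed within contact range of matching antigen
#' beads. The geometry is deliberately schematic; what it guarantees is the
#' mapping truth: which scheme positions bury surface and contact the
#' antigen, with which contact types.
#'
#' @param numbered A \code{NumberedChain} (Kabat scheme recommended).
#' @param contact_positions Character vector of scheme position labels to
#'   place at the interface.
#' @param contact_types Matching vector of types: \code{"salt_bridge"}
#'   (lysine/arginine vs glutamate), \code{"hbond"} (side-chain hydroxyl or
#'   amine vs a backbone carbonyl) or \code{"hydrophobic"}.
#' @param chain_id Chain identifier for the antibody chain (default "L").
#' @return List: \code{model} (\code{StructureModel}, partition antibody vs
#'   antigen), \code{truth} (data frame: position, region, planted type).
#' @export
make_paratope_complex <- function(numbered, contact_positions,
                                  contact_types, chain_id = "L") {
  stopifnot(inherits(numbered, "NumberedChain"),
            length(contact_positions) == length(contact_types))
  pos <- numbered$positions
  idx <- match(contact_positions, pos$label)
  if (anyNA(idx))
    stop("positions not in chain: ",
         paste(contact_positions[is.na(idx)], collapse = ", "), call. = FALSE)
  one_to_three <- stats::setNames(names(AA_THREE_TO_ONE)[1:20],
                                  unname(AA_THREE_TO_ONE[1:20]))
  spacing <- 5
  atoms <- do.call(rbind, lapply(seq_len(nrow(pos)), function(i)
    bead_atoms(chain_id, i, one_to_three[[pos$aa[i]]], "CA",
               c(0, spacing * i, 0), "C")))
  ag <- NULL
  ag_res <- 0L
  truth <- NULL
  for (k in seq_along(idx)) {
    i <- idx[k]
    y <- spacing * i
    aa <- pos$aa[i]
    type <- contact_types[k]
    ag_res <- ag_res + 1L
    if (type == "salt_bridge") {
      sc <- switch(aa, K = "NZ", R = "NH1",
                   stop("salt_bridge site needs K or R at position ",
                        contact_positions[k], call. = FALSE))
      atoms <- rbind(atoms, bead_atoms(chain_id, i, one_to_three[[aa]], sc,
                                       c(2, y, 0), "N"))
      ag <- rbind(ag,
                  bead_atoms("G", ag_res, "GLU", "OE1", c(5, y, 0), "O"),
                  bead_atoms("G", ag_res, "GLU", "CA", c(8, y, 0), "C"))
    } else if (type == "hbond") {
      sc <- switch(aa, Y = "OH", S = "OG", T = "OG1", R = "NH1", K = "NZ",
                   N = "ND2", Q = "NE2",
                   stop("hbond site needs a polar side chain at position ",
                        contact_positions[k], call. = FALSE))
      el <- if (substr(sc, 1, 1) == "O") "O" else "N"
      atoms <- rbind(atoms, bead_atoms(chain_id, i, one_to_three[[aa]], sc,
                                       c(2, y, 0), el))
      ag <- rbind(ag,
                  bead_atoms("G", ag_res, "PRO", "O", c(4.9, y, 0), "O"),
                  bead_atoms("G", ag_res, "PRO", "CA", c(8, y, 0), "C"))
    } else if (type == "hydrophobic") {
      atoms <- rbind(atoms, bead_atoms(chain_id, i, one_to_three[[aa]], "CB",
                                       c(2, y, 0), "C"))
      ag <- rbind(ag,
                  bead_atoms("G", ag_res, "ALA", "CB", c(5.8, y, 0), "C"),
                  bead_atoms("G", ag_res, "ALA", "CA", c(8, y, 0), "C"))
    } else stop("unknown contact type ", type, call. = FALSE)
    truth <- rbind(truth, data.frame(position = contact_positions[k],
                                     region = pos$region[i], type = type,
                                     stringsAsFactors = FALSE))
  }
  model <- structure_model(rbind(atoms, ag),
                           partition = stats::setNames(
                             list(chain_id, "G"), c("antibody", "antigen")),
                           model_id = "paratope_complex")
  list(model = model, truth = truth)
}

#' A small helical peptide backbone as a structure fixture
#'
#' Deterministic poly-alanine-like trace (CA atoms on an ideal helix, one
#' residue per position) used as a base for ensembles and superposition
#' tests.
#'
#' @param n_res Number of residues.
#' @param chain Chain identifier.
#' @return A \code{StructureModel} of CA beads.
#' @export
make_helix_trace <- function(n_res = 30, chain = "A") {
  i <- seq_len(n_res)
  atoms <- do.call(rbind, lapply(i, function(k)
    bead_atoms(chain, k, "ALA", "CA",
               c(2.3 * cos(k * 100 * pi / 180),
                 2.3 * sin(k * 100 * pi / 180), 1.5 * k), "C")))
  structure_model(atoms, model_id = sprintf("helix_%s%d", chain, n_res))
}
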