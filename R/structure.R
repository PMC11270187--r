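# Structure container and PDB/mmCIF I/O (via bio3d), with altloc handling,
# element-based van der Waals radius assignment and chain partitions.

vdw_radii_table <- function() {
  t <- read_bundled_csv("vdw_radii.csv")
  stats::setNames(as.numeric(t$radius), t$element)
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the atom name: strip digits, take the leading letters;
    # two-letter elements in proteins are rare and caught by the radii table
    nm <- gsub("[0-9']", "", toupper(trimws(elety[miss])))
    known2 <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CU")
    el[miss] <- ifelse(substr(nm, 1, 2) %in% known2, substr(nm, 1, 2),
                       substr(nm, 1, 1))
  }
  el
}

#' Create a structure model from an atom table
#'
#' @param atoms Data frame with columns \code{chain}, \code{resno},
#'   \code{ins}, \code{resid} (three-letter residue name), \code{elety}
#'   (atom name), \code{element}, \code{x}, \code{y}, \code{z} (Angstrom)
#'   and optionally \code{o} (occupancy). Radii are assigned from the
#'   bundled element table; unknown elements error unless
#'   \code{radius_override} supplies them.
#' @param partition Optional named list of two character vectors of chain
#'   ids declaring the interface sides, e.g.
#'   \code{list(Fab = c("H","L"), antigen = c("A","B"))}.
#' @param model_id Identifier stored with the model.
#' @param radius_override Named numeric vector element -> radius (Angstrom).
#' @return A \code{StructureModel}.
#' @export
structure_model <- function(atoms, partition = NULL, model_id = "model",
                            radius_override = NULL) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$element))
    atoms$element <- guess_element(NA_character_, atoms$elety)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates", call. = FALSE)
  radii <- vdw_radii_table()
  if (!is.null(radius_override)) radii[names(radius_override)] <- radius_override
  atoms$radius <- unname(radii[toupper(atoms$element)])
  if (any(is.na(atoms$radius))) {
    bad <- unique(toupper(atoms$element)[is.na(atoms$radius)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "),
         "; supply radius_override", call. = FALSE)
  }
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records; resolve altlocs first",
         call. = FALSE)
  if (!is.null(partition)) partition <- validate_partition(partition, atoms)
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, atoms = atoms, partition = partition),
            class = "StructureModel")
}

validate_partition <- function(partition, atoms) {
  if (length(partition) != 2L || is.null(names(partition)) ||
      any(!nzchar(names(partition))))
    stop("partition must be a named list of two chain-id groups",
         call. = FALSE)
  a <- unique(partition[[1]]); b <- unique(partition[[2]])
  if (length(intersect(a, b)))
    stop("partition groups overlap: ", paste(intersect(a, b), collapse = ","),
         call. = FALSE)
  for (g in list(a, b))
    if (!any(atoms$chain %in% g))
      stop("partition group has no atoms in the model", call. = FALSE)
  list2env(list(), envir = emptyenv()) # no-op, keeps list order below
  stats::setNames(list(a, b), names(partition))
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel %s: %d atoms, %d chains (%s)\n", x$model_id,
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(sort(unique(x$atoms$chain)), collapse = ",")))
  if (!is.null(x$partition))
    cat(sprintf("  partition: %s = {%s} vs %s = {%s}\n",
                names(x$partition)[1], paste(x$partition[[1]], collapse = ","),
                names(x$partition)[2], paste(x$partition[[2]], collapse = ",")))
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' Uses bio3d for parsing. Altlocs are resolved to the highest-occupancy
#' conformer (first on ties); waters and non-protein hetero atoms are
#' excluded by default (opt in via \code{keep_hetero}), hydrogens are kept
#' only on request.
#'
#' @param path File path (\code{.pdb} or \code{.cif}).
#' @param partition Optional chain partition, as in
#'   \code{\link{structure_model}}.
#' @param multi_model If \code{TRUE}, return a list of \code{StructureModel}
#'   frames (one per MODEL record), e.g. for a coordinate ensemble.
#' @param keep_hetero Keep non-water hetero atoms (ions, ligands).
#' @param keep_waters Keep waters.
#' @param keep_hydrogens Keep hydrogen atoms.
#' @return A \code{StructureModel}, or a list of them when
#'   \code{multi_model = TRUE}.
#' @export
read_structure <- function(path, partition = NULL, multi_model = FALSE,
                           keep_hetero = FALSE, keep_waters = FALSE,
                           keep_hydrogens = FALSE) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, multi = multi_model, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      ins = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid, elety = at$elety,
                      element = guess_element(at$elesy, at$elety),
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      alt = ifelse(is.na(at$alt), "", at$alt),
                      type = at$type, stringsAsFactors = FALSE)
  if (!keep_waters) atoms <- atoms[!atoms$resid %in% c("HOH", "WAT", "DOD"), ]
  if (!keep_hetero)
    atoms <- atoms[atoms$type == "ATOM" |
                     atoms$resid %in% names(AA_THREE_TO_ONE), ]
  if (!keep_hydrogens) atoms <- atoms[!atoms$element %in% c("H", "D"), ]
  atoms <- resolve_altlocs(atoms)
  atoms$alt <- atoms$type <- NULL
  base <- tools::file_path_sans_ext(basename(path))
  if (multi_model && !is.null(pdb$xyz) && nrow(pdb$xyz) > 1L) {
    xyz <- pdb$xyz
    sel <- match(paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety),
                 paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                       at$elety))
    lapply(seq_len(nrow(xyz)), function(m) {
      fr <- atoms
      fr$x <- xyz[m, 3 * (sel - 1) + 1]
      fr$y <- xyz[m, 3 * (sel - 1) + 2]
      fr$z <- xyz[m, 3 * (sel - 1) + 3]
      structure_model(fr, partition = partition,
                      model_id = sprintf("%s#%d", base, m))
    })
  } else {
    structure_model(atoms, partition = partition, model_id = base)
  }
}

resolve_altlocs <- function(atoms) {
  if (is.null(atoms$alt) || all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    if (length(i) == 1L) return(i)
    i[order(-atoms$o[i], atoms$alt[i])][1L]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Write a structure (or ensemble) as PDB
#'
#' @param model A \code{StructureModel} or a list of them with identical
#'   atom tables (written as a multi-MODEL file).
#' @param path Output file.
#' @export
write_structure <- function(model, path) {
  frames <- if (inherits(model, "StructureModel")) list(model) else model
  a <- frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f)
    as.vector(t(as.matrix(f$atoms[, c("x", "y", "z")])))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, chain = a$chain,
                   resid = a$resid, eleno = seq_len(nrow(a)), elety = a$elety,
                   insert = ifelse(a$ins == "", NA, a$ins), o = a$o,
                   elesy = a$element)
  invisible(path)
}

# residues of a model in record order: one row per (chain, resno, ins)
model_residues <- function(model, chains = NULL) {
  a <- model$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, ]
  key <- paste(a$chain, a$resno, a$ins, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             ins = a$ins[first], resid = a$resid[first],
             key = key[first], stringsAsFactors = FALSE)
}

side_chains <- function(model, side) {
  if (is.null(model$partition))
    stop("model has no chain partition; supply one via structure_model() ",
         "or read_structure(partition = ...)", call. = FALSE)
  model$partition[[side]]
}
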