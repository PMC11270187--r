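# Least-squares rigid-body superposition (Kabsch, via SVD), per-residue
# RMSD after framework-anchored fitting, and per-residue RMSF over
# coordinate ensembles.

# optimal rotation/translation mapping mobile onto reference (n x 3 each)
kabsch <- function(reference, mobile) {
  stopifnot(nrow(reference) == nrow(mobile), nrow(reference) >= 3L)
  cr <- colMeans(reference)
  cm <- colMeans(mobile)
  H <- t(sweep(mobile, 2, cm)) %*% sweep(reference, 2, cr)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(cr - R %*% cm))
}

apply_transform <- function(xyz, tr) {
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

atom_xyz <- function(model, sel) as.matrix(model$atoms[sel, c("x", "y", "z")])

residue_label_df <- function(model) {
  with(model$atoms, paste(chain, resno, ins, sep = "|"))
}

#' Superpose one structure onto another and report per-residue RMSD
#'
#' Finds the least-squares optimal rigid transform of \code{mobile} onto
#' \code{reference} over the fit selection (by default the C-alpha atoms of
#' all mapped residues), then reports per-residue RMSD over all mapped
#' residues. Framework-anchored fitting is obtained by passing the
#' framework residue keys as \code{fit_selection}.
#'
#' @param reference,mobile \code{StructureModel}s.
#' @param fit_selection Optional character vector of residue keys
#'   (\code{"chain|resno|ins"}, see \code{\link{residue_keys}}) used for
#'   fitting; default: all mapped residues.
#' @param map Optional two-column data frame (\code{ref}, \code{mob}) of
#'   residue keys defining the correspondence; default: residues sharing a
#'   key in both models.
#' @param atoms \code{"calpha"} (default) or \code{"all"}: atoms used for
#'   fitting and RMSD within each mapped residue.
#' @return A \code{SuperpositionResult}: \code{rotation} (3x3,
#'   det = +1), \code{translation}, \code{per_residue_rmsd} (named by
#'   reference residue key), \code{fit_rmsd}, \code{fit_selection}.
#' @export
superpose <- function(reference, mobile, fit_selection = NULL, map = NULL,
                      atoms = c("calpha", "all")) {
  atoms <- match.arg(atoms)
  stopifnot(inherits(reference, "StructureModel"),
            inherits(mobile, "StructureModel"))
  rk <- residue_label_df(reference)
  mk <- residue_label_df(mobile)
  if (is.null(map)) {
    shared <- intersect(unique(rk), unique(mk))
    map <- data.frame(ref = shared, mob = shared, stringsAsFactors = FALSE)
  }
  if (nrow(map) < 3L) stop("need at least 3 mapped residues", call. = FALSE)
  if (is.null(fit_selection)) fit_selection <- map$ref

  pick <- function(model, keys_all, key) {
    sel <- keys_all == key
    if (atoms == "calpha") sel <- sel & model$atoms$elety == "CA"
    which(sel)
  }
  # paired atom coordinates per mapped residue (atom-name matched)
  ref_xyz <- mob_xyz <- NULL
  res_rows <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    ri <- pick(reference, rk, map$ref[i])
    mi <- pick(mobile, mk, map$mob[i])
    common <- intersect(reference$atoms$elety[ri], mobile$atoms$elety[mi])
    if (!length(common)) next
    ri <- ri[match(common, reference$atoms$elety[ri])]
    mi <- mi[match(common, mobile$atoms$elety[mi])]
    res_rows[[i]] <- NROW(ref_xyz) + seq_along(ri)
    ref_xyz <- rbind(ref_xyz, atom_xyz(reference, ri))
    mob_xyz <- rbind(mob_xyz, atom_xyz(mobile, mi))
  }
  names(res_rows) <- map$ref
  fit_rows <- unlist(res_rows[map$ref %in% fit_selection], use.names = FALSE)
  if (length(fit_rows) < 3L)
    stop("fewer than 3 fit atoms after mapping", call. = FALSE)
  fx <- ref_xyz[fit_rows, , drop = FALSE]
  if (qr(sweep(fx, 2, colMeans(fx)))$rank < 2L)
    stop("degenerate (collinear) fit selection", call. = FALSE)
  tr <- kabsch(ref_xyz[fit_rows, , drop = FALSE],
               mob_xyz[fit_rows, , drop = FALSE])
  moved <- apply_transform(mob_xyz, tr)
  dev2 <- rowSums((moved - ref_xyz)^2)
  per_res <- vapply(res_rows, function(rows)
    if (is.null(rows)) NA_real_ else sqrt(mean(dev2[rows])), numeric(1))
  structure(list(rotation = tr$rotation, translation = tr$translation,
                 per_residue_rmsd = per_res,
                 fit_rmsd = sqrt(mean(dev2[fit_rows])),
                 fit_selection = fit_selection, atoms = atoms),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: fit RMSD %.3f A over %d residues (%s); %d mapped residues\n",
              x$fit_rmsd, length(x$fit_selection), x$atoms,
              length(x$per_residue_rmsd)))
  invisible(x)
}

#' Residue keys of a structure model
#'
#' Keys are \code{"chain|resno|ins"} strings, in record order; used to name
#' fit selections and RMSD/RMSF vectors.
#'
#' @param model A \code{StructureModel}.
#' @param chains Optional chain filter.
#' @return Character vector of keys.
#' @export
residue_keys <- function(model, chains = NULL) {
  model_residues(model, chains = chains)$key
}

#' Per-residue RMSF over a coordinate ensemble
#'
#' RMSF_i = sqrt(mean_t |x_i(t) - mean_t x_i|^2) on the selected atoms
#' (default one C-alpha per residue), optionally after least-squares
#' superposition of every frame onto the ensemble mean (two-pass: fit to
#' the first frame, compute the mean, refit to the mean).
#'
#' @param frames List of \code{StructureModel}s with identical atom
#'   topology (e.g., from \code{read_structure(multi_model = TRUE)}).
#' @param selection \code{"calpha"} (default) or \code{"all"}.
#' @param fit Superpose frames onto the mean first (default \code{TRUE}).
#' @return An \code{EnsembleRmsf}: \code{per_residue} (named numeric,
#'   Angstrom), \code{n_frames}, \code{selection}, \code{fit}.
#' @export
ensemble_rmsf <- function(frames, selection = c("calpha", "all"), fit = TRUE) {
  selection <- match.arg(selection)
  stopifnot(is.list(frames), length(frames) >= 2L)
  a0 <- frames[[1]]$atoms
  sel <- if (selection == "calpha") which(a0$elety == "CA")
         else seq_len(nrow(a0))
  if (!length(sel)) stop("selection matches no atoms", call. = FALSE)
  sig0 <- paste(a0$chain, a0$resno, a0$ins, a0$elety)
  coords <- lapply(frames, function(f) {
    if (!identical(paste(f$atoms$chain, f$atoms$resno, f$atoms$ins,
                         f$atoms$elety), sig0))
      stop("frames differ in atom topology", call. = FALSE)
    as.matrix(f$atoms[sel, c("x", "y", "z")])
  })
  if (fit && length(sel) >= 3L) {
    refit <- function(target)
      lapply(coords, function(m) apply_transform(m, kabsch(target, m)))
    coords <- refit(coords[[1]])
    mean_xyz <- Reduce(`+`, coords) / length(coords)
    coords <- refit(mean_xyz)
  }
  mean_xyz <- Reduce(`+`, coords) / length(coords)
  msf <- Reduce(`+`, lapply(coords, function(m)
    rowSums((m - mean_xyz)^2))) / length(coords)
  rmsf_atom <- sqrt(msf)
  keys <- paste(a0$chain[sel], a0$resno[sel], a0$ins[sel], sep = "|")
  per_res <- vapply(split(rmsf_atom, factor(keys, unique(keys))), mean,
                    numeric(1))
  structure(list(per_residue = per_res, n_frames = length(frames),
                 selection = selection, fit = fit),
            class = "EnsembleRmsf")
}

#' @export
print.EnsembleRmsf <- function(x, ...) {
  cat(sprintf("EnsembleRmsf: %d residues over %d frames (%s%s); mean %.3f A\n",
              length(x$per_residue), x$n_frames, x$selection,
              if (x$fit) ", fitted" else "", mean(x$per_residue)))
  invisible(x)
}
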