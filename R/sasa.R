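# Shrake-Rupley solvent-accessible surface area with a deterministic
# generalized-spiral (Fibonacci) sphere point set.

#' Deterministic unit-sphere point set
#'
#' Generalized spiral (golden-angle) construction over one hemisphere,
#' completed by the antipodes: the set is exactly symmetric under central
#' inversion, so inversion-related environments receive identical SASA,
#' and odd-order quadrature error cancels. Fixed for a given \code{n}, so
#' SASA values are exactly reproducible. Odd \code{n} is rounded up to the
#' next even count.
#'
#' @param n Number of points.
#' @return \code{n x 3} matrix of unit vectors (\code{n} rounded up to
#'   even).
#' @export
sphere_points <- function(n) {
  m <- ceiling(n / 2)
  i <- seq_len(m) - 0.5
  z <- i / m                       # upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * i
  upper <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  rbind(upper, -upper)
}

rot_z <- function(th) matrix(c(cos(th), -sin(th), 0,
                               sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
rot_x <- function(th) matrix(c(1, 0, 0, 0, cos(th), -sin(th),
                               0, sin(th), cos(th)), 3, byrow = TRUE)

# cell-list neighbor search: for each atom, indices of atoms within cutoff
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  cell <- floor(xyz / cutoff)
  id <- paste(cell[, 1], cell[, 2], cell[, 3])
  bins <- split(seq_len(n), id)
  coords <- lapply(strsplit(names(bins), " "), as.numeric)
  bin_index <- new.env(parent = emptyenv(), size = length(bins))
  for (k in seq_along(bins)) assign(names(bins)[k], k, envir = bin_index)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(n), function(i) {
    ci <- cell[i, ]
    cand <- integer(0)
    for (k in seq_len(27)) {
      key <- paste(ci[1] + offsets[k, 1], ci[2] + offsets[k, 2],
                   ci[3] + offsets[k, 3])
      b <- bin_index[[key]]
      if (!is.null(b)) cand <- c(cand, bins[[b]])
    }
    cand <- cand[cand != i]
    if (!length(cand)) return(integer(0))
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
      (xyz[cand, 3] - xyz[i, 3])^2
    cand[d2 < cutoff^2]
  })
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius \code{probe_radius} over the van der Waals
#' spheres of all atoms, counting accessible test points on each atom's
#' expanded sphere. Deterministic for a fixed point count.
#'
#' @param model A \code{StructureModel} (radii already assigned).
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @return A \code{SasaResult}: list with \code{per_atom} (Angstrom^2, in
#'   atom order), \code{per_residue} data frame (sum over atoms),
#'   \code{probe_radius}, \code{n_points}.
#' @export
#' @examples
#' one <- structure_model(data.frame(chain = "A", resno = 1, resid = "ALA",
#'                                   elety = "C", element = "C",
#'                                   x = 0, y = 0, z = 0))
#' compute_sasa(one)$per_atom  # 4*pi*(1.7+1.4)^2
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(model, "StructureModel"), probe_radius >= 0,
            n_points >= 12)
  a <- model$atoms
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ext <- a$radius + probe_radius
  pts <- sphere_points(n_points)
  n_points <- nrow(pts)
  # deterministic per-atom-name rotation of the point set: decorrelates the
  # lattice quadrature error between atoms of a residue (so per-residue
  # error averages down) while keeping symmetry-related atoms, which share
  # an atom name, on identical point orientations
  rot_pts <- lapply(unique(a$elety), function(nm) {
    h <- sum(utf8ToInt(nm) * seq_len(nchar(nm)))
    gold <- (sqrt(5) - 1) / 2
    ang <- 2 * pi * ((h * c(gold, gold^2, 0.5 + gold^3)) %% 1)
    R <- rot_z(ang[1]) %*% rot_x(ang[2]) %*% rot_z(ang[3])
    pts %*% t(R)
  })
  names(rot_pts) <- unique(a$elety)
  cutoff <- 2 * max(ext)
  nbrs <- neighbor_pairs(xyz, cutoff)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    # only neighbors whose expanded sphere can intersect atom i's surface
    if (length(nb)) {
      d <- sqrt((xyz[nb, 1] - xyz[i, 1])^2 + (xyz[nb, 2] - xyz[i, 2])^2 +
                  (xyz[nb, 3] - xyz[i, 3])^2)
      nb <- nb[d < ext[i] + ext[nb]]
    }
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * ext[i]^2
      next
    }
    surf <- rot_pts[[a$elety[i]]] * ext[i]
    surf <- sweep(surf, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      d2 <- (surf[acc, 1] - xyz[j, 1])^2 + (surf[acc, 2] - xyz[j, 2])^2 +
        (surf[acc, 3] - xyz[j, 3])^2
      keep <- d2 > ext[j]^2
      acc[acc] <- keep
    }
    per_atom[i] <- 4 * pi * ext[i]^2 * sum(acc) / n_points
  }
  res <- model_residues(model)
  akey <- paste(a$chain, a$resno, a$ins, sep = "|")
  res$sasa <- as.numeric(tapply(per_atom, factor(akey, levels = res$key),
                                sum))
  res$key <- NULL
  structure(list(per_atom = per_atom, per_residue = res,
                 probe_radius = probe_radius, n_points = n_points,
                 model_id = model$model_id,
                 radii_source = "bundled Bondi-type element radii (vdw_radii.csv)"),
            class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SasaResult %s: %d atoms, total %.1f A^2 (probe %.2f A, %d points)\n",
              x$model_id, length(x$per_atom), sum(x$per_atom),
              x$probe_radius, x$n_points))
  invisible(x)
}

subset_model <- function(model, chains) {
  structure_model(model$atoms[model$atoms$chain %in% chains, , drop = FALSE],
                  model_id = paste0(model$model_id, ":",
                                    paste(chains, collapse = "")))
}
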