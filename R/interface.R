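# Per-residue interface buried surface area across a declared chain
# partition, with optional FR/CDR region aggregation via numbered chains.

#' Map structure residues of one chain onto a numbered antibody chain
#'
#' Pairs the chain's residues (in record order) with the positions of a
#' \code{NumberedChain} either by sequence (exact one-letter match of the
#' structure chain's sequence to a unique window of the numbered sequence)
#' or by author numbering (structure resno+insert read directly as scheme
#' labels).
#'
#' @param model A \code{StructureModel}.
#' @param chain_id Chain identifier in the structure.
#' @param numbered A \code{NumberedChain}.
#' @param by \code{"sequence"} (default) or \code{"author"}.
#' @return Data frame: \code{chain}, \code{resno}, \code{ins},
#'   \code{label}, \code{region}, \code{aa}.
#' @export
map_chain_regions <- function(model, chain_id, numbered,
                              by = c("sequence", "author")) {
  by <- match.arg(by)
  res <- model_residues(model, chains = chain_id)
  if (nrow(res) == 0L)
    stop("chain ", chain_id, " not present in model", call. = FALSE)
  pos <- numbered$positions
  if (by == "sequence") {
    sseq <- paste(aa_three_to_one(res$resid), collapse = "")
    cseq <- paste(pos$aa, collapse = "")
    hit <- gregexpr(sseq, cseq, fixed = TRUE)[[1]]
    if (identical(as.integer(hit), -1L))
      stop("chain ", chain_id, " sequence does not match numbered chain '",
           numbered$source$id, "'", call. = FALSE)
    if (length(hit) > 1L)
      stop("chain ", chain_id, " sequence matches numbered chain '",
           numbered$source$id, "' at multiple offsets; use by = 'author'",
           call. = FALSE)
    idx <- seq(from = hit, length.out = nrow(res))
  } else {
    lab <- format_position_label(res$resno, res$ins)
    idx <- match(lab, pos$label)
    if (anyNA(idx))
      stop("author numbering of chain ", chain_id, " has labels absent from ",
           "the numbered chain: ", paste(utils::head(lab[is.na(idx)], 5),
                                         collapse = ", "), call. = FALSE)
  }
  data.frame(chain = res$chain, resno = res$resno, ins = res$ins,
             label = pos$label[idx], region = pos$region[idx],
             aa = pos$aa[idx], stringsAsFactors = FALSE)
}

#' Per-residue interface buried surface area
#'
#' BSA follows the side-alone-minus-complex convention: for each residue,
#' SASA computed with its own side isolated minus SASA in the complex,
#' clamped at numeric zero. Totals per side are the sums over that side's
#' residues. When \code{regions} supplies numbered chains, each annotated
#' residue is classed CDR or framework under the numbered chains' boundary
#' table and per-class BSA fractions are reported per side.
#'
#' @param complex A \code{StructureModel} with a two-group chain partition.
#' @param probe_radius,n_points Passed to \code{\link{compute_sasa}}.
#' @param regions Optional named list \code{chain_id -> NumberedChain}.
#' @param map_by Residue correspondence mode for \code{regions}
#'   (see \code{\link{map_chain_regions}}).
#' @param contacts If \code{TRUE} (default) typed contacts are detected and
#'   attached (see \code{\link{detect_contacts}}).
#' @param contact_config Cutoff configuration for contact detection.
#' @return An \code{InterfaceReport}: \code{per_residue} data frame
#'   (\code{side}, \code{chain}, \code{resno}, \code{ins}, \code{resid},
#'   \code{bsa}, optional \code{label}/\code{region}), \code{totals} per
#'   side, \code{fraction_bsa_by_region_class} per annotated side, and
#'   \code{contacts}.
#' @export
interface_bsa <- function(complex, probe_radius = 1.4, n_points = 960,
                          regions = NULL, map_by = "sequence",
                          contacts = TRUE,
                          contact_config = default_contact_config()) {
  stopifnot(inherits(complex, "StructureModel"))
  if (is.null(complex$partition))
    stop("interface_bsa needs a chain partition (two named groups)",
         call. = FALSE)
  sides <- names(complex$partition)
  sasa_cx <- compute_sasa(complex, probe_radius, n_points)
  per_res <- NULL
  for (s in sides) {
    alone <- subset_model(complex, complex$partition[[s]])
    sasa_alone <- compute_sasa(alone, probe_radius, n_points)
    pr <- sasa_alone$per_residue
    cx <- sasa_cx$per_residue
    m <- match(paste(pr$chain, pr$resno, pr$ins),
               paste(cx$chain, cx$resno, cx$ins))
    pr$bsa <- pmax(pr$sasa - cx$sasa[m], 0)
    pr$bsa[pr$bsa < 1e-9] <- 0
    pr$side <- s
    pr$sasa <- NULL
    per_res <- rbind(per_res, pr)
  }
  per_res <- per_res[, c("side", "chain", "resno", "ins", "resid", "bsa")]
  totals <- vapply(sides, function(s) sum(per_res$bsa[per_res$side == s]),
                   numeric(1))

  fractions <- NULL
  if (!is.null(regions)) {
    per_res$label <- NA_character_
    per_res$region <- NA_character_
    for (cid in names(regions)) {
      mp <- map_chain_regions(complex, cid, regions[[cid]], by = map_by)
      i <- match(paste(cid, mp$resno, mp$ins),
                 paste(per_res$chain, per_res$resno, per_res$ins))
      per_res$label[i] <- mp$label
      per_res$region[i] <- mp$region
    }
    per_res$region_class <- ifelse(is.na(per_res$region), NA_character_,
                                   ifelse(is_cdr(per_res$region),
                                          "CDR", "framework"))
    fractions <- list()
    for (s in sides) {
      rows <- per_res[per_res$side == s & !is.na(per_res$region_class), ]
      if (nrow(rows) == 0L || sum(rows$bsa) == 0) next
      tot <- sum(rows$bsa)
      fractions[[s]] <- c(
        CDR = sum(rows$bsa[rows$region_class == "CDR"]) / tot,
        framework = sum(rows$bsa[rows$region_class == "framework"]) / tot)
    }
  }

  cts <- if (contacts) detect_contacts(complex, config = contact_config)
         else NULL
  structure(list(per_residue = per_res, totals = totals,
                 fraction_bsa_by_region_class = fractions,
                 contacts = cts,
                 probe_radius = probe_radius, n_points = n_points,
                 bsa_convention = "side-alone minus complex, per residue; side totals are sums over that side",
                 boundary_table = if (!is.null(regions))
                   "bundled cdr_boundaries.csv (canonical Kabat/IMGT definitions)"
                 else NULL,
                 model_id = complex$model_id),
            class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf("InterfaceReport %s\n", x$model_id))
  for (s in names(x$totals))
    cat(sprintf("  %s: total BSA %.1f A^2 over %d residues\n", s,
                x$totals[[s]],
                sum(x$per_residue$side == s & x$per_residue$bsa > 0)))
  if (!is.null(x$fraction_bsa_by_region_class))
    for (s in names(x$fraction_bsa_by_region_class)) {
      f <- x$fraction_bsa_by_region_class[[s]]
      cat(sprintf("  %s region split: CDR %.1f%%, framework %.1f%%\n", s,
                  100 * f[["CDR"]], 100 * f[["framework"]]))
    }
  if (!is.null(x$contacts))
    cat(sprintf("  contacts: %d (%s)\n", nrow(x$contacts),
                paste(names(table(x$contacts$type)), table(x$contacts$type),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write an interface report as JSON or TSV
#'
#' @param report An \code{InterfaceReport}.
#' @param path Output file.
#' @param format \code{"json"} or \code{"tsv"} (per-residue table only).
#' @export
write_interface_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report$per_residue, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    obj <- unclass(report)
    obj$totals <- as.list(obj$totals)
    if (!is.null(obj$fraction_bsa_by_region_class))
      obj$fraction_bsa_by_region_class <-
        lapply(obj$fraction_bsa_by_region_class, as.list)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
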