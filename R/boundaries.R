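REGIONS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' CDR/framework boundary table for a numbering scheme
#'
#' Returns the bundled region boundary definitions (Kabat or IMGT) for one
#' chain class. Boundaries are shipped as packaged data
#' (\code{inst/extdata/cdr_boundaries.csv}) and follow the canonical
#' published definitions; they are cited in every report that uses them.
#'
#' @param scheme \code{"kabat"} or \code{"imgt"}.
#' @param chain_class \code{"heavy"}, \code{"kappa"} or \code{"lambda"}.
#' @return A data frame with class \code{CdrBoundaryTable}: columns
#'   \code{region}, \code{start}, \code{end} (scheme position numbers),
#'   plus \code{scheme}/\code{chain_class} attributes.
#' @export
#' @examples
#' cdr_boundary_table("kabat", "heavy")
cdr_boundary_table <- function(scheme = c("kabat", "imgt"),
                               chain_class = c("heavy", "kappa", "lambda")) {
  scheme <- match.arg(scheme)
  chain_class <- match.arg(chain_class)
  all <- read_bundled_csv("cdr_boundaries.csv")
  tab <- all[all$scheme == scheme & all$chain_class == chain_class,
             c("region", "start", "end")]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  stopifnot(nrow(tab) == 7L, all(tab$start <= tab$end),
            all(tab$region == REGIONS))
  structure(tab, scheme = scheme, chain_class = chain_class,
            class = c("CdrBoundaryTable", "data.frame"))
}

# vectorised region lookup by scheme position
region_of <- function(number, ins, table) {
  key <- position_key(number, ins)
  region <- rep(NA_character_, length(key))
  for (i in seq_len(nrow(table))) {
    hit <- key >= table$start[i] & key < table$end[i] + 1
    region[hit] <- table$region[i]
  }
  region
}

is_cdr <- function(region) region %in% c("CDR1", "CDR2", "CDR3")
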