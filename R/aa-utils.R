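#' @keywords internal
"_PACKAGE"

# one-letter alphabet accepted throughout: 20 standard residues plus X
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

aa_three_to_one <- function(resid) {
  out <- unname(AA_THREE_TO_ONE[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

validate_residues <- function(residues, what = "sequence") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues) ||
      nchar(residues) == 0L)
    stop(what, " must be a non-empty character string", call. = FALSE)
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA_LETTERS, "X"))
  if (length(bad))
    stop(what, " contains invalid residue letters: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  invisible(residues)
}

# total ordering key for scheme positions: insertion codes sort after the
# parent number and before the next integer ("100" < "100A" < "100B" < "101")
position_key <- function(number, ins) {
  ins <- ifelse(is.na(ins) | ins == "", 0L, match(ins, LETTERS))
  as.numeric(number) + ins / 100
}

# "82A" -> number 82, ins "A"; "82" -> ins ""
parse_position_label <- function(label) {
  number <- as.integer(sub("([0-9]+)[A-Z]?$", "\\1", label))
  ins <- sub("^[0-9]+", "", label)
  data.frame(number = number, ins = ins, stringsAsFactors = FALSE)
}

format_position_label <- function(number, ins) {
  paste0(number, ifelse(is.na(ins) | ins == "", "", ins))
}

# package-local cache for bundled tables
.abgraft_cache <- new.env(parent = emptyenv())

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "abgraft")
  if (path == "") {
    # allow use from a source checkout during development
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path))
    stop("bundled data file not found: ", file, call. = FALSE)
  path
}

read_bundled_csv <- function(file) {
  key <- paste0("csv:", file)
  if (!exists(key, envir = .abgraft_cache)) {
    assign(key,
           utils::read.csv(extdata_path(file), stringsAsFactors = FALSE,
                           colClasses = "character"),
           envir = .abgraft_cache)
  }
  get(key, envir = .abgraft_cache)
}
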