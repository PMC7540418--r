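# Shared codon machinery: the standard genetic code (via Biostrings), sense
# codon enumeration, and the bundled canonical amino-acid substitution
# matrices used for radicality scoring.

.cd_env <- new.env(parent = emptyenv())

.geneticCode <- function() {
  if (is.null(.cd_env$gc)) .cd_env$gc <- Biostrings::GENETIC_CODE
  .cd_env$gc
}

#' Translate codons under the standard genetic code
#'
#' @param codons character vector of 3-letter codons (A/C/G/T).
#' @return character vector of one-letter amino acids, \code{"*"} for stop.
#' @export
translateCodon <- function(codons) {
  aa <- unname(.geneticCode()[toupper(codons)])
  if (anyNA(aa)) stop("non-ACGT codon passed to translateCodon: ",
                      paste(codons[is.na(aa)], collapse = ", "))
  aa
}

#' Sense codons of the standard code
#'
#' @return character vector of the 61 non-stop codons.
#' @export
senseCodons <- function() {
  gc <- .geneticCode()
  names(gc)[gc != "*"]
}

.isStopCodon <- function(codons) .geneticCode()[toupper(codons)] == "*"

# mutate codon string(s) at position pos (1..3) to nt
.mutateCodon <- function(codon, pos, nt) {
  substr(codon, pos, pos) <- nt
  codon
}

#' Load a bundled canonical substitution matrix
#'
#' Parses the canonical NCBI-format PAM100 or BLOSUM90 file shipped with the
#' package and returns the integer score matrix.
#'
#' @param name \code{"PAM100"} or \code{"BLOSUM90"}.
#' @return integer matrix with amino-acid row/column names.
#' @examples
#' m <- substitutionMatrix("BLOSUM90")
#' m["W", "G"]
#' @export
substitutionMatrix <- function(name = c("PAM100", "BLOSUM90")) {
  name <- match.arg(name)
  key <- paste0("mat_", name)
  if (!is.null(.cd_env[[key]])) return(.cd_env[[key]])
  path <- system.file("extdata", paste0(name, ".txt"), package = "clonedecay")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  rownames(m) <- vapply(rows, `[`, "", 1)
  colnames(m) <- header
  .cd_env[[key]] <- m
  m
}

#' Radicality score of an amino-acid replacement
#'
#' Looks up the replacement in the canonical PAM100 or BLOSUM90 matrix; lower
#' scores mean more radical (physico-chemically disruptive) changes. Stop
#' symbols are rejected: stop-gains are tallied separately, not scored.
#'
#' @param aa_from,aa_to one-letter amino acids (vectorised, equal length).
#' @param matrix \code{"PAM100"} (default) or \code{"BLOSUM90"}.
#' @return integer score(s).
#' @examples
#' radicalityScore("I", "L")            # conservative, high score
#' radicalityScore("W", "G")            # radical, low score
#' @export
radicalityScore <- function(aa_from, aa_to, matrix = c("PAM100", "BLOSUM90")) {
  m <- substitutionMatrix(match.arg(matrix))
  aa_from <- toupper(aa_from); aa_to <- toupper(aa_to)
  if (any(aa_from == "*" | aa_to == "*"))
    stop("stop symbol has no radicality score; tally stop-gains separately")
  std <- rownames(m)[rownames(m) != "*"]
  bad <- !(aa_from %in% std) | !(aa_to %in% std)
  if (any(bad)) stop("unknown amino acid: ",
                     paste(unique(c(aa_from[bad], aa_to[bad])), collapse = ", "))
  m[cbind(aa_from, aa_to)]
}
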