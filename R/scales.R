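#' Read a propensity scale from a plain-text config file
#'
#' Scales are stored one residue per line as `X=value`; lines starting with
#' `#` are comments. A valid scale has exactly one finite value per canonical
#' amino acid.
#'
#' @param path file path.
#' @param name scale label; defaults to the file name.
#' @return a [PropensityScale-class].
#' @export
readScale <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("scale file must contain 'X=value' lines: ", path)
  keys <- toupper(trimws(vapply(parts, `[`, "", 1L)))
  vals <- as.numeric(trimws(vapply(parts, `[`, "", 2L)))
  if (anyDuplicated(keys)) stop("duplicate residue in scale file: ", path)
  names(vals) <- keys
  PropensityScale(vals, name = name)
}

#' Built-in propensity scales
#'
#' Shipped scales: `"chou_fasman_alpha"` and `"chou_fasman_beta"`
#' (helix/sheet conformational propensities), `"top_idp"` (disorder
#' propensity), `"kyte_doolittle"` (hydropathy).
#'
#' @param which scale name.
#' @return a [PropensityScale-class].
#' @examples
#' builtinScale("chou_fasman_alpha")
#' @export
builtinScale <- function(which = c("chou_fasman_alpha", "chou_fasman_beta",
                                   "top_idp", "kyte_doolittle")) {
  which <- match.arg(which)
  readScale(tailorderFile(paste0(which, ".txt")), name = which)
}

#' Look up scale values for a sequence
#'
#' @param scale a [PropensityScale-class].
#' @param sequence amino-acid string or character vector of residues.
#' @return numeric vector, one value per residue.
#' @export
scaleValues <- function(scale, sequence) {
  stopifnot(is(scale, "PropensityScale"))
  res <- if (length(sequence) == 1L && nchar(sequence) > 1L)
    strsplit(sequence, "")[[1]] else sequence
  unname(scale@values[res])
}

#' Read a physicochemical amino-acid partition
#'
#' Config format: one class per line, `class_name=RESIDUES`. Classes must be
#' disjoint and jointly cover all 20 amino acids. The default shipped
#' partition is hydrophobic / aromatic / polar-uncharged / positive /
#' negative / special (G, P, C).
#'
#' @param path config path; default is the shipped partition.
#' @return named list of character vectors of residues.
#' @export
readAAClasses <- function(path = tailorderFile("aa_classes.txt")) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  classes <- lapply(parts, function(p) strsplit(toupper(trimws(p[2])), "")[[1]])
  names(classes) <- trimws(vapply(parts, `[`, "", 1L))
  all <- unlist(classes)
  if (anyDuplicated(all) || !setequal(all, AMINO_ACIDS))
    stop("classes must partition the 20 canonical amino acids")
  classes
}

#' Read peptides from a FASTA file
#'
#' Thin wrapper over Biostrings; the description line is parsed as the id.
#'
#' @param path FASTA file.
#' @return list of [Peptide-class] objects.
#' @export
readPeptideFASTA <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  mapply(function(s, id) Peptide(s, id = id),
         as.character(ss), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write peptides to a FASTA file
#'
#' @param peptides a [Peptide-class] or list of them.
#' @param path output file.
#' @export
writePeptideFASTA <- function(peptides, path) {
  if (is(peptides, "Peptide")) peptides <- list(peptides)
  seqs <- vapply(peptides, function(p) p@sequence, "")
  names(seqs) <- vapply(peptides, function(p) p@id, "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path)
  invisible(path)
}
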