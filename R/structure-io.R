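# PDB / FASTA / Clustal input-output.  Parsing of PDB records is delegated to
# bio3d::read.pdb; this layer enforces the pipeline's policies on top of it:
# first MODEL only, waters and non-amino-acid heteroatoms dropped, one altloc
# per atom (highest occupancy, alphabetical tie-break), occupancy clamped to
# [0, 1] with a warning.

#' Parse a PDB-format structure
#'
#' @param text PDB-format content: a single string or a character vector of
#'   lines.
#' @param modelId Identifier recorded on the returned model.
#' @param taxonLabel Optional free-text organism label.
#' @return A [StructureModel-class].
#'
#' @details Only the first `MODEL` of a multi-model file is read.  `HETATM`
#'   waters (HOH/WAT/DOD) and heteroatoms that are not standard amino acids
#'   are excluded.  When alternate locations are present, the
#'   highest-occupancy altloc is kept per atom; ties go to the alphabetically
#'   first tag.  Out-of-range occupancies are clamped to \[0, 1\] with a
#'   warning.  A file without ATOM records, or with a coordinate field that
#'   does not parse, is an error (the latter names the offending line).
#' @seealso [readStructure()] for files, [writeStructure()] for output.
#' @export
parseStructure <- function(text, modelId, taxonLabel = "") {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }
  ## First MODEL only.
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1L] - 1L)]

  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records found; not a PDB structure")
  coord_txt <- substr(lines[rec], 31L, 54L)
  xyz <- suppressWarnings(cbind(
    as.numeric(substr(coord_txt, 1L, 8L)),
    as.numeric(substr(coord_txt, 9L, 16L)),
    as.numeric(substr(coord_txt, 17L, 24L))
  ))
  if (anyNA(xyz)) {
    bad <- which(rec)[which(rowSums(is.na(xyz)) > 0)[1L]]
    stop(sprintf("malformed coordinate field at line %d", bad))
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom

  ## Drop waters and non-amino-acid HETATMs.
  water <- toupper(at$resid) %in% c("HOH", "WAT", "DOD")
  nonaa_het <- at$type == "HETATM" & !(toupper(at$resid) %in% names(.AA3))
  at <- at[!(water | nonaa_het), , drop = FALSE]
  if (!nrow(at)) stop("no amino-acid atoms remain after filtering")

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  if (any(at$o < 0 | at$o > 1)) {
    warning("occupancy outside [0, 1]; clamping")
    at$o <- pmin(1, pmax(0, at$o))
  }

  ## Altloc policy: highest occupancy, tie -> alphabetically first tag.
  ## Winners are selected per atom key but file order is preserved.
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  winners <- sort(ord[!duplicated(key[ord])])
  at <- at[winners, , drop = FALSE]

  at$chain[is.na(at$chain)] <- " "
  keep <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "b")
  if (any(!nzchar(at$elesy) | is.na(at$elesy))) {
    ## Fall back on the first letter of the atom name when the element
    ## column is blank (common in old or program-written files).
    miss <- !nzchar(at$elesy) | is.na(at$elesy)
    at$elesy[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1L, 1L)
  }
  StructureModel(at[, keep], modelId = modelId, taxonLabel = taxonLabel)
}

#' Read a PDB file
#'
#' @param path Path to a PDB-format file.
#' @param modelId Identifier; defaults to the file basename without extension.
#' @param taxonLabel Optional taxon label.
#' @return A [StructureModel-class].
#' @export
readStructure <- function(path, modelId = sub("\\.[^.]*$", "", basename(path)),
                          taxonLabel = "") {
  parseStructure(readLines(path, warn = FALSE), modelId = modelId,
                 taxonLabel = taxonLabel)
}

#' Write a StructureModel in PDB format
#'
#' Fixed-width PDB v3.3 ATOM records with coordinates at 8.3f precision; a
#' TER record after each chain.  Sufficient for round-tripping the package's
#' fixtures at the format's own 1e-3 angstrom precision.
#'
#' @param model A [StructureModel-class].
#' @param file Optional path; when `NULL` the text is returned only.
#' @return Invisibly, the character vector of PDB lines.
#' @export
writeStructure <- function(model, file = NULL) {
  at <- model@atoms
  fmt_name <- function(n) ifelse(nchar(n) >= 4L, substr(n, 1L, 4L),
                                 sprintf(" %-3s", n))
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, fmt_name(sub$elety[i]), sub$resid[i], ch, sub$resno[i],
        ifelse(nzchar(sub$insert[i]), sub$insert[i], " "),
        sub$x[i], sub$y[i], sub$z[i], sub$o[i], sub$b[i], sub$elesy[i]))
    }
    serial <- serial + 1L
    last <- sub[nrow(sub), ]
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d", serial,
                              last$resid, ch, last$resno))
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' One-letter sequence of a chain
#'
#' Translates 3-letter residue names to the 20-letter alphabet; anything
#' outside the 20 standard amino acids (e.g. MSE) becomes `"X"`.
#'
#' @param model A [StructureModel-class].
#' @param chain Chain id; defaults to the first chain.
#' @return Single character string, one letter per residue, named by the
#'   chain id.
#' @export
chainSequence <- function(model, chain = chainIds(model)[1L]) {
  rt <- residueTable(model, chain)
  stats::setNames(paste(aa_three_to_one(rt$resid), collapse = ""), chain)
}

## ---- alignments -----------------------------------------------------------

#' Parse a multiple sequence alignment
#'
#' Accepts gapped FASTA or Clustal text (any Clustal consensus line is
#' ignored).  The format is auto-detected from the header line.
#'
#' @param text Alignment content: single string or character vector of lines.
#' @return A [ProteinAlignment-class].
#' @export
parseAlignment <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }
  first <- lines[nzchar(trimws(lines))][1L]
  if (is.na(first)) stop("empty alignment input")
  tf <- tempfile(fileext = ".aln")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    aln <- Biostrings::readAAMultipleAlignment(tf, format = "clustal")
    seqs <- as.character(aln)
  } else {
    ss <- Biostrings::readAAStringSet(tf)
    seqs <- stats::setNames(as.character(ss), names(ss))
    ## First whitespace-delimited token is the id, FASTA convention.
    names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  }
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  ProteinAlignment(seqs)
}

#' Read an alignment file (FASTA or Clustal)
#'
#' @param path File path.
#' @return A [ProteinAlignment-class].
#' @export
readAlignment <- function(path) parseAlignment(readLines(path, warn = FALSE))

#' Write an alignment as gapped FASTA
#'
#' @param aln A [ProteinAlignment-class].
#' @param file Optional path; when `NULL` the text is returned only.
#' @return Invisibly, the character vector of FASTA lines.
#' @export
writeAlignment <- function(aln, file = NULL) {
  lines <- as.vector(rbind(paste0(">", aln@ids), aln@seqs))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
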