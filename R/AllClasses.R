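#' @import methods
NULL

#' StructureModel: a parsed atomic protein structure
#'
#' Container for one structure (one model of a PDB entry or a synthetic
#' fixture).  Atoms are held as a flat table, one row per atom, ordered by
#' chain, residue number and insertion code; residue- and chain-level views
#' are provided by accessors rather than nested objects.
#'
#' @slot modelId Accession-style identifier (e.g. a PDB or model-database id).
#' @slot taxonLabel Free-text organism/taxon label (may be empty).
#' @slot atoms `data.frame` with columns `chain`, `resno` (author residue
#'   number), `insert` (insertion code, `""` when absent), `resid` (3-letter
#'   residue name), `elety` (atom name, e.g. `"CA"`), `elesy` (element
#'   symbol), `x`, `y`, `z` (angstrom), `o` (occupancy), `b` (B-factor).
#'
#' @seealso [parseStructure()], [writeStructure()], [atoms()], [coords()]
#' @export
setClass("StructureModel",
  representation(
    modelId = "character",
    taxonLabel = "character",
    atoms = "data.frame"
  )
)

setValidity("StructureModel", function(object) {
  msg <- character()
  at <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "b")
  if (!all(need %in% names(at))) {
    return(paste("atoms table must contain columns:",
                 paste(setdiff(need, names(at)), collapse = ", ")))
  }
  if (nrow(at) < 1L) msg <- c(msg, "structure must contain at least one atom")
  if (nrow(at) >= 1L) {
    if (!all(is.finite(as.matrix(at[, c("x", "y", "z")])))) {
      msg <- c(msg, "atom coordinates must be finite")
    }
    if (any(!nzchar(at$elesy))) msg <- c(msg, "element symbols must be non-empty")
    if (any(at$o < 0 | at$o > 1)) msg <- c(msg, "occupancies must lie in [0, 1]")
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    if (anyDuplicated(key)) {
      msg <- c(msg, "duplicate atom for a (chain, resno, insert, name) after altloc resolution")
    }
  }
  if (length(object@modelId) != 1L || !nzchar(object@modelId)) {
    msg <- c(msg, "modelId must be a single non-empty string")
  }
  if (length(msg)) msg else TRUE
})

#' ProteinAlignment: a multiple sequence alignment
#'
#' @slot ids Sequence identifiers (unique).
#' @slot seqs Gapped, uppercase residue strings, all of equal length.
#' @slot nCols Number of alignment columns.
#'
#' @seealso [parseAlignment()], [columnConservation()]
#' @export
setClass("ProteinAlignment",
  representation(ids = "character", seqs = "character", nCols = "integer")
)

setValidity("ProteinAlignment", function(object) {
  msg <- character()
  if (length(object@ids) < 2L) msg <- c(msg, "alignment needs at least 2 rows")
  if (length(object@ids) != length(object@seqs)) {
    msg <- c(msg, "ids and seqs lengths differ")
  }
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate sequence ids")
  w <- nchar(object@seqs)
  if (length(w) && any(w != object@nCols)) {
    bad <- object@ids[which(w != object@nCols)[1L]]
    msg <- c(msg, sprintf("row '%s' length differs from nCols", bad))
  }
  if (length(object@seqs) && any(grepl("[a-z]", object@seqs))) {
    msg <- c(msg, "sequences must be uppercase")
  }
  if (length(msg)) msg else TRUE
})

#' RigidTransform: a proper rotation plus translation
#'
#' Applying the transform maps a coordinate row-vector `x` to
#' `rotation %*% x + translation`.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation Length-3 numeric vector (angstrom).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8) {
      msg <- c(msg, "rotation must be orthonormal (within 1e-8)")
    }
    if (abs(det(R) - 1) > 1e-8) {
      msg <- c(msg, "rotation must be proper (det +1); reflections are not rigid motions")
    }
  }
  if (length(object@translation) != 3L || !all(is.finite(object@translation))) {
    msg <- c(msg, "translation must be a finite 3-vector")
  }
  if (length(msg)) msg else TRUE
})

#' SuperpositionResult: outcome of iterative common-core superposition
#'
#' @slot transform The [RigidTransform-class] mapping target onto reference.
#' @slot pairs `data.frame` with columns `ref_resno`, `target_resno`: the
#'   residue pairs retained in the final fit.
#' @slot rmsd Calpha RMSD (angstrom) over the final pairs.
#' @slot fractionMatched Final pairs as a percentage of the residue count of
#'   the *target* chain (always target-relative; see the vignette).
#' @slot nIterations Iterations used until the pair set stabilised.
#' @export
setClass("SuperpositionResult",
  representation(
    transform = "RigidTransform",
    pairs = "data.frame",
    rmsd = "numeric",
    fractionMatched = "numeric",
    nIterations = "integer"
  )
)

setValidity("SuperpositionResult", function(object) {
  msg <- character()
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (object@fractionMatched <= 0 || object@fractionMatched > 100) {
    msg <- c(msg, "fractionMatched must lie in (0, 100]")
  }
  if (anyDuplicated(object@pairs$ref_resno) ||
      anyDuplicated(object@pairs$target_resno)) {
    msg <- c(msg, "pairs must be unique on both sides")
  }
  if (length(msg)) msg else TRUE
})

#' CatalyticTriad: locators of the His/Asp/Ser catalytic residues
#'
#' Residue locators are length-2 character vectors `c(chain, resno)`; residue
#' numbers follow the author numbering of the source file (e.g. His57, Asp102,
#' Ser195 in chymotrypsin numbering).  A residue whose type does not match the
#' expected His/Asp/Ser raises a warning, not an error: predicted models may
#' genuinely differ.
#'
#' @slot his,asp,ser Character vectors `c(chain, resno)`.
#' @slot referenceLabels The chymotrypsin-numbering names of the three sites.
#' @export
setClass("CatalyticTriad",
  representation(his = "character", asp = "character", ser = "character",
                 referenceLabels = "numeric")
)

setValidity("CatalyticTriad", function(object) {
  locs <- list(object@his, object@asp, object@ser)
  if (any(vapply(locs, length, 1L) != 2L)) {
    return("each locator must be c(chain, resno)")
  }
  keys <- vapply(locs, paste, "", collapse = ":")
  if (anyDuplicated(keys)) return("the three triad residues must be distinct")
  TRUE
})

#' TriadGeometry: the three catalytic-triad Calpha distances
#'
#' @slot dAspHis,dHisSer,dAspSer Calpha--Calpha distances in angstrom.
#' @export
setClass("TriadGeometry",
  representation(dAspHis = "numeric", dHisSer = "numeric", dAspSer = "numeric")
)

setValidity("TriadGeometry", function(object) {
  d <- c(object@dAspHis, object@dHisSer, object@dAspSer)
  if (any(d < 0)) return("distances must be >= 0")
  ## Three Calpha-Calpha distances of real points always satisfy the
  ## triangle inequality; tolerate only numerical noise.
  if (max(d) > sum(d) - max(d) + 1e-9) {
    return("distances violate the triangle inequality")
  }
  TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  at <- object@atoms
  cat(sprintf("StructureModel '%s'%s: %d atoms, %d residues, chains: %s\n",
              object@modelId,
              if (nzchar(object@taxonLabel)) paste0(" (", object@taxonLabel, ")") else "",
              nrow(at),
              length(unique(paste(at$chain, at$resno, at$insert))),
              paste(unique(at$chain), collapse = ", ")))
})

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns\n",
              length(object@ids), object@nCols))
  n <- min(5L, length(object@ids))
  w <- min(50L, object@nCols)
  for (i in seq_len(n)) {
    cat(sprintf("  %-12s %s%s\n", object@ids[i],
                substr(object@seqs[i], 1L, w),
                if (object@nCols > w) "..." else ""))
  }
  if (length(object@ids) > n) cat(sprintf("  ... %d more rows\n", length(object@ids) - n))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(sprintf("%.3f", object@translation), collapse = " "), "\n")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf(
    "SuperpositionResult: %d pairs, rmsd %.3f A, %.1f%% of target residues matched (%d iterations)\n",
    nrow(object@pairs), object@rmsd, object@fractionMatched, object@nIterations))
})

setMethod("show", "CatalyticTriad", function(object) {
  cat(sprintf("CatalyticTriad: His %s:%s  Asp %s:%s  Ser %s:%s (reference numbering %s)\n",
              object@his[1], object@his[2], object@asp[1], object@asp[2],
              object@ser[1], object@ser[2],
              paste(object@referenceLabels, collapse = "/")))
})

setMethod("show", "TriadGeometry", function(object) {
  cat(sprintf("TriadGeometry (Calpha-Calpha, A): Asp-His %.2f  His-Ser %.2f  Asp-Ser %.2f\n",
              object@dAspHis, object@dHisSer, object@dAspSer))
})

## ---- constructors and accessors -------------------------------------------

#' Construct a StructureModel from an atom table
#'
#' Mostly used by the synthetic generators and by tests; end users usually get
#' models from [parseStructure()].  Atom rows are sorted by chain, residue
#' number and insertion code.
#'
#' @param atoms Atom `data.frame` (see [StructureModel-class]).
#' @param modelId Identifier string.
#' @param taxonLabel Optional taxon label.
#' @return A [StructureModel-class].
#' @export
StructureModel <- function(atoms, modelId, taxonLabel = "") {
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"o" %in% names(atoms)) atoms$o <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), , drop = FALSE]
  rownames(atoms) <- NULL
  new("StructureModel", modelId = modelId, taxonLabel = taxonLabel,
      atoms = atoms)
}

#' Construct a ProteinAlignment from gapped strings
#'
#' @param seqs Named character vector (or unnamed with `ids` given) of
#'   equal-length gapped residue strings.
#' @param ids Sequence identifiers; defaults to `names(seqs)`.
#' @return A [ProteinAlignment-class].
#' @export
ProteinAlignment <- function(seqs, ids = names(seqs)) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  seqs <- toupper(unname(seqs))
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    bad <- ids[which(w != w[1L])[1L]]
    stop(sprintf("alignment rows have unequal lengths (row '%s')", bad))
  }
  new("ProteinAlignment", ids = ids, seqs = seqs, nCols = as.integer(w[1L]))
}

#' Construct a CatalyticTriad
#'
#' @param his,asp,ser Residue locators, either `c(chain, resno)` or a string
#'   `"A:57"`.
#' @param referenceLabels Chymotrypsin-numbering labels of the three sites.
#' @return A [CatalyticTriad-class].
#' @export
catalyticTriad <- function(his, asp, ser, referenceLabels = c(57, 102, 195)) {
  parse_loc <- function(x) {
    if (length(x) == 1L && grepl(":", x)) x <- strsplit(x, ":", fixed = TRUE)[[1L]]
    as.character(x)
  }
  new("CatalyticTriad", his = parse_loc(his), asp = parse_loc(asp),
      ser = parse_loc(ser), referenceLabels = referenceLabels)
}

#' @describeIn StructureModel-class Atom table accessor.
#' @param x A `StructureModel`.
#' @export
atoms <- function(x) x@atoms

#' @describeIn StructureModel-class N x 3 coordinate matrix (angstrom).
#' @export
coords <- function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @describeIn StructureModel-class Model identifier.
#' @export
modelId <- function(x) x@modelId

#' @describeIn StructureModel-class Taxon label.
#' @export
taxonLabel <- function(x) x@taxonLabel

#' @describeIn StructureModel-class Chain identifiers present.
#' @export
chainIds <- function(x) unique(x@atoms$chain)

#' Residue-level view of one chain
#'
#' @param x A [StructureModel-class].
#' @param chain Chain identifier; defaults to the first chain.
#' @return `data.frame` with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, in file order.
#' @export
residueTable <- function(x, chain = chainIds(x)[1L]) {
  at <- x@atoms[x@atoms$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' not found in model '%s'", chain, x@modelId))
  key <- !duplicated(paste(at$resno, at$insert))
  out <- at[key, c("chain", "resno", "insert", "resid"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coordinates of one named atom per residue along a chain
#'
#' @param x A [StructureModel-class].
#' @param chain Chain id.
#' @param elety Atom name (default `"CA"`).
#' @return Matrix of coordinates with rownames set to residue numbers
#'   (`resno` pasted with any insertion code); residues lacking the atom are
#'   omitted.
#' @export
namedAtomCoords <- function(x, chain = chainIds(x)[1L], elety = "CA") {
  at <- x@atoms[x@atoms$chain == chain & x@atoms$elety == elety, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- paste0(at$resno, at$insert)
  m
}

#' Replace the coordinates of a model
#'
#' @param x A [StructureModel-class].
#' @param value N x 3 matrix in atom-row order.
#' @return The modified model.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(nrow(value) == nrow(x@atoms), ncol(value) == 3L)
  x@atoms$x <- value[, 1L]
  x@atoms$y <- value[, 2L]
  x@atoms$z <- value[, 3L]
  validObject(x)
  x
}

#' @describeIn ProteinAlignment-class Alignment as a character matrix
#'   (rows = sequences, columns = alignment columns).
#' @param x A `ProteinAlignment`.
#' @export
alignmentMatrix <- function(x) {
  m <- do.call(rbind, strsplit(x@seqs, "", fixed = TRUE))
  rownames(m) <- x@ids
  m
}

#' @describeIn ProteinAlignment-class Sequence identifiers.
#' @export
alignmentIds <- function(x) x@ids

#' @describeIn ProteinAlignment-class Gapped row strings, named by id.
#' @export
alignmentRows <- function(x) stats::setNames(x@seqs, x@ids)

setMethod("dim", "ProteinAlignment", function(x) c(length(x@ids), x@nCols))

## Accessors for superposition results / transforms.

#' @describeIn SuperpositionResult-class The rigid transform.
#' @param x A `SuperpositionResult`.
#' @export
transform <- function(x) x@transform

#' @describeIn SuperpositionResult-class Final residue pairs.
#' @export
corePairs <- function(x) x@pairs

#' @describeIn SuperpositionResult-class Final-core RMSD (angstrom).
#' @export
rmsd <- function(x) x@rmsd

#' @describeIn SuperpositionResult-class Matched fraction of target residues (%).
#' @export
fractionMatched <- function(x) x@fractionMatched

#' @describeIn RigidTransform-class Rotation matrix.
#' @param x A `RigidTransform`.
#' @export
rotation <- function(x) x@rotation

#' @describeIn RigidTransform-class Translation vector.
#' @export
translation <- function(x) x@translation

#' @describeIn TriadGeometry-class The three distances as a named vector
#'   (`d_asp_his`, `d_his_ser`, `d_asp_ser`), angstrom.
#' @param x A `TriadGeometry`.
#' @export
triadDistances <- function(x) {
  c(d_asp_his = x@dAspHis, d_his_ser = x@dHisSer, d_asp_ser = x@dAspSer)
}
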