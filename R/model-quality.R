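# Geometry-based model validation: phi/psi/omega dihedrals, four-region
# Ramachandran summaries, heavy-atom clashscore, and bond length/angle RMSD
# against standard values.

#' Backbone dihedral angles of a chain
#'
#' IUPAC conventions: phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1), omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i).  Angles are
#' degrees in (-180, 180].  The first residue has no phi/omega and the last
#' no psi; a chain break (peptide C--N distance above `breakDistance`) splits
#' the computation the same way, and any missing backbone atom leaves the
#' affected dihedrals `NA` rather than erroring.
#'
#' @param model A [StructureModel-class].
#' @param chain Chain id (default: first chain).
#' @param breakDistance C--N distance (angstrom) above which consecutive
#'   residues are treated as disconnected (default 2.5).
#' @return `data.frame` with columns `chain`, `resno`, `insert`, `resid`,
#'   `phi`, `psi`, `omega` (`NA` where undefined).
#' @export
backboneDihedrals <- function(model, chain = chainIds(model)[1L],
                              breakDistance = 2.5) {
  rt <- residueTable(model, chain)
  at <- model@atoms[model@atoms$chain == chain, , drop = FALSE]
  n <- nrow(rt)
  get_atom <- function(i, name) {
    sel <- at$resno == rt$resno[i] & at$insert == rt$insert[i] & at$elety == name
    if (!any(sel)) return(NULL)
    r <- at[which(sel)[1L], ]
    c(r$x, r$y, r$z)
  }
  Natm <- lapply(seq_len(n), get_atom, "N")
  CAatm <- lapply(seq_len(n), get_atom, "CA")
  Catm <- lapply(seq_len(n), get_atom, "C")
  linked <- function(i) {
    # is residue i peptide-bonded to residue i+1?
    if (i < 1L || i >= n) return(FALSE)
    if (is.null(Catm[[i]]) || is.null(Natm[[i + 1L]])) return(FALSE)
    vnorm(Catm[[i]] - Natm[[i + 1L]]) <= breakDistance
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok <- !is.null(Natm[[i]]) && !is.null(CAatm[[i]]) && !is.null(Catm[[i]])
    if (!ok) next
    if (i > 1L && linked(i - 1L)) {
      phi[i] <- dihedral4(Catm[[i - 1L]], Natm[[i]], CAatm[[i]], Catm[[i]])
      if (!is.null(CAatm[[i - 1L]])) {
        omega[i] <- dihedral4(CAatm[[i - 1L]], Catm[[i - 1L]], Natm[[i]], CAatm[[i]])
      }
    }
    if (i < n && linked(i)) {
      psi[i] <- dihedral4(Natm[[i]], CAatm[[i]], Catm[[i]], Natm[[i + 1L]])
    }
  }
  data.frame(chain = rt$chain, resno = rt$resno, insert = rt$insert,
             resid = rt$resid, phi = phi, psi = psi, omega = omega,
             stringsAsFactors = FALSE)
}

## ---- Ramachandran region map ----------------------------------------------

## A 10 x 10 degree grid over the phi-psi torus with four region labels.
## Cores (most favoured) are rectangles approximating the beta, right-handed
## alpha and left-handed alpha basins of the classic PROCHECK map; the
## additional-allowed and generously-allowed regions are one and two
## 8-neighbour grid dilations of the cores (wrapping at +/-180).  This is an
## approximation bundled for self-contained classification -- see the
## vignette -- and is replaceable via the `map` argument of
## ramachandranSummary().
.rama_map_cache <- new.env(parent = emptyenv())

#' Build (or fetch) the bundled four-region Ramachandran map
#'
#' @return 36 x 36 integer matrix over 10-degree cells (rows: phi from -180;
#'   columns: psi from -180) with values 1 = most favoured, 2 = additional
#'   allowed, 3 = generously allowed, 4 = disallowed.
#' @export
ramachandranMap <- function() {
  if (!is.null(.rama_map_cache$map)) return(.rama_map_cache$map)
  n <- 36L
  cells_in <- function(phi_lim, psi_lim) {
    centers <- seq(-175, 175, by = 10)
    pi_idx <- which(centers >= phi_lim[1L] & centers <= phi_lim[2L])
    ps_idx <- which(centers >= psi_lim[1L] & centers <= psi_lim[2L])
    as.matrix(expand.grid(pi_idx, ps_idx))
  }
  core <- matrix(FALSE, n, n)
  core[cells_in(c(-180, -40), c(60, 180))] <- TRUE    # beta basin
  core[cells_in(c(-180, -40), c(-180, -170))] <- TRUE # beta tail (psi wrap)
  core[cells_in(c(-140, -40), c(-70, 0))] <- TRUE     # right-handed alpha
  core[cells_in(c(30, 90), c(0, 80))] <- TRUE         # left-handed alpha
  dilate <- function(m) {
    out <- m
    idx <- which(m, arr.ind = TRUE)
    wrap <- function(k) ((k - 1L) %% n) + 1L
    for (di in -1:1) for (dj in -1:1) {
      out[cbind(wrap(idx[, 1L] + di), wrap(idx[, 2L] + dj))] <- TRUE
    }
    out
  }
  allowed <- dilate(core)
  generous <- dilate(allowed)
  map <- matrix(4L, n, n)
  map[generous] <- 3L
  map[allowed] <- 2L
  map[core] <- 1L
  .rama_map_cache$map <- map
  map
}

## Classify (phi, psi) pairs (degrees) into region codes 1..4.
ramachandranRegion <- function(phi, psi, map = ramachandranMap()) {
  cell <- function(x) {
    i <- floor((x + 180) / 10) + 1L
    i[i > 36L] <- 36L   # +180 belongs to the last cell
    i[i < 1L] <- 1L
    i
  }
  map[cbind(cell(phi), cell(psi))]
}

.rama_regions <- c("most_favoured", "additional_allowed",
                   "generously_allowed", "disallowed")

#' Percentages from Ramachandran region counts
#'
#' `100 * count / sum(counts)`, rounded half-away-from-zero to 1 decimal --
#' the arithmetic used in conventional validation tables.
#'
#' @param counts Numeric vector of region counts (any length/order).
#' @return Numeric vector of percentages at 1 decimal.
#' @export
ramaPercentages <- function(counts) {
  round_half_away(100 * counts / sum(counts), 1)
}

#' Four-region Ramachandran summary
#'
#' Counts and percentages of residues (with both phi and psi defined) in the
#' most-favoured, additional-allowed, generously-allowed and disallowed
#' regions.  Glycine and proline are classified with the same map, matching
#' the single four-region totals of conventional summary tables; the
#' denominator (`n`) is reported explicitly.
#'
#' @param dihedrals Output of [backboneDihedrals()].
#' @param map Region map, as [ramachandranMap()].
#' @return List of class `"RamachandranSummary"` with `counts` (named
#'   integer), `percentages` (named numeric, 1 decimal,
#'   half-away-from-zero), and `n`.
#' @export
ramachandranSummary <- function(dihedrals, map = ramachandranMap()) {
  ok <- !is.na(dihedrals$phi) & !is.na(dihedrals$psi)
  if (!any(ok)) stop("no residue has both phi and psi defined")
  reg <- ramachandranRegion(dihedrals$phi[ok], dihedrals$psi[ok], map)
  counts <- vapply(1:4, function(k) sum(reg == k), 0L)
  names(counts) <- .rama_regions
  out <- list(counts = counts,
              percentages = stats::setNames(ramaPercentages(counts), .rama_regions),
              n = sum(ok))
  class(out) <- "RamachandranSummary"
  out
}

#' @export
print.RamachandranSummary <- function(x, ...) {
  cat(sprintf("RamachandranSummary (n = %d residues with phi and psi):\n", x$n))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-20s %4d (%.1f%%)\n", nm, x$counts[[nm]], x$percentages[[nm]]))
  }
  invisible(x)
}

## ---- clashscore ------------------------------------------------------------

#' Heavy-atom clashscore
#'
#' Counts unordered heavy-atom pairs whose van der Waals overlap
#' `r_vdw(a) + r_vdw(b) - d(a, b)` exceeds `overlapCutoff` (default 0.4
#' angstrom), excluding pairs within three covalent bonds of each other (bond
#' graph inferred from distances and elements, which also covers disulfide
#' partners); the score is clashes per 1000 heavy atoms.  Inputs without
#' hydrogens give a heavy-atom score, not directly comparable to tools that
#' add hydrogens first.
#'
#' @param model A [StructureModel-class].
#' @param overlapCutoff Overlap threshold (angstrom, default 0.4).
#' @param radii Van der Waals radii, as [vdwRadii()].
#' @return List with `score` (clashes per 1000 atoms), `n_clashes`,
#'   `n_atoms`, and `clashes` (a `data.frame` of the offending pairs).
#' @export
clashscore <- function(model, overlapCutoff = 0.4, radii = vdwRadii()) {
  at <- model@atoms[toupper(model@atoms$elesy) != "H", , drop = FALSE]
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- radii[toupper(at$elesy)]
  r[is.na(r)] <- max(radii)
  d <- cross_dist(xyz, xyz)
  overlap <- outer(r, r, "+") - d
  cand <- which(upper.tri(d) & overlap > overlapCutoff, arr.ind = TRUE)
  if (nrow(cand)) {
    excl <- bonded_within(xyz, toupper(at$elesy), max_sep = 3L)
    keep <- !excl[cand]
    cand <- cand[keep, , drop = FALSE]
  }
  clash_df <- if (nrow(cand)) {
    data.frame(
      chain1 = at$chain[cand[, 1L]], resno1 = at$resno[cand[, 1L]],
      atom1 = at$elety[cand[, 1L]],
      chain2 = at$chain[cand[, 2L]], resno2 = at$resno[cand[, 2L]],
      atom2 = at$elety[cand[, 2L]],
      overlap = overlap[cand],
      stringsAsFactors = FALSE)
  } else {
    data.frame(chain1 = character(), resno1 = integer(), atom1 = character(),
               chain2 = character(), resno2 = integer(), atom2 = character(),
               overlap = numeric(), stringsAsFactors = FALSE)
  }
  list(score = 1000 * nrow(clash_df) / n, n_clashes = nrow(clash_df),
       n_atoms = n, clashes = clash_df)
}

## ---- bond geometry ---------------------------------------------------------

#' Bond length and angle RMSD against standard values
#'
#' Observed backbone (and CA--CB) bond lengths and angles are compared with
#' the bundled standard-geometry table ([standardGeometry()]); the result is
#' the RMSD over all recognised bonds and over all recognised angles.
#' Inter-residue terms are only evaluated across intact peptide bonds
#' (C--N within `breakDistance`); unrecognised or incomplete terms are
#' skipped and counted.
#'
#' @param model A [StructureModel-class].
#' @param reference Standard-geometry table, as [standardGeometry()].
#' @param breakDistance Peptide-bond break cutoff (angstrom, default 2.5).
#' @return List with `length_rmsd` (angstrom), `angle_rmsd` (degrees),
#'   `n_bonds`, `n_angles`, `n_skipped`.
#' @export
bondGeometryRMSD <- function(model, reference = standardGeometry(),
                             breakDistance = 2.5) {
  dev_len <- numeric(0)
  dev_ang <- numeric(0)
  skipped <- 0L
  for (ch in chainIds(model)) {
    rt <- residueTable(model, ch)
    at <- model@atoms[model@atoms$chain == ch, , drop = FALSE]
    n <- nrow(rt)
    get_atom <- function(i, name) {
      if (i < 1L || i > n) return(NULL)
      sel <- at$resno == rt$resno[i] & at$insert == rt$insert[i] & at$elety == name
      if (!any(sel)) return(NULL)
      row <- at[which(sel)[1L], ]
      c(row$x, row$y, row$z)
    }
    fetch <- function(i, name) {
      if (startsWith(name, "+")) get_atom(i + 1L, substring(name, 2L))
      else get_atom(i, name)
    }
    peptide_ok <- function(i) {
      a <- get_atom(i, "C"); b <- get_atom(i + 1L, "N")
      !is.null(a) && !is.null(b) && vnorm(a - b) <= breakDistance
    }
    for (i in seq_len(n)) {
      for (k in seq_len(nrow(reference$bonds))) {
        b <- reference$bonds[k, ]
        cross <- startsWith(b$atom1, "+") || startsWith(b$atom2, "+")
        if (cross && !peptide_ok(i)) { skipped <- skipped + 1L; next }
        p1 <- fetch(i, b$atom1); p2 <- fetch(i, b$atom2)
        if (is.null(p1) || is.null(p2)) { skipped <- skipped + 1L; next }
        dev_len <- c(dev_len, vnorm(p1 - p2) - b$length)
      }
      for (k in seq_len(nrow(reference$angles))) {
        a <- reference$angles[k, ]
        cross <- any(startsWith(c(a$atom1, a$atom2, a$atom3), "+"))
        if (cross && !peptide_ok(i)) { skipped <- skipped + 1L; next }
        p1 <- fetch(i, a$atom1); p2 <- fetch(i, a$atom2); p3 <- fetch(i, a$atom3)
        if (is.null(p1) || is.null(p2) || is.null(p3)) { skipped <- skipped + 1L; next }
        dev_ang <- c(dev_ang, angle3(p1, p2, p3) - a$angle)
      }
    }
  }
  list(
    length_rmsd = if (length(dev_len)) sqrt(mean(dev_len^2)) else 0,
    angle_rmsd = if (length(dev_ang)) sqrt(mean(dev_ang^2)) else 0,
    n_bonds = length(dev_len),
    n_angles = length(dev_ang),
    n_skipped = skipped
  )
}

#' Full geometry-based quality report for one structure
#'
#' Convenience wrapper producing the per-structure validation block used by
#' [runPipeline()]: Ramachandran summary (first chain unless given),
#' clashscore and bond-geometry RMSD.
#'
#' @param model A [StructureModel-class].
#' @param chain Chain for the dihedral summary (default: first chain).
#' @return List of class `"QualityReport"`: `clashscore`, `bond_length_rmsd`,
#'   `bond_angle_rmsd`, `rama` (a `"RamachandranSummary"`).
#' @export
qualityReport <- function(model, chain = chainIds(model)[1L]) {
  cs <- clashscore(model)
  bg <- bondGeometryRMSD(model)
  dih <- backboneDihedrals(model, chain)
  out <- list(clashscore = cs$score,
              bond_length_rmsd = bg$length_rmsd,
              bond_angle_rmsd = bg$angle_rmsd,
              rama = ramachandranSummary(dih))
  class(out) <- "QualityReport"
  out
}

#' @export
print.QualityReport <- function(x, ...) {
  cat(sprintf("QualityReport: clashscore %.2f /1000 atoms, bond-length RMSD %.3f A, bond-angle RMSD %.2f deg\n",
              x$clashscore, x$bond_length_rmsd, x$bond_angle_rmsd))
  print(x$rama)
  invisible(x)
}
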