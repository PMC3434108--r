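# Secondary-structure assignment from dihedral windows, Shrake-Rupley
# solvent-accessible surface area, and a qualitative Coulomb surface-potential
# classifier.

#' Assign secondary structure from backbone dihedrals
#'
#' Window rule: a residue with defined phi/psi is helix-eligible when phi is
#' in \[-100, -30\] and psi in \[-80, -5\]; strand-eligible when phi is in
#' \[-180, -40\] and psi in \[60, 180\] or \[-180, -170\].  Maximal runs of
#' eligible residues of at least `minHelix` (default 4) or `minStrand`
#' (default 3) become H/E elements; everything else is coil (`C`).  This is
#' a dihedral-based assignment, chosen over hydrogen-bond (DSSP-style)
#' assignment because it is exactly testable on synthetic dihedral fixtures;
#' the windows are configurable.
#'
#' @param model A [StructureModel-class].
#' @param chain Chain id (default: first chain).
#' @param minHelix,minStrand Minimum element lengths.
#' @return List of class `"SSEAnnotation"`: `labels` (`data.frame` with
#'   `resno`, `insert`, `label`), and `elements` (`data.frame` with `type`,
#'   `start_resno`, `end_resno`, `length`).
#' @export
assignSSE <- function(model, chain = chainIds(model)[1L],
                      minHelix = 4L, minStrand = 3L) {
  dih <- backboneDihedrals(model, chain)
  phi <- dih$phi
  psi <- dih$psi
  defined <- !is.na(phi) & !is.na(psi)
  helix_ok <- defined & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  strand_ok <- defined & phi >= -180 & phi <= -40 &
    ((psi >= 60 & psi <= 180) | (psi >= -180 & psi <= -170))
  n <- nrow(dih)
  lab <- rep("C", n)
  mark_runs <- function(ok, min_len, code) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= min_len) {
        lab[starts[k]:ends[k]] <<- code
      }
    }
  }
  ## Helix takes precedence where windows could overlap (they do not with the
  ## default windows, but custom windows may intersect).
  mark_runs(strand_ok & lab == "C", minStrand, "E")
  mark_runs(helix_ok, minHelix, "H")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  el <- r$values != "C"
  elements <- data.frame(
    type = r$values[el],
    start_resno = dih$resno[starts[el]],
    end_resno = dih$resno[ends[el]],
    length = r$lengths[el],
    stringsAsFactors = FALSE
  )
  out <- list(labels = data.frame(resno = dih$resno, insert = dih$insert,
                                  label = lab, stringsAsFactors = FALSE),
              elements = elements)
  class(out) <- "SSEAnnotation"
  out
}

#' @export
print.SSEAnnotation <- function(x, ...) {
  tab <- table(factor(x$labels$label, levels = c("H", "E", "C")))
  cat(sprintf("SSEAnnotation: %d helix / %d strand / %d coil residues; %d elements\n",
              tab[["H"]], tab[["E"]], tab[["C"]], nrow(x$elements)))
  if (nrow(x$elements)) print(x$elements)
  invisible(x)
}

## Deterministic, nearly uniform unit sphere points (golden-section spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi_ang <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi_ang) * cos(theta), sin(phi_ang) * sin(theta), cos(phi_ang))
}

#' Shrake--Rupley solvent-accessible surface area
#'
#' Classic sphere-point algorithm: each heavy atom is covered with `nPoints`
#' quasi-uniform points on its solvent-expanded sphere (radius r + probe);
#' points falling inside any neighbouring atom's expanded sphere are buried,
#' and the exposed fraction scales the sphere area `4 pi (r + probe)^2`.
#'
#' @param model A [StructureModel-class].
#' @param probe Probe radius (angstrom, default 1.4, a water molecule).
#' @param nPoints Sphere points per atom (default 960; >= 16 required).
#' @param radii Van der Waals radii, as [vdwRadii()].
#' @param keepPoints When `TRUE`, the exposed surface points are returned
#'   (needed by [surfacePotential()]).
#' @return List of class `"SASAResult"`: `atom_area` (numeric, angstrom^2 per
#'   atom row), `residue_area` (`data.frame`), `total`, and optionally
#'   `points` (`data.frame` with `x`, `y`, `z`, `atom`).
#' @export
shrakeRupleySASA <- function(model, probe = 1.4, nPoints = 960L,
                             radii = vdwRadii(), keepPoints = FALSE) {
  if (nPoints < 16L) stop("nPoints must be at least 16")
  at <- model@atoms[toupper(model@atoms$elesy) != "H", , drop = FALSE]
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- radii[toupper(at$elesy)]
  r[is.na(r)] <- max(radii)
  rs <- r + probe
  unit <- sphere_points(nPoints)
  d <- cross_dist(xyz, xyz)
  area <- numeric(n)
  pts_out <- if (keepPoints) vector("list", n) else NULL
  ## Orient each atom's point sphere in a molecule-fixed local frame (built
  ## from the directions to its two nearest non-collinear neighbours) so the
  ## computed area is exactly invariant under rigid transforms of the model
  ## rather than depending on the lab-frame orientation of the point grid.
  local_frame <- function(i) {
    ord <- setdiff(order(d[i, ]), i)
    if (!length(ord)) return(diag(3))
    e1 <- xyz[ord[1L], ] - xyz[i, ]
    e1 <- e1 / vnorm(e1)
    for (j in ord[-1L]) {
      v <- xyz[j, ] - xyz[i, ]
      w <- vcross(e1, v)
      if (vnorm(w) > 1e-6 * vnorm(v)) {
        e3 <- w / vnorm(w)
        return(cbind(e1, vcross(e3, e1), e3))
      }
    }
    diag(3)
  }
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rs[i] + rs & seq_len(n) != i)
    pts <- tcrossprod(unit, local_frame(i)) * rs[i] + rep(xyz[i, ], each = nPoints)
    exposed <- rep(TRUE, nPoints)
    for (j in nb) {
      still <- which(exposed)
      if (!length(still)) break
      dj <- pts[still, , drop = FALSE] - rep(xyz[j, ], each = length(still))
      exposed[still[rowSums(dj * dj) < rs[j]^2]] <- FALSE
    }
    area[i] <- 4 * pi * rs[i]^2 * sum(exposed) / nPoints
    if (keepPoints && any(exposed)) {
      pts_out[[i]] <- cbind(pts[exposed, , drop = FALSE], i)
    }
  }
  res_key <- paste(at$chain, at$resno, at$insert)
  agg <- tapply(area, res_key, sum)
  first <- at[!duplicated(res_key), , drop = FALSE]
  residue_area <- data.frame(
    first[, c("chain", "resno", "insert", "resid")],
    area = as.numeric(agg[paste(first$chain, first$resno, first$insert)]),
    stringsAsFactors = FALSE)
  rownames(residue_area) <- NULL
  out <- list(atom_area = area, residue_area = residue_area,
              total = sum(area))
  if (keepPoints) {
    pm <- do.call(rbind, pts_out)
    out$points <- data.frame(x = pm[, 1L], y = pm[, 2L], z = pm[, 3L],
                             atom = as.integer(pm[, 4L]))
  }
  class(out) <- "SASAResult"
  out
}

#' @export
print.SASAResult <- function(x, ...) {
  cat(sprintf("SASAResult: total %.1f A^2 over %d atoms (%d residues)\n",
              x$total, length(x$atom_area), nrow(x$residue_area)))
  invisible(x)
}

## Formal-charge centroids of charged side-chain groups.
chargedGroupCentroids <- function(model, hisCharge = 0) {
  at <- model@atoms
  groups <- list(
    ASP = list(atoms = c("OD1", "OD2", "CG"), q = -1),
    GLU = list(atoms = c("OE1", "OE2", "CD"), q = -1),
    LYS = list(atoms = "NZ", q = +1),
    ARG = list(atoms = c("NE", "NH1", "NH2", "CZ"), q = +1)
  )
  if (hisCharge != 0) {
    groups$HIS <- list(atoms = c("ND1", "NE2"), q = hisCharge)
  }
  res_key <- paste(at$chain, at$resno, at$insert)
  rows <- list()
  for (key in unique(res_key)) {
    sel <- at[res_key == key, , drop = FALSE]
    g <- groups[[toupper(sel$resid[1L])]]
    if (is.null(g)) next
    ga <- sel[sel$elety %in% g$atoms, , drop = FALSE]
    if (!nrow(ga)) next
    rows[[length(rows) + 1L]] <- c(mean(ga$x), mean(ga$y), mean(ga$z), g$q)
  }
  if (!length(rows)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      q = numeric()))
  }
  m <- do.call(rbind, rows)
  data.frame(x = m[, 1L], y = m[, 2L], z = m[, 3L], q = m[, 4L])
}

#' Qualitative Coulomb surface-potential classification
#'
#' Reduced Coulomb potential `V(p) = sum_i q_i / d(p, site_i)` over formal
#' charges placed at charged-group centroids (Asp/Glu -1, Lys/Arg +1, His
#' configurable, default neutral), with no dielectric constant -- the
#' dielectric is absorbed into the neutral-band threshold `t`.  Points are
#' classified negative (`V < -t`), positive (`V > t`) or neutral.  This is a
#' qualitative classifier of surface character, not a Poisson--Boltzmann
#' potential.
#'
#' @param model A [StructureModel-class].
#' @param points Surface points: a `data.frame`/matrix with `x`, `y`, `z`
#'   columns, typically `shrakeRupleySASA(..., keepPoints = TRUE)$points`.
#' @param threshold Neutral half-band `t` in charge/angstrom (default 0.05).
#' @param hisCharge Formal charge on His (default 0).
#' @return `data.frame` with `x`, `y`, `z`, `potential`, `cls` plus a
#'   `"fractions"` attribute (named fractions negative/neutral/positive).
#' @export
surfacePotential <- function(model, points, threshold = 0.05, hisCharge = 0) {
  pm <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  ch <- chargedGroupCentroids(model, hisCharge = hisCharge)
  V <- rep(0, nrow(pm))
  if (nrow(ch)) {
    d <- cross_dist(pm, as.matrix(ch[, c("x", "y", "z")]))
    d[d < 1e-6] <- 1e-6
    V <- as.numeric(d^(-1) %*% ch$q)
  }
  cls <- ifelse(V < -threshold, "negative",
                ifelse(V > threshold, "positive", "neutral"))
  out <- data.frame(x = pm[, 1L], y = pm[, 2L], z = pm[, 3L],
                    potential = V, cls = cls, stringsAsFactors = FALSE)
  frac <- table(factor(cls, levels = c("negative", "neutral", "positive")))
  attr(out, "fractions") <- as.numeric(frac) / nrow(out)
  names(attr(out, "fractions")) <- c("negative", "neutral", "positive")
  out
}
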