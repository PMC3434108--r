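# Seeded synthetic fixtures: ideal secondary-structure backbones, toy
# protease-like structures with an exactly placed His/Asp/Ser triad, random
# rigid transforms with optional coordinate noise, and alignments with
# controlled per-column occupancy.  These are geometric stand-ins for
# exercising the pipeline, not folded proteins (see the vignette).

## Build an N/CA/C/O backbone at constant (phi, psi) using the standard
## geometry table, so bondGeometryRMSD() is zero by construction.
build_backbone <- function(n, phi, psi, omega = 180) {
  geom <- standardGeometry()
  bl <- stats::setNames(geom$bonds$length,
                        paste(geom$bonds$atom1, geom$bonds$atom2))
  ba <- stats::setNames(geom$angles$angle,
                        paste(geom$angles$atom1, geom$angles$atom2, geom$angles$atom3))
  N <- CA <- C <- O <- vector("list", n)
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(bl[["N CA"]], 0, 0)
  ang <- deg2rad(ba[["N CA C"]])
  C[[1L]] <- CA[[1L]] + bl[["CA C"]] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    N[[i + 1L]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                              bl[["C +N"]], ba[["CA C +N"]], psi)
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         bl[["C O"]], ba[["CA C O"]], psi + 180)
    CA[[i + 1L]] <- place_atom(CA[[i]], C[[i]], N[[i + 1L]],
                               bl[["N CA"]], ba[["C +N +CA"]], omega)
    C[[i + 1L]] <- place_atom(C[[i]], N[[i + 1L]], CA[[i + 1L]],
                              bl[["CA C"]], ba[["N CA C"]], phi)
  }
  ## Last residue: no following N; place O by the same psi + 180 rule with a
  ## virtual psi equal to the chain's psi.
  O[[n]] <- place_atom(N[[n]], CA[[n]], C[[n]],
                       bl[["C O"]], ba[["CA C O"]], psi + 180)
  list(N = N, CA = CA, C = C, O = O)
}

backbone_atom_table <- function(bb, chain, resno, resid = "ALA") {
  n <- length(bb$N)
  if (length(resid) == 1L) resid <- rep(resid, n)
  rows <- lapply(seq_len(n), function(i) {
    pos <- rbind(bb$N[[i]], bb$CA[[i]], bb$C[[i]], bb$O[[i]])
    data.frame(chain = chain, resno = resno[i], insert = "",
               resid = resid[i],
               elety = c("N", "CA", "C", "O"),
               elesy = c("N", "C", "C", "O"),
               x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
               o = 1, b = 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ideal helix or strand fixture
#'
#' An N/CA/C/O backbone built by internal-coordinate construction at constant
#' dihedrals -- (-57, -47) for a helix, (-120, 120) for a strand -- with bond
#' lengths and angles taken exactly from [standardGeometry()], so
#' [backboneDihedrals()] recovers the dihedrals and [bondGeometryRMSD()] is
#' zero by construction.
#'
#' @param kind `"helix"` or `"strand"`.
#' @param n Number of residues (>= 4).
#' @param chain Chain id (default `"A"`).
#' @param modelId Identifier for the returned model.
#' @return A [StructureModel-class] (all-alanine, no side chains).
#' @export
makeIdealSSE <- function(kind = c("helix", "strand"), n,
                         chain = "A", modelId = paste0("ideal-", kind[1L])) {
  kind <- match.arg(kind)
  if (n < 4L) stop("n must be at least 4")
  ang <- switch(kind, helix = c(-57, -47), strand = c(-120, 120))
  bb <- build_backbone(n, phi = ang[1L], psi = ang[2L])
  StructureModel(backbone_atom_table(bb, chain, seq_len(n)),
                 modelId = modelId)
}

## Solve the triangle with the three given side lengths in the z = 0 plane.
triad_triangle <- function(d_asp_his, d_his_ser, d_asp_ser) {
  d <- c(d_asp_his, d_his_ser, d_asp_ser)
  if (any(d <= 0) || max(d) >= sum(d) - max(d)) {
    stop("triad target distances must satisfy the triangle inequality")
  }
  asp <- c(0, 0, 0)
  his <- c(d_asp_his, 0, 0)
  x <- (d_asp_his^2 + d_asp_ser^2 - d_his_ser^2) / (2 * d_asp_his)
  y <- sqrt(d_asp_ser^2 - x^2)
  ser <- c(x, y, 0)
  rbind(asp = asp, his = his, ser = ser)
}

#' Toy protease-like structure with an exactly placed catalytic triad
#'
#' Two strand lobes (emulating, at toy scale, the two-lobed trypsin fold that
#' brings the catalytic residues together at the lobe interface) flank three
#' Calpha-only residues His/Asp/Ser whose mutual Calpha distances equal the
#' targets exactly before noise.  Gaussian coordinate noise of `noiseSigma`
#' is then added to every atom.  Deterministic given `seed`.
#'
#' @param nResiduesPerLobe Residues per strand lobe (default 12).
#' @param distances Named or ordered targets `c(d_asp_his, d_his_ser,
#'   d_asp_ser)` in angstrom; the defaults (6.4, 8.4, 9.8) are the consensus
#'   experimental means for the S1-family triad.
#' @param noiseSigma Gaussian noise SD per coordinate (angstrom, default 0).
#' @param seed RNG seed (default 1).
#' @param modelId,taxonLabel Metadata for the returned model.
#' @return List with `model` (a [StructureModel-class]) and `triad` (a
#'   [CatalyticTriad-class] locating His/Asp/Ser).
#' @export
makeToyProtease <- function(nResiduesPerLobe = 12L,
                            distances = c(6.4, 8.4, 9.8),
                            noiseSigma = 0, seed = 1L,
                            modelId = "toy-protease", taxonLabel = "synthetic") {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  tri <- triad_triangle(distances[1L], distances[2L], distances[3L])
  n <- as.integer(nResiduesPerLobe)

  lobe <- function(resno_start, shift) {
    bb <- build_backbone(n, phi = -120, psi = 120)
    tab <- backbone_atom_table(bb, "A", resno_start + seq_len(n) - 1L)
    tab[, c("x", "y", "z")] <- sweep(as.matrix(tab[, c("x", "y", "z")]),
                                     2L, shift, "+")
    tab
  }
  lobe1 <- lobe(1L, c(-5, 15, 0))
  lobe2 <- lobe(201L, c(-5, -15, 0))

  triad_tab <- data.frame(
    chain = "A", resno = c(101L, 102L, 103L), insert = "",
    resid = c("HIS", "ASP", "SER"),
    elety = "CA", elesy = "C",
    x = tri[c("his", "asp", "ser"), 1L],
    y = tri[c("his", "asp", "ser"), 2L],
    z = tri[c("his", "asp", "ser"), 3L],
    o = 1, b = 0, stringsAsFactors = FALSE)

  at <- rbind(lobe1, triad_tab, lobe2)
  if (noiseSigma > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(3L * nrow(at), sd = noiseSigma),
                                    ncol = 3L))
    at[, c("x", "y", "z")] <- as.matrix(at[, c("x", "y", "z")]) + noise
  }
  model <- StructureModel(at, modelId = modelId, taxonLabel = taxonLabel)
  list(model = model,
       triad = catalyticTriad(his = c("A", 101), asp = c("A", 102),
                              ser = c("A", 103)))
}

## Uniform random rotation via a normalised 4-normal quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Apply a random rigid transform (plus optional noise) to a model
#'
#' Draws a uniform random rotation (quaternion method) and a translation
#' uniform in \[-50, 50\]^3, applies them to every atom, then adds i.i.d.
#' Gaussian coordinate noise.  The applied transform is returned so recovery
#' can be tested.  Deterministic given `seed`.
#'
#' @param model A [StructureModel-class].
#' @param seed RNG seed.
#' @param noiseSigma Gaussian noise SD per coordinate (angstrom, default 0).
#' @return List with `model` (transformed) and `transform` (the applied
#'   [RigidTransform-class]).
#' @export
applyRandomTransform <- function(model, seed = 1L, noiseSigma = 0) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  out <- with_seed(seed, {
    R <- random_rotation()
    trans <- stats::runif(3L, -50, 50)
    xyz <- coords(model)
    moved <- tcrossprod(xyz, R) + rep(trans, each = nrow(xyz))
    if (noiseSigma > 0) {
      moved <- moved + matrix(stats::rnorm(length(moved), sd = noiseSigma),
                              ncol = 3L)
    }
    list(R = R, trans = trans, moved = moved)
  })
  coords(model) <- out$moved
  list(model = model,
       transform = new("RigidTransform", rotation = out$R,
                       translation = out$trans))
}

#' Synthetic alignment with controlled column occupancy
#'
#' Background columns are drawn uniformly from the 20 residues with 10% gap
#' probability; each conserved column carries its specified residue in
#' exactly `ceiling(occupancy * nRows)` seeded-chosen rows, the remaining
#' rows drawing from the other 19 residues (so the target residue's modal
#' count is exact).  Deterministic given `seed`.
#'
#' @param nRows,nCols Alignment dimensions.
#' @param conserved `data.frame` (or list coercible to one) with columns
#'   `col`, `residue`, `occupancy` (fractions in (0, 1\]); distinct columns.
#' @param gapProb Background gap probability (default 0.1).
#' @param seed RNG seed.
#' @return A [ProteinAlignment-class] with rows named `seq01`, `seq02`, ...
#' @export
makeSyntheticAlignment <- function(nRows = 21L, nCols = 60L,
                                   conserved = NULL, gapProb = 0.1,
                                   seed = 1L) {
  aa <- unname(.AA3)
  if (!is.null(conserved)) {
    conserved <- as.data.frame(conserved)
    if (any(conserved$col < 1L | conserved$col > nCols)) {
      stop("conserved column index out of range")
    }
    if (anyDuplicated(conserved$col)) stop("conserved columns must be distinct")
    if (any(conserved$occupancy <= 0 | conserved$occupancy > 1)) {
      stop("occupancy fractions must lie in (0, 1]")
    }
  }
  M <- with_seed(seed, {
    M <- matrix(sample(c(aa, "-"), nRows * nCols, replace = TRUE,
                       prob = c(rep((1 - gapProb) / 20, 20), gapProb)),
                nrow = nRows)
    if (!is.null(conserved)) {
      for (k in seq_len(nrow(conserved))) {
        col <- conserved$col[k]
        res <- toupper(conserved$residue[k])
        n_cons <- ceiling(conserved$occupancy[k] * nRows)
        rows <- sample.int(nRows, n_cons)
        M[, col] <- sample(setdiff(aa, res), nRows, replace = TRUE)
        M[rows, col] <- res
      }
    }
    M
  })
  ids <- sprintf("seq%02d", seq_len(nRows))
  ProteinAlignment(stats::setNames(apply(M, 1L, paste, collapse = ""), ids))
}
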