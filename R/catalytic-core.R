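# Catalytic-triad Calpha geometry, cross-structure aggregation, active-site
# proximity and stabilizing-contact (hydrogen bond / disulfide) detection.

## Resolve one triad locator to the atom rows of that residue.
resolve_residue <- function(model, loc, what) {
  at <- model@atoms
  sel <- at$chain == loc[1L] & at$resno == as.integer(loc[2L])
  if (!any(sel)) {
    stop(sprintf("%s residue %s:%s not found in model '%s'",
                 what, loc[1L], loc[2L], model@modelId))
  }
  at[sel, , drop = FALSE]
}

ca_coord <- function(model, loc, what) {
  res <- resolve_residue(model, loc, what)
  ca <- res[res$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) {
    stop(sprintf("%s residue %s:%s has no CA atom", what, loc[1L], loc[2L]))
  }
  c(ca$x[1L], ca$y[1L], ca$z[1L])
}

#' Catalytic-triad Calpha geometry
#'
#' The three Calpha--Calpha distances Asp--His, His--Ser and Asp--Ser for a
#' located catalytic triad.  A triad residue whose type is not the expected
#' His/Asp/Ser raises a warning (models may differ), not an error.
#'
#' @param model A [StructureModel-class].
#' @param triad A [CatalyticTriad-class].
#' @return A [TriadGeometry-class].
#' @export
triadGeometry <- function(model, triad) {
  locs <- list(his = triad@his, asp = triad@asp, ser = triad@ser)
  expect <- c(his = "HIS", asp = "ASP", ser = "SER")
  pos <- list()
  for (nm in names(locs)) {
    res <- resolve_residue(model, locs[[nm]], nm)
    if (toupper(res$resid[1L]) != expect[[nm]]) {
      warning(sprintf("%s locator %s:%s points at %s, expected %s",
                      nm, locs[[nm]][1L], locs[[nm]][2L],
                      res$resid[1L], expect[[nm]]))
    }
    pos[[nm]] <- ca_coord(model, locs[[nm]], nm)
  }
  new("TriadGeometry",
      dAspHis = vnorm(pos$asp - pos$his),
      dHisSer = vnorm(pos$his - pos$ser),
      dAspSer = vnorm(pos$asp - pos$ser))
}

#' Aggregate triad geometries across structures
#'
#' Per-distance mean and sample standard deviation (n - 1 denominator; with a
#' single geometry the SD is 0).  Values are kept at full precision; the
#' conventional tabular display rounds to one decimal
#' ([formatTriadStats()]).
#'
#' @param geometries List of [TriadGeometry-class] objects, or a numeric
#'   matrix/data.frame with columns `d_asp_his`, `d_his_ser`, `d_asp_ser`.
#' @return List of class `"TriadStats"`: `mean`, `sd` (named numeric),
#'   `n`, and `sd_type = "sample"`.
#' @export
aggregateTriadStats <- function(geometries) {
  if (is.list(geometries) && !is.data.frame(geometries)) {
    if (!length(geometries)) stop("no geometries supplied")
    mat <- do.call(rbind, lapply(geometries, triadDistances))
  } else {
    mat <- as.matrix(as.data.frame(geometries))
    colnames(mat) <- c("d_asp_his", "d_his_ser", "d_asp_ser")
  }
  if (!nrow(mat)) stop("no geometries supplied")
  sds <- if (nrow(mat) == 1L) {
    stats::setNames(c(0, 0, 0), colnames(mat))
  } else {
    apply(mat, 2L, stats::sd)
  }
  out <- list(mean = colMeans(mat), sd = sds, n = nrow(mat),
              sd_type = "sample")
  class(out) <- "TriadStats"
  out
}

#' @export
print.TriadStats <- function(x, ...) {
  cat(sprintf("TriadStats over n = %d structures (%s SD):\n", x$n, x$sd_type))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-10s %.1f +/- %.2f A\n", nm, round_half_away(x$mean[[nm]], 1),
                x$sd[[nm]]))
  }
  invisible(x)
}

#' Format triad statistics at the conventional precision
#'
#' @param stats A `"TriadStats"` object.
#' @return Character vector `"mean +/- sd"` per distance, mean rounded
#'   half-away-from-zero to 1 decimal, SD to 2 decimals.
#' @export
formatTriadStats <- function(stats) {
  vapply(names(stats$mean), function(nm) {
    sprintf("%.1f ± %.2f", round_half_away(stats$mean[[nm]], 1),
            round_half_away(stats$sd[[nm]], 2))
  }, "")
}

#' Residues close to the catalytic site
#'
#' Residues having any atom strictly closer than `radius` to any atom of any
#' triad residue; the triad residues themselves are excluded.  The default
#' 6-angstrom radius is the usual "close proximity" bound for asking whether
#' questionable model regions impinge on the active site.
#'
#' @param model A [StructureModel-class].
#' @param triad A [CatalyticTriad-class].
#' @param radius Proximity radius (angstrom, default 6.0).
#' @return `data.frame` of residue locators (`chain`, `resno`, `insert`,
#'   `resid`, `min_distance`), sorted by distance.
#' @export
proximalResidues <- function(model, triad, radius = 6.0) {
  at <- model@atoms
  triad_keys <- vapply(list(triad@his, triad@asp, triad@ser),
                       function(l) paste(l[1L], as.integer(l[2L])), "")
  for (nm in c("his", "asp", "ser")) resolve_residue(model, slot(triad, nm), nm)
  atom_res_key <- paste(at$chain, at$resno)
  is_triad <- atom_res_key %in% triad_keys
  if (!any(!is_triad)) {
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  }
  d <- cross_dist(as.matrix(at[!is_triad, c("x", "y", "z")]),
                  as.matrix(at[is_triad, c("x", "y", "z")]))
  dmin <- apply(d, 1L, min)
  other <- at[!is_triad, , drop = FALSE]
  res_key <- paste(other$chain, other$resno, other$insert)
  agg <- tapply(dmin, res_key, min)
  hit <- names(agg)[agg < radius]
  if (!length(hit)) {
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  }
  first <- other[!duplicated(res_key) & res_key %in% hit, , drop = FALSE]
  out <- data.frame(first[, c("chain", "resno", "insert", "resid")],
                    min_distance = as.numeric(agg[paste(first$chain, first$resno, first$insert)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Covalent bond graph inferred from interatomic distances and element
## symbols; returns graph distances up to `max_sep` bonds as a logical
## exclusion matrix.
bonded_within <- function(xyz, elements, max_sep = 3L) {
  rc <- covalentRadii()
  r <- rc[elements]
  r[is.na(r)] <- 0.77
  n <- nrow(xyz)
  d <- cross_dist(xyz, xyz)
  thr <- outer(r, r, "+") + 0.4
  A <- d <= thr
  diag(A) <- FALSE
  reach <- A
  acc <- A
  if (max_sep >= 2L) {
    for (k in 2:max_sep) {
      reach <- (reach %*% A) > 0
      acc <- acc | reach
    }
  }
  diag(acc) <- FALSE
  acc
}

#' Detect stabilizing contacts: hydrogen bonds and disulfides
#'
#' Disulfide: a Cys Sgamma--Sgamma pair within `ssDmax` (default 2.3
#' angstrom, a conventional bound).  Hydrogen bond (heavy-atom criterion, no
#' hydrogens required): donor N/O to acceptor N/O distance at most
#' `hbondDmax` with the antecedent--donor--acceptor angle at least
#' `hbondAngleMin`; pairs within two covalent bonds of each other and pairs
#' within one residue are excluded.  Each contact is reported once.
#'
#' @param model A [StructureModel-class].
#' @param hbondDmax Donor--acceptor heavy-atom distance cutoff (angstrom,
#'   default 3.5).
#' @param hbondAngleMin Minimum antecedent--donor--acceptor angle (degrees,
#'   default 120).
#' @param ssDmax Sgamma--Sgamma distance cutoff (angstrom, default 2.3).
#' @return `data.frame` with columns `kind` (`"hbond"`/`"disulfide"`),
#'   `chain1`, `resno1`, `atom1`, `chain2`, `resno2`, `atom2`, `distance`,
#'   `angle` (`NA` for disulfides).
#' @export
detectStabilizingContacts <- function(model, hbondDmax = 3.5,
                                      hbondAngleMin = 120, ssDmax = 2.3) {
  at <- model@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  empty <- data.frame(kind = character(), chain1 = character(),
                      resno1 = integer(), atom1 = character(),
                      chain2 = character(), resno2 = integer(),
                      atom2 = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE)
  rows <- list()

  ## Disulfides.
  sg <- which(toupper(at$resid) == "CYS" & at$elety == "SG")
  if (length(sg) >= 2L) {
    dss <- cross_dist(xyz[sg, , drop = FALSE], xyz[sg, , drop = FALSE])
    for (i in seq_along(sg)) {
      for (j in seq_along(sg)) {
        if (j <= i) next
        if (dss[i, j] <= ssDmax) {
          a <- sg[i]; b <- sg[j]
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "disulfide",
            chain1 = at$chain[a], resno1 = at$resno[a], atom1 = "SG",
            chain2 = at$chain[b], resno2 = at$resno[b], atom2 = "SG",
            distance = dss[i, j], angle = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  ## Hydrogen bonds (heavy-atom geometric criterion).
  don_tab <- hbond_donors()
  acc_tab <- hbond_acceptors()
  res_key <- paste(at$chain, at$resno, at$insert)
  find_atoms <- function(tab) {
    idx <- integer(0)
    ante <- character(0)
    for (k in seq_len(nrow(tab))) {
      hit <- at$elety == tab$atom[k] &
        (tab$resid[k] == "*" | toupper(at$resid) == tab$resid[k])
      idx <- c(idx, which(hit))
      if ("antecedent" %in% names(tab)) {
        ante <- c(ante, rep(tab$antecedent[k], sum(hit)))
      }
    }
    list(idx = idx, ante = ante)
  }
  don <- find_atoms(don_tab)
  acc <- find_atoms(acc_tab)

  if (length(don$idx) && length(acc$idx)) {
    excl <- bonded_within(xyz, at$elesy, max_sep = 2L)
    dmat <- cross_dist(xyz[don$idx, , drop = FALSE],
                       xyz[acc$idx, , drop = FALSE])
    for (di in seq_along(don$idx)) {
      d_atom <- don$idx[di]
      ## antecedent atom in the same residue
      ante_sel <- which(res_key == res_key[d_atom] &
                          at$elety == don$ante[di])
      if (!length(ante_sel)) next
      a_pos <- xyz[ante_sel[1L], ]
      for (ai in seq_along(acc$idx)) {
        a_atom <- acc$idx[ai]
        if (a_atom == d_atom) next
        if (res_key[a_atom] == res_key[d_atom]) next
        if (dmat[di, ai] > hbondDmax) next
        if (excl[d_atom, a_atom]) next
        ang <- angle3(a_pos, xyz[d_atom, ], xyz[a_atom, ])
        if (ang < hbondAngleMin) next
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "hbond",
          chain1 = at$chain[d_atom], resno1 = at$resno[d_atom],
          atom1 = at$elety[d_atom],
          chain2 = at$chain[a_atom], resno2 = at$resno[a_atom],
          atom2 = at$elety[a_atom],
          distance = dmat[di, ai], angle = ang,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  ## canonical order for stability
  out <- out[order(out$kind, out$chain1, out$resno1, out$atom1,
                   out$chain2, out$resno2, out$atom2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
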