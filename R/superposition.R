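# Rigid-body least-squares superposition (Kabsch) and iterative common-core
# detection.  The common core of two homologous protease chains is found by
# seeding a residue correspondence from a sequence alignment, fitting, and
# repeatedly discarding residue pairs whose post-fit Calpha separation
# exceeds a cutoff until the pair set is stable.

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimising the RMSD of `moving`
#' onto `fixed` over all rigid motions (SVD solution with the usual sign
#' correction, so a reflection is never returned).
#'
#' @param fixed,moving N x 3 coordinate matrices with matched rows, N >= 3.
#' @return List with `transform` (a [RigidTransform-class]) and `rmsd`
#'   (angstrom, computed after applying the transform).
#' @examples
#' pts <- matrix(rnorm(15), ncol = 3)
#' kabschFit(pts, pts)$rmsd  # 0
#' @export
kabschFit <- function(fixed, moving) {
  fixed <- as.matrix(fixed)
  moving <- as.matrix(moving)
  if (!all(dim(fixed) == dim(moving))) stop("fixed and moving must match in size")
  n <- nrow(fixed)
  if (n < 3L) stop("at least 3 point pairs are required")
  cf <- colMeans(fixed)
  cm <- colMeans(moving)
  P <- sweep(moving, 2L, cm)
  Q <- sweep(fixed, 2L, cf)
  H <- crossprod(P, Q)            # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1)) {
    stop("degenerate (collinear) point cloud; superposition is ill-defined")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cf - R %*% cm)
  moved <- tcrossprod(moving, R) + rep(trans, each = n)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(transform = new("RigidTransform", rotation = R, translation = trans),
       rmsd = rmsd)
}

#' Apply a rigid transform
#'
#' @param x An N x 3 coordinate matrix or a [StructureModel-class].
#' @param tr A [RigidTransform-class].
#' @return Object of the same kind with transformed coordinates.
#' @export
applyTransform <- function(x, tr) {
  if (is(x, "StructureModel")) {
    coords(x) <- applyTransform(coords(x), tr)
    return(x)
  }
  x <- as.matrix(x)
  tcrossprod(x, tr@rotation) + rep(tr@translation, each = nrow(x))
}

#' Invert a rigid transform
#'
#' @param tr A [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(tr) {
  Rt <- t(tr@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% tr@translation))
}

## Alignment-seeded Calpha correspondence between two chains: residue numbers
## paired at columns where the global alignment places both sequences.
alignmentPairs <- function(refModel, targetModel,
                           refChain = chainIds(refModel)[1L],
                           targetChain = chainIds(targetModel)[1L],
                           match = 1, mismatch = -1, gap = -1) {
  sa <- chainSequence(refModel, refChain)
  sb <- chainSequence(targetModel, targetChain)
  pa <- globalAlign(sa, sb, match = match, mismatch = mismatch, gap = gap)
  ra <- strsplit(pa$aligned_a, "")[[1L]]
  rb <- strsplit(pa$aligned_b, "")[[1L]]
  ia <- cumsum(ra != "-")
  ib <- cumsum(rb != "-")
  both <- ra != "-" & rb != "-"
  rta <- residueTable(refModel, refChain)
  rtb <- residueTable(targetModel, targetChain)
  data.frame(ref_resno = rta$resno[ia[both]],
             target_resno = rtb$resno[ib[both]])
}

#' Iterative common-core superposition of two chains
#'
#' Starting from a residue correspondence (by default seeded from a global
#' sequence alignment of the two chains), repeatedly: fit a Kabsch
#' superposition on the current Calpha pairs, discard all pairs whose
#' post-fit Calpha--Calpha distance exceeds `pruneCutoff`, and refit, until
#' the pair set is stable (or repeats, or `maxIters` is reached).  The
#' surviving pairs are the structurally conserved common core.
#'
#' @param refModel,targetModel [StructureModel-class] objects.
#' @param refChain,targetChain Chain selectors (defaults: first chain).
#' @param pairs Optional starting correspondence, a `data.frame` with columns
#'   `ref_resno` and `target_resno`; computed from [globalAlign()] when
#'   missing.
#' @param pruneCutoff Distance cutoff in angstrom (default 2.0, the usual
#'   reporting threshold for predicted-model cores).
#' @param maxIters Iteration cap (default 50).
#' @return A [SuperpositionResult-class].  `fractionMatched` is always the
#'   percentage of *target-chain* residues retained in the final core.
#' @export
iterativeCoreSuperpose <- function(refModel, targetModel,
                                   refChain = chainIds(refModel)[1L],
                                   targetChain = chainIds(targetModel)[1L],
                                   pairs = NULL,
                                   pruneCutoff = 2.0, maxIters = 50L) {
  if (is.null(pairs)) {
    pairs <- alignmentPairs(refModel, targetModel, refChain, targetChain)
  }
  ca_ref <- namedAtomCoords(refModel, refChain, "CA")
  ca_tgt <- namedAtomCoords(targetModel, targetChain, "CA")
  keep <- paste0(pairs$ref_resno, "") %in% rownames(ca_ref) &
    paste0(pairs$target_resno, "") %in% rownames(ca_tgt)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3L) stop("initial correspondence has fewer than 3 Calpha pairs")

  n_target <- nrow(residueTable(targetModel, targetChain))
  seen <- character(0)
  fit <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    f <- ca_ref[as.character(pairs$ref_resno), , drop = FALSE]
    m <- ca_tgt[as.character(pairs$target_resno), , drop = FALSE]
    fit <- kabschFit(f, m)
    moved <- applyTransform(m, fit$transform)
    d <- sqrt(rowSums((moved - f)^2))
    keep <- d <= pruneCutoff
    if (all(keep) || iter >= maxIters) break
    if (sum(keep) < 3L) {
      stop(sprintf(paste0("core shrank below 3 pairs at iteration %d ",
                          "(last stable core: %d pairs, rmsd %.3f A); ",
                          "consider a larger pruneCutoff"),
                   iter, nrow(pairs), fit$rmsd))
    }
    pairs <- pairs[keep, , drop = FALSE]
    sig <- paste(pairs$ref_resno, pairs$target_resno, collapse = ";")
    if (sig %in% seen) break   # oscillation guard
    seen <- c(seen, sig)
  }
  rownames(pairs) <- NULL
  new("SuperpositionResult",
      transform = fit$transform,
      pairs = pairs,
      rmsd = fit$rmsd,
      fractionMatched = 100 * nrow(pairs) / n_target,
      nIterations = iter)
}
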