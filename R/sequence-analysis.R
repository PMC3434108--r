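# Pairwise global alignment, alignment conservation statistics, chymotrypsin
# reference numbering and physico-chemical composition profiling.

#' Needleman--Wunsch global alignment
#'
#' Optimal global alignment under linear gap scoring with deterministic
#' traceback (ties prefer diagonal over up over left), so the same inputs
#' always give the same alignment.  Intended for seeding the Calpha
#' correspondence between homologous chains; substitution matrices beyond
#' match/mismatch are deliberately out of scope.
#'
#' @param a,b Sequences (character strings, non-empty; names ignored).
#' @param match,mismatch,gap Scores (defaults +1 / -1 / -1).
#' @return List with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length, never both gapped in a column), `score`, and `identity_pct`
#'   (identical columns as a percentage of alignment length).
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- as.character(a)[1L]
  b <- as.character(b)[1L]
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(ca)
  m <- length(cb)
  F <- matrix(0, n + 1L, m + 1L)
  ## pointer: 1 diag, 2 up (consume a), 3 left (consume b)
  P <- matrix(0L, n + 1L, m + 1L)
  F[, 1L] <- gap * (0:n)
  F[1L, ] <- gap * (0:m)
  P[-1L, 1L] <- 2L
  P[1L, -1L] <- 3L
  for (i in seq_len(n)) {
    s_row <- ifelse(cb == ca[i], match, mismatch)
    for (j in seq_len(m)) {
      diag <- F[i, j] + s_row[j]
      up <- F[i, j + 1L] + gap
      left <- F[i + 1L, j] + gap
      best <- max(diag, up, left)
      F[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (diag == best) 1L else if (up == best) 2L else 3L
    }
  }
  i <- n + 1L
  j <- m + 1L
  ra <- character(0)
  rb <- character(0)
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) {
      ra <- c(ca[i - 1L], ra); rb <- c(cb[j - 1L], rb); i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      ra <- c(ca[i - 1L], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(cb[j - 1L], rb); j <- j - 1L
    }
  }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       score = F[n + 1L, m + 1L],
       identity_pct = 100 * sum(ra == rb) / length(ra))
}

#' Per-column conservation occupancy and symbols
#'
#' For each alignment column: the occupancy percentage (rows carrying the
#' most frequent non-gap residue, over *all* rows -- gapped rows stay in the
#' denominator) and the conservation symbol: `"*"` when every row carries the
#' same residue with no gaps, `":"` when all non-gap residues fall in one
#' strong group, `"."` one weak group, `" "` otherwise.  Gaps disqualify
#' `"*"` but not the group symbols.  Percentages are returned at full
#' precision; print at 0 decimals for the conventional display.
#'
#' @param aln A [ProteinAlignment-class].
#' @param groups Conservation groups, as [conservationGroups()].
#' @return `data.frame` with columns `col`, `occupancy_pct`, `symbol`,
#'   `modal_residue`, `n_rows`.
#' @export
columnConservation <- function(aln, groups = conservationGroups()) {
  M <- alignmentMatrix(aln)
  n_rows <- nrow(M)
  strong <- strsplit(groups$strong, "", fixed = TRUE)
  weak <- strsplit(groups$weak, "", fixed = TRUE)
  one_col <- function(col) {
    res <- col[col != "-"]
    if (!length(res)) {
      return(list(occ = 0, sym = " ", modal = NA_character_))
    }
    tab <- table(res)
    modal <- names(tab)[which.max(tab)]   # ties: first alphabetically
    occ <- 100 * max(tab) / n_rows
    u <- unique(res)
    sym <- if (length(res) == n_rows && length(u) == 1L) {
      "*"
    } else if (any(vapply(strong, function(g) all(u %in% g), TRUE))) {
      ":"
    } else if (any(vapply(weak, function(g) all(u %in% g), TRUE))) {
      "."
    } else {
      " "
    }
    list(occ = occ, sym = sym, modal = modal)
  }
  stats_list <- apply(M, 2L, one_col)
  data.frame(
    col = seq_len(ncol(M)),
    occupancy_pct = vapply(stats_list, function(s) s$occ, 0),
    symbol = vapply(stats_list, function(s) s$sym, ""),
    modal_residue = vapply(stats_list, function(s) s$modal, ""),
    n_rows = n_rows,
    stringsAsFactors = FALSE
  )
}

#' Map alignment rows onto reference residue numbering
#'
#' Chymotrypsin-style reference numbering: every alignment column where the
#' reference row has a residue assigns that residue's reference number to all
#' sequences' residues in the column; columns gapped in the reference are
#' insertions relative to the reference.
#'
#' @param aln A [ProteinAlignment-class].
#' @param referenceId Id of the reference row (e.g. the chymotrypsin entry).
#' @return `data.frame` with columns `seq_id`, `res_index` (1-based position
#'   in the ungapped sequence), `column`, `residue`, `ref_number` (integer,
#'   `NA` for insertions), `insertion` (logical).
#' @export
mapReferenceNumbering <- function(aln, referenceId) {
  if (!(referenceId %in% aln@ids)) {
    stop(sprintf("reference id '%s' not present in the alignment", referenceId))
  }
  M <- alignmentMatrix(aln)
  refrow <- M[referenceId, ]
  refnum <- rep(NA_integer_, length(refrow))
  refnum[refrow != "-"] <- seq_len(sum(refrow != "-"))
  out <- lapply(aln@ids, function(id) {
    row <- M[id, ]
    nong <- which(row != "-")
    data.frame(
      seq_id = id,
      res_index = seq_along(nong),
      column = nong,
      residue = row[nong],
      ref_number = refnum[nong],
      insertion = is.na(refnum[nong]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Physico-chemical composition profile of a sequence
#'
#' Molar percentage of residues falling in each physico-chemical class (see
#' [compositionClasses()]).  Classes overlap, so percentages do not sum to
#' anything in particular, except that `nonpolar + polar = 100` for
#' sequences over the 20 standard residues.  `X` residues are excluded from
#' the denominator.
#'
#' @param seq Character string of one-letter residues (may contain `X`).
#' @param classes Class membership list, as [compositionClasses()].
#' @return Named numeric vector of molar percentages, one per class.
#' @export
compositionProfile <- function(seq, classes = compositionClasses()) {
  res <- strsplit(toupper(as.character(seq)[1L]), "", fixed = TRUE)[[1L]]
  res <- res[res %in% unname(.AA3)]
  if (!length(res)) stop("sequence contains no standard residues")
  vapply(classes, function(cl) 100 * sum(res %in% cl) / length(res), 0)
}

#' Flag composition outliers across a set of profiles
#'
#' For each class, profiles more than one sample standard deviation above
#' (below) the cross-profile mean are flagged `"high"` (`"low"`); the
#' comparison is strict, so identical profiles (SD 0) are never flagged.
#'
#' @param profiles Named list of profiles from [compositionProfile()] (names
#'   are the labels), or a numeric matrix with one row per profile.
#' @return `data.frame` with columns `label`, `class`, `direction`, `value`,
#'   `mean`, `sd`.
#' @export
flagCompositionOutliers <- function(profiles) {
  if (is.list(profiles)) {
    labels <- names(profiles)
    mat <- do.call(rbind, profiles)
  } else {
    mat <- as.matrix(profiles)
    labels <- rownames(mat)
  }
  if (is.null(labels)) labels <- paste0("profile", seq_len(nrow(mat)))
  if (nrow(mat) < 3L) stop("at least 3 profiles are required to flag outliers")
  out <- list()
  for (cl in colnames(mat)) {
    v <- mat[, cl]
    mu <- mean(v)
    s <- stats::sd(v)
    hi <- v > mu + s
    lo <- v < mu - s
    if (any(hi) || any(lo)) {
      out[[cl]] <- data.frame(
        label = labels[hi | lo],
        class = cl,
        direction = ifelse(hi[hi | lo], "high", "low"),
        value = v[hi | lo],
        mean = mu,
        sd = s,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(label = character(), class = character(),
                      direction = character(), value = numeric(),
                      mean = numeric(), sd = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
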