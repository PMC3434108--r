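# Shared fixture builders and independent oracles.

withr_like_tempdir <- function() {
  d <- tempfile("triadcore-test-")
  dir.create(d)
  d
}

## Quick atom-table builder for hand-made structures.
make_atoms <- function(x, y, z, elety = "CA", elesy = "C", resid = "ALA",
                       resno = seq_along(x), chain = "A") {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z,
             o = 1, b = 0, stringsAsFactors = FALSE)
}

make_model <- function(..., modelId = "fixture") {
  StructureModel(make_atoms(...), modelId = modelId)
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

## Independent superposition oracle: best RMSD over rotation space by a dense
## Euler-angle grid followed by Nelder-Mead refinement of the best starts.
## Translation is eliminated analytically by centering both clouds.
brute_force_rmsd <- function(fixed, moving, grid_step = pi / 6) {
  fc <- sweep(fixed, 2, colMeans(fixed))
  mc <- sweep(moving, 2, colMeans(moving))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((tcrossprod(mc, R) - fc)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi - grid_step, by = grid_step),
                      b = seq(0, pi, by = grid_step),
                      c = seq(0, 2 * pi - grid_step, by = grid_step))
  vals <- apply(grid, 1, obj)
  best <- order(vals)[1:3]
  refined <- vapply(best, function(k) {
    stats::optim(as.numeric(grid[k, ]), obj,
                 control = list(reltol = 1e-14, maxit = 2000))$value
  }, 0)
  min(refined)
}

## Independent alignment oracle: exhaustive recursion over every global
## alignment (no DP sharing), feasible for sequences up to length ~6.
enum_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(ca), length(cb))
}

random_aa_string <- function(len) {
  paste(sample(c("A", "C", "D", "E", "G", "K"), len, replace = TRUE),
        collapse = "")
}

## Helix fixture whose second half is heavily perturbed (zero-mean jitter),
## leaving the first half as the only coherent core.
make_half_perturbed_pair <- function(n = 40, sigma = 8, seed = 11) {
  ref <- makeIdealSSE("helix", n)
  at <- atoms(ref)
  sel <- at$resno > n / 2
  set.seed(seed)
  at[sel, c("x", "y", "z")] <- as.matrix(at[sel, c("x", "y", "z")]) +
    matrix(rnorm(sum(sel) * 3, sd = sigma), ncol = 3)
  list(ref = ref, target = StructureModel(at, "perturbed"),
       pairs = data.frame(ref_resno = seq_len(n), target_resno = seq_len(n)))
}

## The bundled published survey of triad distances (packaged example data).
triad_survey <- function() {
  read.delim(system.file("extdata", "s1_triad_survey.tsv",
                         package = "triadcore"))
}

rama_counts_table <- function() {
  read.delim(system.file("extdata", "s1_ramachandran_counts.tsv",
                         package = "triadcore"))
}

## Minimal toy pipeline config over freshly written toy-protease files.
write_toy_config <- function(dir, n = 3, noise = 0, seeds = seq_len(n)) {
  entries <- lapply(seq_len(n), function(i) {
    tp <- makeToyProtease(noiseSigma = noise, seed = seeds[i],
                          modelId = sprintf("toy%d", i))
    path <- file.path(dir, sprintf("toy%d.pdb", i))
    writeStructure(tp$model, path)
    list(path = path, model_id = sprintf("toy%d", i), chain = "A",
         taxon = "synthetic",
         triad = list(his = "A:101", asp = "A:102", ser = "A:103"))
  })
  list(reference = "toy1", seed = 1, structures = entries)
}
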