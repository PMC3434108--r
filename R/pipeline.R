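# End-to-end orchestration: for a configured set of structures, superpose
# each onto a reference, measure triad geometry and quality metrics, and
# aggregate cross-structure statistics, conservation and composition tables
# into a single deterministic report.

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML mapping with keys:
#' \preformatted{
#' reference: 1SGI            # model_id of the reference entry
#' seed: 1
#' cutoffs:                   # all optional, defaults shown
#'   prune: 2.0
#'   proximity: 6.0
#'   hbond_dmax: 3.5
#'   hbond_angle_min: 120
#'   ss_dmax: 2.3
#'   potential_t: 0.05
#' alignment: path/to/aln.fasta     # optional
#' reference_seq_id: CTRB           # required when alignment given
#' structures:
#'   - path: path/to/model.pdb
#'     model_id: 1SGI
#'     chain: B
#'     taxon: "H. sapiens"
#'     triad: {his: "B:57", asp: "B:102", ser: "B:195"}
#' }
#'
#' @param path Path to the YAML file.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg, dir = dirname(path))
}

validatePipelineConfig <- function(cfg, dir = ".") {
  if (is.null(cfg$structures) || !length(cfg$structures)) {
    stop("config must list at least one structure entry")
  }
  ids <- vapply(cfg$structures, function(s) s$model_id %||% "", "")
  if (any(!nzchar(ids))) stop("every structure entry needs a model_id")
  if (is.null(cfg$reference) || !(cfg$reference %in% ids)) {
    stop("config 'reference' must name one of the structure entries")
  }
  for (s in cfg$structures) {
    if (is.null(s$path)) stop(sprintf("entry '%s' has no path", s$model_id))
    p <- s$path
    if (!file.exists(p) && file.exists(file.path(dir, p))) p <- file.path(dir, p)
    if (!file.exists(p)) stop(sprintf("structure file not found: %s", s$path))
  }
  if (!is.null(cfg$alignment)) {
    p <- cfg$alignment
    if (!file.exists(p) && file.exists(file.path(dir, p))) p <- file.path(dir, p)
    if (!file.exists(p)) stop(sprintf("alignment file not found: %s", cfg$alignment))
  }
  cfg$.dir <- dir
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_path <- function(p, dir) {
  if (!file.exists(p) && file.exists(file.path(dir, p))) file.path(dir, p) else p
}

default_cutoffs <- function(cutoffs = NULL) {
  defs <- list(prune = 2.0, proximity = 6.0, hbond_dmax = 3.5,
               hbond_angle_min = 120, ss_dmax = 2.3, potential_t = 0.05)
  utils::modifyList(defs, cutoffs %||% list())
}

parse_triad_entry <- function(triad, model_id) {
  if (is.null(triad) || is.null(triad$his) || is.null(triad$asp) ||
      is.null(triad$ser)) {
    stop(sprintf("entry '%s' has no complete triad (his/asp/ser) locators",
                 model_id))
  }
  catalyticTriad(his = triad$his, asp = triad$asp, ser = triad$ser)
}

#' Run the full structural-comparison pipeline
#'
#' For each configured structure: iterative common-core superposition onto
#' the reference entry (alignment-seeded, distance-pruned), catalytic-triad
#' Calpha geometry, quality metrics (Ramachandran, clashscore, bond
#' geometry), secondary-structure elements and a surface summary.  Across
#' structures: triad-distance mean/SD, and -- when an alignment is supplied
#' -- the conservation table and composition profiles with outlier flags.
#' All outputs are deterministic for a given configuration.
#'
#' @param config Configuration list (see [readPipelineConfig()]), or a path
#'   to a YAML file.
#' @return List of class `"StudyReport"`: `structures` (per-structure table:
#'   `model_id`, `taxon`, `fraction_matched`, `rmsd`, `d_asp_his`,
#'   `d_his_ser`, `d_asp_ser`), `triad_stats`, `quality` (named list of
#'   `"QualityReport"`), `sse` (named list), `surface` (named list of class
#'   fractions), `conservation`, `composition`, `composition_outliers`,
#'   `parameters`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  else config <- validatePipelineConfig(config, dir = config$.dir %||% ".")
  cutoffs <- default_cutoffs(config$cutoffs)
  dir <- config$.dir %||% "."

  entries <- config$structures
  ids <- vapply(entries, function(s) s$model_id, "")
  message(sprintf("pipeline: %d structures, reference '%s', prune cutoff %.2f A",
                  length(entries), config$reference, cutoffs$prune))

  models <- lapply(entries, function(s) {
    readStructure(resolve_path(s$path, dir), modelId = s$model_id,
                  taxonLabel = s$taxon %||% "")
  })
  names(models) <- ids
  chains <- vapply(entries, function(s) s$chain %||% NA_character_, "")
  chains <- ifelse(is.na(chains),
                   vapply(models, function(m) chainIds(m)[1L], ""),
                   chains)
  names(chains) <- ids
  ref_id <- config$reference
  ref_model <- models[[ref_id]]
  ref_chain <- chains[[ref_id]]

  rows <- list()
  quality <- list()
  sse <- list()
  surface <- list()
  geoms <- list()
  for (k in seq_along(entries)) {
    id <- ids[k]
    message(sprintf("  [%s] superpose + triad + quality", id))
    triad <- parse_triad_entry(entries[[k]]$triad, id)
    model <- models[[id]]
    sup <- iterativeCoreSuperpose(ref_model, model,
                                  refChain = ref_chain,
                                  targetChain = chains[[id]],
                                  pruneCutoff = cutoffs$prune)
    geom <- triadGeometry(model, triad)
    geoms[[id]] <- geom
    quality[[id]] <- qualityReport(model, chains[[id]])
    sse[[id]] <- assignSSE(model, chains[[id]])
    sasa <- shrakeRupleySASA(model, keepPoints = TRUE)
    pot <- surfacePotential(model, sasa$points,
                            threshold = cutoffs$potential_t)
    surface[[id]] <- attr(pot, "fractions")
    d <- triadDistances(geom)
    rows[[k]] <- data.frame(
      model_id = id, taxon = taxonLabel(model),
      fraction_matched = fractionMatched(sup), rmsd = rmsd(sup),
      d_asp_his = d[["d_asp_his"]], d_his_ser = d[["d_his_ser"]],
      d_asp_ser = d[["d_asp_ser"]], stringsAsFactors = FALSE)
  }
  structures <- do.call(rbind, rows)
  rownames(structures) <- NULL

  triad_stats <- if (length(geoms) >= 2L) aggregateTriadStats(geoms) else NULL
  if (length(entries) < 2L) {
    message("  single-structure mode: skipping cross-structure aggregation")
  }

  conservation <- NULL
  composition <- NULL
  outliers <- NULL
  if (!is.null(config$alignment)) {
    aln <- readAlignment(resolve_path(config$alignment, dir))
    conservation <- columnConservation(aln)
    if (!is.null(config$reference_seq_id)) {
      refnum <- mapReferenceNumbering(aln, config$reference_seq_id)
      ref_cols <- refnum[refnum$seq_id == config$reference_seq_id, ]
      conservation$ref_number <- NA_integer_
      conservation$ref_number[ref_cols$column] <- ref_cols$ref_number
    }
    seqs <- alignmentRows(aln)
    profiles <- lapply(seqs, function(s) {
      compositionProfile(gsub("-", "", s, fixed = TRUE))
    })
    composition <- do.call(rbind, profiles)
    if (length(profiles) >= 3L) {
      outliers <- flagCompositionOutliers(profiles)
    }
  }

  out <- list(structures = structures, triad_stats = triad_stats,
              quality = quality, sse = sse, surface = surface,
              conservation = conservation, composition = composition,
              composition_outliers = outliers,
              parameters = list(reference = ref_id, cutoffs = cutoffs,
                                seed = config$seed %||% 1L))
  class(out) <- "StudyReport"
  out
}

#' @export
print.StudyReport <- function(x, ...) {
  cat(sprintf("StudyReport: %d structures (reference '%s')\n",
              nrow(x$structures), x$parameters$reference))
  df <- x$structures
  df$fraction_matched <- sprintf("%.1f", round_half_away(df$fraction_matched, 1))
  df$rmsd <- sprintf("%.3f", df$rmsd)
  for (cl in c("d_asp_his", "d_his_ser", "d_asp_ser")) {
    df[[cl]] <- sprintf("%.1f", round_half_away(x$structures[[cl]], 1))
  }
  print(df)
  if (!is.null(x$triad_stats)) print(x$triad_stats)
  invisible(x)
}

#' Write a study report to disk
#'
#' The TSV mirrors the conventional survey-table layout (id, taxon,
#' superposed %, RMSD, the three triad distances) with display rounding
#' applied only at serialization: one decimal for distances and percentages
#' (half-away-from-zero), three decimals for RMSD.  The JSON carries full
#' precision and is byte-stable for identical inputs.
#'
#' @param report A `"StudyReport"` from [runPipeline()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, dir, formats = c("tsv", "json")) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir))
  }
  paths <- character(0)
  if ("tsv" %in% formats) {
    df <- report$structures
    out <- data.frame(
      model_id = df$model_id, taxon = df$taxon,
      superposed_pct = sprintf("%.1f", round_half_away(df$fraction_matched, 1)),
      rmsd = sprintf("%.3f", round_half_away(df$rmsd, 3)),
      d_asp_his = sprintf("%.1f", round_half_away(df$d_asp_his, 1)),
      d_his_ser = sprintf("%.1f", round_half_away(df$d_his_ser, 1)),
      d_asp_ser = sprintf("%.1f", round_half_away(df$d_asp_ser, 1)),
      stringsAsFactors = FALSE)
    p <- file.path(dir, "structures.tsv")
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$triad_stats)) {
      st <- report$triad_stats
      foot <- data.frame(
        distance = names(st$mean),
        mean = sprintf("%.1f", round_half_away(unname(st$mean), 1)),
        sd = sprintf("%.2f", round_half_away(unname(st$sd), 2)),
        n = st$n, stringsAsFactors = FALSE)
      pf <- file.path(dir, "triad_stats.tsv")
      utils::write.table(foot, pf, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, pf)
    }
    if (!is.null(report$conservation)) {
      pc <- file.path(dir, "conservation.tsv")
      cons <- report$conservation
      cons$occupancy_pct <- sprintf("%.0f", round_half_away(cons$occupancy_pct, 0))
      utils::write.table(cons, pc, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, pc)
    }
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    ser <- report
    class(ser) <- NULL
    ser$quality <- lapply(ser$quality, function(q) {
      list(clashscore = q$clashscore, bond_length_rmsd = q$bond_length_rmsd,
           bond_angle_rmsd = q$bond_angle_rmsd,
           rama = list(counts = as.list(q$rama$counts),
                       percentages = as.list(q$rama$percentages),
                       n = q$rama$n))
    })
    ser$sse <- lapply(ser$sse, function(s) s$elements)
    ser$triad_stats <- if (!is.null(ser$triad_stats)) {
      list(mean = as.list(ser$triad_stats$mean),
           sd = as.list(ser$triad_stats$sd),
           n = ser$triad_stats$n, sd_type = ser$triad_stats$sd_type)
    }
    if (!is.null(ser$composition)) {
      ser$composition <- cbind(data.frame(seq_id = rownames(ser$composition),
                                          stringsAsFactors = FALSE),
                               as.data.frame(ser$composition))
      rownames(ser$composition) <- NULL
    }
    jsonlite::write_json(ser, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}
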