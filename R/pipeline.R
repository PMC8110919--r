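## End-to-end pipeline: enrich -> background (controls) -> score -> rank,
## driven by a flat YAML config with defaults.

.configDefaults <- list(
  ks = c(5L, 6L),
  window = 5L,
  mode = "normalized",
  n_perm = 1000L,
  seed = 1L,
  sd_floor = NA_real_,       # NA = automatic (1st percentile of positive sds)
  score_threshold = 6,
  min_reads_warn = 10000L,
  write_intermediates = TRUE,
  verbose = TRUE
)

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list with keys `proteome`,
#' `manifest`, `out_dir` (required) and any of the optional parameters
#' (`ks`, `window`, `mode`, `n_perm`, `seed`, `sd_floor`,
#' `score_threshold`, `min_reads_warn`, `write_intermediates`, `verbose`).
#' Unknown keys produce a warning, not an error. Defaults are resolved and
#' the full configuration is returned; referenced input paths must exist.
#'
#' @param config file path or named list.
#' @return validated configuration list with all defaults filled in.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("proteome", "manifest", "out_dir", names(.configDefaults))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  for (key in c("proteome", "manifest", "out_dir")) {
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  }
  for (key in c("proteome", "manifest")) {
    if (!file.exists(config[[key]]))
      stop("config field '", key, "': file not found: ", config[[key]])
  }
  cfg <- utils::modifyList(.configDefaults, config[intersect(names(config), known)])
  cfg$ks <- as.integer(cfg$ks)
  if (!all(cfg$ks %in% c(5L, 6L))) stop("config field 'ks': must be within {5, 6}")
  if (length(cfg$window) != 1L || is.na(cfg$window) || cfg$window < 0)
    stop("config field 'window': must be a single non-negative integer")
  cfg$window <- as.integer(cfg$window)
  if (!cfg$mode %in% c("normalized", "raw"))
    stop("config field 'mode': must be 'normalized' or 'raw'")
  if (cfg$n_perm < 100L) stop("config field 'n_perm': must be at least 100")
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.na(cfg$sd_floor) && cfg$sd_floor <= 0)
    stop("config field 'sd_floor': must be positive (or omitted for automatic)")
  cfg
}

#' Run the full PIWAS pipeline
#'
#' Executes enrichment for every manifest sample, builds the control
#' background (restricted to the proteome's kmers), scores every sample
#' against every protein, and ranks the proteome by case-versus-control
#' statistics. All outputs are written under the configured output
#' directory: `scores.tsv`, `protein_stats.tsv`, `background.tsv`,
#' per-sample `kmer_<sample>.tsv` (when `write_intermediates`) and a
#' deterministic `run_log.txt` recording package version, parameters and
#' per-sample dropped-read counts. Identical inputs and seed reproduce the
#' outputs byte for byte.
#'
#' @param config a config path or list, see [validateConfig()].
#' @return (invisibly) list with `stats`, `scores`, `background`, `config`
#'   and the output file `paths`.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  log <- c(sprintf("piwas version: %s", as.character(utils::packageVersion("piwas"))),
           sprintf("parameters: ks=%s window=%d mode=%s n_perm=%d seed=%d sd_floor=%s score_threshold=%g",
                   paste(cfg$ks, collapse = ","), cfg$window, cfg$mode,
                   cfg$n_perm, cfg$seed,
                   if (is.na(cfg$sd_floor)) "auto" else sprintf("%g", cfg$sd_floor),
                   cfg$score_threshold))
  say <- function(...) if (cfg$verbose) message(sprintf(...))

  proteome <- loadProteome(cfg$proteome)
  manifest <- readManifest(cfg$manifest)
  say("stage enrich: %d samples", nrow(manifest))
  tables <- lapply(seq_len(nrow(manifest)), function(i) {
    rs <- tryCatch(loadReads(manifest$path[i], manifest$sample_id[i],
                             minReads = cfg$min_reads_warn),
                   error = function(e) stop("stage enrich, sample ",
                                            manifest$sample_id[i], ": ",
                                            conditionMessage(e)))
    tbl <- kmerEnrich(rs, ks = cfg$ks)
    log <<- c(log, sprintf("sample %s: %d unique reads, %d dropped",
                           sampleId(rs), nReads(rs), rs@nDropped))
    tbl
  })
  names(tables) <- manifest$sample_id

  say("stage background: %d controls", sum(manifest$cohort == "control"))
  bg <- buildBackground(tables[manifest$cohort == "control"], proteome = proteome,
                        sdFloor = if (is.na(cfg$sd_floor)) NULL else cfg$sd_floor)
  log <- c(log, sprintf("background: %d kmers, sd_floor=%s",
                        nrow(kmerEntries(bg)),
                        paste(sprintf("%.6g", sdFloor(bg)), collapse = ",")))

  say("stage score: %d proteins x %d samples", nrow(proteome), length(tables))
  scores <- scoreCohort(proteome, tables, background = bg, mode = cfg$mode,
                        w = cfg$window)

  say("stage stats: ranking %d proteins", nrow(proteome))
  stats <- rankProteome(scores, manifest, nPerm = cfg$n_perm, seed = cfg$seed,
                        proteome = proteome, scoreThreshold = cfg$score_threshold,
                        w = cfg$window)

  paths <- list(scores = file.path(cfg$out_dir, "scores.tsv"),
                stats = file.path(cfg$out_dir, "protein_stats.tsv"),
                background = file.path(cfg$out_dir, "background.tsv"),
                log = file.path(cfg$out_dir, "run_log.txt"))
  writeScores(scores, paths$scores)
  writeProteinStats(stats, paths$stats)
  writeBackground(bg, paths$background)
  if (isTRUE(cfg$write_intermediates)) {
    for (id in names(tables))
      writeKmerTable(tables[[id]], file.path(cfg$out_dir, paste0("kmer_", id, ".tsv")))
  }
  writeLines(log, paths$log)
  invisible(list(stats = stats, scores = scores, background = bg,
                 config = cfg, paths = paths))
}
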