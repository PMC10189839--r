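#' @include synthetic-ensemble.R io.R superpose.R rmsf.R rmsd.R pca.R fel.R
#' @include monitors.R energy.R classify.R cluster.R thermostability.R
NULL

.PIPE_KEYS <- c("seed", "outdir", "states", "k", "nRestarts", "threshold",
                "topN", "nSamplesRmsd", "embedMethod", "synthetic",
                "manifest", "monitors", "references", "tm")
.SYN_KEYS <- c("nResidues", "nReplicates", "nFramesPerReplicate", "noiseSd",
               "variants", "plantedGroups")

#' Build a validated pipeline configuration
#'
#' Schema-validated before any computation; unknown keys are rejected.
#' Input is either a synthetic-landscape specification (`synthetic`) or
#' a file manifest (`manifest`: `data.frame` with columns `variant`,
#' `nucleotide`, `topology`, `trajectories`, the latter
#' semicolon-separated paths).
#'
#' @param seed integer master seed.
#' @param outdir output directory.
#' @param states nucleotide states, default `c("GDP", "GTP")`.
#' @param k k-means groups per state (default 6, capped at the number
#'   of variants).
#' @param nRestarts k-means restarts, default 50.
#' @param threshold classification sigma threshold, default 1.
#' @param topN defining features per group signature, default 10.
#' @param nSamplesRmsd RMSD frames sampled per replicate, default 50.
#' @param embedMethod `"pca"` (default) or `"umap"`.
#' @param synthetic list with `nResidues` (default 80), `nReplicates`
#'   (3), `nFramesPerReplicate` (150), `noiseSd` (0.4), `variants`
#'   (labels; WT added if absent) and `plantedGroups` (2).
#' @param manifest optional file manifest (see above).
#' @param monitors optional monitor-set CSV path.
#' @param references optional named list of reference PDB paths.
#' @param tm optional melting-curve manifest: `data.frame` with
#'   columns `variant`, `state` (`GDP`/`PNP`), `path`.
#' @return List of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, outdir = tempfile("switchscore_"),
                           states = c("GDP", "GTP"), k = 6L, nRestarts = 50L,
                           threshold = 1, topN = 10L, nSamplesRmsd = 50L,
                           embedMethod = "pca", synthetic = NULL,
                           manifest = NULL, monitors = NULL,
                           references = NULL, tm = NULL) {
  cfg <- list(seed = as.integer(seed), outdir = outdir, states = states,
              k = as.integer(k), nRestarts = as.integer(nRestarts),
              threshold = threshold, topN = as.integer(topN),
              nSamplesRmsd = as.integer(nSamplesRmsd),
              embedMethod = embedMethod, synthetic = synthetic,
              manifest = manifest, monitors = monitors,
              references = references, tm = tm)
  if (is.null(cfg$synthetic) && is.null(cfg$manifest))
    stop("config needs either a 'synthetic' spec or a 'manifest'")
  if (!is.null(cfg$synthetic)) {
    bad <- setdiff(names(cfg$synthetic), .SYN_KEYS)
    if (length(bad))
      stop(sprintf("unknown synthetic keys: %s", paste(bad, collapse = ", ")))
    defaults <- list(nResidues = 80L, nReplicates = 3L,
                     nFramesPerReplicate = 150L, noiseSd = 0.4,
                     variants = c("WT", "VAR1", "VAR2"), plantedGroups = 2L)
    cfg$synthetic <- utils::modifyList(defaults, cfg$synthetic)
    if (!"WT" %in% cfg$synthetic$variants)
      cfg$synthetic$variants <- c("WT", cfg$synthetic$variants)
  }
  if (!all(cfg$states %in% c("GDP", "GTP"))) stop("states must be GDP/GTP")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` or `.json`); unknown keys
#'   are rejected.
#' @return A `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  bad <- setdiff(names(raw), .PIPE_KEYS)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  if (!is.null(raw$manifest) && is.character(raw$manifest) &&
      length(raw$manifest) == 1L)
    raw$manifest <- utils::read.csv(raw$manifest, stringsAsFactors = FALSE)
  if (!is.null(raw$tm) && is.character(raw$tm) && length(raw$tm) == 1L)
    raw$tm <- utils::read.csv(raw$tm, stringsAsFactors = FALSE)
  do.call(pipelineConfig, raw)
}

.configHash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  slim <- cfg[!vapply(cfg, is.null, logical(1))]
  # hash the analysis parameters only: not the output location, and not
  # data frames (which carry no canonical yaml form)
  slim$outdir <- NULL; slim$manifest <- NULL; slim$tm <- NULL
  yaml::write_yaml(slim, f)
  unname(tools::md5sum(f))
}

# planted per-variant effects for the synthetic landscape: variants are
# assigned to groups round-robin; group 1 is WT-like
.syntheticEffects <- function(variants, plantedGroups) {
  nv <- length(variants)
  grp <- integer(nv); names(grp) <- variants
  nonWt <- setdiff(variants, "WT")
  grp[nonWt] <- rep_len(seq_len(plantedGroups), length(nonWt))
  grp["WT"] <- 1L
  spread <- if (plantedGroups > 1) (grp - 1) / (plantedGroups - 1) else grp * 0
  data.frame(
    variant = variants, group = grp,
    occupancy_gdp = 0.15 + 0.65 * spread,     # well-II occupancy, GDP state
    mode_scale = 1 + 0.8 * spread,            # switch-mode amplitude scale
    energy_gdp = -260 + 15 * spread,          # mean nucleotide E_int, kcal/mol
    energy_gtp = -250 + 15 * spread,
    stringsAsFactors = FALSE)
}

.syntheticMonitorSet <- function(nResidues) {
  stopifnot(nResidues >= 65)
  monitorSet(c("M12_61", "M17_35", "M32_40"),
             resA = c(12L, 17L, 32L), resB = c(61L, 35L, 40L),
             rule = "ca",
             theme = c("p-loop-switch2", "nucleotide-mg-coordination",
                       "switch1-switch2-coordination"))
}

.pipeRegionMap <- function(nResidues) {
  if (nResidues >= 166) krasRegionMap()
  else regionMap(p_loop = c(10L, 17L), switch1 = c(25L, 40L),
                 switch2 = c(57L, 75L),
                 alignmentExclusions = c("switch1", "switch2"))
}

# build the synthetic ensembles of one landscape; shared mode/two-well
# directions across variants so a joint PCA is meaningful
.syntheticEnsembles <- function(cfg) {
  syn <- cfg$synthetic
  n <- syn$nResidues
  sw1 <- randomModes(n, 2L, region = c(25L, 40L), seed = cfg$seed)
  sw2 <- randomModes(n, 1L, region = c(57L, 75L), seed = cfg$seed + 1L)
  eff <- .syntheticEffects(syn$variants, syn$plantedGroups)
  ens <- list(); truths <- list()
  vseed <- 0L
  for (v in syn$variants) {
    e <- eff[eff$variant == v, ]
    for (st in cfg$states) {
      vseed <- vseed + 1L
      modes <- list(
        list(direction = sw1[, 1], sd = 1.0 * e$mode_scale),
        list(direction = sw2[, 1], sd = 0.6 * e$mode_scale))
      twoWell <- if (st == "GDP")
        list(direction = sw1[, 2], centerI = 0, centerII = 4,
             occupancyII = e$occupancy_gdp, dwell = 10)
      else NULL
      sp <- ensembleSpec(n, syn$nReplicates, syn$nFramesPerReplicate,
                         modes = modes, twoWell = twoWell,
                         noiseSd = syn$noiseSd,
                         seed = cfg$seed * 1000L + vseed)
      out <- generateEnsemble(sp, variantId = v, nucleotide = st)
      key <- paste(v, st, sep = ".")
      ens[[key]] <- out$ensemble
      truths[[key]] <- out$truth
    }
  }
  list(ensembles = ens, truths = truths, effects = eff)
}

.loadManifestEnsembles <- function(cfg) {
  mf <- cfg$manifest
  ens <- list()
  for (i in seq_len(nrow(mf))) {
    trajs <- strsplit(mf$trajectories[i], ";", fixed = TRUE)[[1]]
    key <- paste(mf$variant[i], mf$nucleotide[i], sep = ".")
    ens[[key]] <- loadEnsemble(mf$topology[i], trajs,
                               mf$variant[i], mf$nucleotide[i])
  }
  list(ensembles = ens, truths = NULL, effects = NULL)
}

.writeCsv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full dynamics-scoring pipeline
#'
#' Executes load/superpose, mobility and RMSD metrics, the PC
#' landscape with two-well occupancy, distance monitors and
#' interaction energy, score-table assembly with WT reference
#' statistics, meta-classification, per-state k-means groups and
#' signatures, the 2D embedding, and (if melting curves are supplied)
#' the thermostability merge. All CSV/JSON artifacts are written to
#' `config$outdir` along with a run log carrying the config hash,
#' seed, package version and per-stage wall times. Any stage error
#' aborts with the stage name after writing the partial results.
#'
#' @param config a `"PipelineConfig"` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return Invisibly, a list with the score table, meta-class matrix,
#'   groups, signatures, embedding, well statistics, Tm records (or
#'   `NULL`) and the output paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  logLines <- c(sprintf("config_hash %s", hash),
                sprintf("seed %d", config$seed),
                sprintf("package SwitchScore %s",
                        as.character(utils::packageVersion("SwitchScore"))))
  res <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      partial <- file.path(config$outdir, "partial_results.rds")
      saveRDS(res, partial)
      stop(sprintf("pipeline stage '%s' failed: %s (partial results in %s)",
                   name, conditionMessage(e), partial), call. = FALSE)
    })
    logLines <<- c(logLines, sprintf("stage %-12s %8.2fs", name,
                                     proc.time()[["elapsed"]] - t0))
    out
  }

  land <- stage("ingest", {
    if (!is.null(config$synthetic)) .syntheticEnsembles(config)
    else .loadManifestEnsembles(config)
  })
  ens <- land$ensembles
  keys <- names(ens)
  variants <- unique(vapply(ens, variantId, character(1)))
  nRes <- length(caIndices(ens[[1]]))
  rmap <- .pipeRegionMap(nRes)

  ens <- stage("superpose", {
    refKey <- if ("WT.GDP" %in% keys) "WT.GDP" else keys[1]
    ref <- caCoordsByResno(ens[[refKey]])
    lapply(ens, superposeEnsemble, reference = ref, map = rmap)
  })

  metrics <- stage("mobility", {
    prof <- lapply(ens, computeRMSF)
    out <- list(rmsf = prof)
    out$meanProfile <- lapply(config$states, function(st) {
      meanRMSFProfile(prof[grepl(paste0("\\.", st, "$"), names(prof))])
    })
    names(out$meanProfile) <- config$states
    out
  })

  refs <- stage("references", {
    r <- list()
    if (!is.null(config$references))
      for (nm in names(config$references))
        r[[nm]] <- caCoordsByResno(readStructure(config$references[[nm]]))
    if (!length(r)) {
      refKey <- if ("WT.GDP" %in% keys) "WT.GDP" else keys[1]
      r[["WT_start"]] <- caCoordsByResno(ens[[refKey]])
    }
    r
  })

  rmsdSer <- stage("rmsd", {
    out <- list()
    for (nm in names(refs))
      out[[nm]] <- lapply(ens, computeRMSDToReference, reference = refs[[nm]],
                          map = rmap, nSamples = config$nSamplesRmsd,
                          referenceName = nm)
    out
  })

  pcs <- stage("pca", {
    models <- lapply(config$states, function(st) {
      fitPCA(ens[grepl(paste0("\\.", st, "$"), keys)], scope = st)
    })
    names(models) <- config$states
    proj <- lapply(keys, function(k) {
      st <- sub("^.*\\.", "", k)
      projectFrames(ens[[k]], models[[st]])
    })
    names(proj) <- keys
    list(models = models, proj = proj)
  })

  wells <- stage("wells", {
    out <- list()
    for (st in config$states) {
      stKeys <- keys[grepl(paste0("\\.", st, "$"), keys)]
      pooled <- unlist(lapply(stKeys, function(k) pcs$proj[[k]][, 1]))
      dw <- detectWells(pooled)
      if (dw$unimodal) { out[[st]] <- list(unimodal = TRUE); next }
      wtKey <- paste("WT", st, sep = ".")
      side <- wellIISideFromWT(pcs$proj[[wtKey]][, 1], dw$boundary)
      ws <- lapply(stKeys, function(k)
        occupancyRatio(pcs$proj[[k]][, 1], dw$boundary, side,
                       replicate = replicateIndex(ens[[k]])))
      names(ws) <- stKeys
      out[[st]] <- list(unimodal = FALSE, boundary = dw$boundary,
                        side = side, stats = ws)
    }
    out
  })

  mons <- stage("monitors", {
    mset <- if (!is.null(config$monitors)) {
      df <- utils::read.csv(config$monitors, stringsAsFactors = FALSE)
      monitorSet(df$name, df$resA, df$resB, df$rule, df$theme)
    } else if (!is.null(config$synthetic)) {
      .syntheticMonitorSet(nRes)
    } else krasMonitors()
    list(set = mset, series = lapply(ens, computeMonitors, monitors = mset))
  })

  energies <- stage("energy", {
    if (!is.null(config$synthetic)) {
      eff <- land$effects
      out <- list()
      i <- 0L
      for (k in keys) {
        i <- i + 1L
        v <- sub("\\..*$", "", k); st <- sub("^.*\\.", "", k)
        mu <- eff[eff$variant == v,
                  if (st == "GDP") "energy_gdp" else "energy_gtp"]
        nf <- nFrames(ens[[k]])
        out[[k]] <- generateEnergySeries(mu, sd = 10, n = nf, autocorr = 0.5,
                                         seed = config$seed * 2000L + i)
      }
      out
    } else NULL   # manifest mode: supply via ingestEnergySeries externally
  })

  table <- stage("scoretable", {
    .assembleScoreTable(config, keys, ens, metrics, rmsdSer, pcs, wells,
                        mons, energies)
  })

  cls <- stage("classify", {
    cfgC <- defaultClassifierConfig(table)
    cfgC$threshold <- config$threshold
    M <- buildMetaclassMatrix(table, cfgC)
    groups <- list(); sigs <- list()
    kUse <- min(config$k, length(variants))
    for (st in config$states) {
      groups[[st]] <- kmeansGroups(table, st, k = kUse, seed = config$seed,
                                   nRestarts = config$nRestarts)
      sigs[[st]] <- groupSignatures(groups[[st]]$assignments, M,
                                    topN = config$topN)
    }
    list(matrix = M, groups = groups, signatures = sigs, config = cfgC)
  })

  tmRec <- stage("tm", {
    if (is.null(config$tm)) NULL
    else {
      calls <- do.call(rbind, lapply(seq_len(nrow(config$tm)), function(i) {
        data.frame(variant = config$tm$variant[i], state = config$tm$state[i],
                   tm = as.numeric(fitTm(readMeltingCurve(config$tm$path[i]))),
                   stringsAsFactors = FALSE)
      }))
      tmStatistics(calls)
    }
  })

  emb <- stage("embed", {
    ann <- NULL
    if (!is.null(tmRec)) {
      # PNP thermal state annotates the GTP simulations
      ann <- c(stats::setNames(tmRec$tm_gdp, paste0(tmRec$variant, ".GDP")),
               stats::setNames(tmRec$tm_pnp, paste0(tmRec$variant, ".GTP")))
    }
    embed2D(table, method = config$embedMethod, seed = config$seed,
            annotate = ann)
  })

  paths <- stage("write", {
    od <- config$outdir
    p <- list(scoreTable = file.path(od, "score_table"))
    writeScoreTable(table, p$scoreTable)
    Mdf <- data.frame(variant = rownames(cls$matrix), cls$matrix,
                      check.names = FALSE)
    p$metaclass <- .writeCsv(Mdf, file.path(od, "metaclass_matrix.csv"), hash)
    for (st in config$states) {
      g <- cls$groups[[st]]$assignments
      p[[paste0("groups_", st)]] <- .writeCsv(
        data.frame(variant = names(g), group = as.integer(g)),
        file.path(od, sprintf("groups_%s.csv", st)), hash)
      jsonlite::write_json(cls$signatures[[st]],
                           file.path(od, sprintf("signatures_%s.json", st)),
                           auto_unbox = TRUE, digits = NA)
      cc <- crossCorrelation(table, st)
      p[[paste0("cor_", st)]] <- .writeCsv(
        data.frame(metric = rownames(cc), cc, check.names = FALSE),
        file.path(od, sprintf("cross_correlation_%s.csv", st)), hash)
    }
    p$embedding <- .writeCsv(emb, file.path(od, "embedding.csv"), hash)
    if (!is.null(tmRec))
      p$tm <- .writeCsv(tmRec, file.path(od, "tm_records.csv"), hash)
    for (st in names(wells)) {
      if (isTRUE(wells[[st]]$unimodal)) next
      ws <- wells[[st]]$stats
      p[[paste0("wells_", st)]] <- .writeCsv(
        data.frame(variant = sub("\\..*$", "", names(ws)),
                   ratio = vapply(ws, wellRatio, numeric(1)),
                   boundary = wells[[st]]$boundary),
        file.path(od, sprintf("wells_%s.csv", tolower(st))), hash)
    }
    p
  })

  writeLines(logLines, file.path(config$outdir, "run_log.txt"))
  invisible(list(table = table, metaclassMatrix = cls$matrix,
                 groups = cls$groups, signatures = cls$signatures,
                 embedding = emb, wells = wells, tm = tmRec,
                 models = pcs$models, paths = paths, configHash = hash))
}

# assemble the variant x state score table with WT reference statistics
.assembleScoreTable <- function(config, keys, ens, metrics, rmsdSer, pcs,
                                wells, mons, energies) {
  rows <- list(); wtRows <- list()
  states <- config$states
  for (st in states) {
    stKeys <- keys[grepl(paste0("\\.", st, "$"), keys)]
    wtKey <- paste("WT", st, sep = ".")
    wtProj <- pcs$proj[[wtKey]]
    wtMon <- mons$series[[wtKey]]
    for (k in stKeys) {
      v <- sub("\\..*$", "", k)
      row <- list(variant = v, nucleotide = st)
      z <- pcStandardScore(pcs$proj[[k]], wtProj, k = 3L)
      row$pc1_score <- z[[1]]; row$pc2_score <- z[[2]]; row$pc3_score <- z[[3]]
      if (!isTRUE(wells[[st]]$unimodal) && !is.null(wells[[st]]$stats))
        row$pc1_fraction <- wellRatio(wells[[st]]$stats[[k]])
      else row$pc1_fraction <- NA_real_
      row$rmsf_mean <- mean(metrics$rmsf[[k]]$rmsf)
      row$ssr <- rmsfSSR(metrics$rmsf[[k]], metrics$meanProfile[[st]])
      for (nm in names(rmsdSer))
        row[[paste0("rmsd_", nm)]] <- rmsdSummary(rmsdSer[[nm]][[k]])[["mean"]]
      if (!is.null(energies)) row$eint <- mean(energies[[k]])
      sc <- monitorSigmaScore(mons$series[[k]], wtMon)
      for (mn in names(sc)) row[[paste0("mon_", mn)]] <- sc[[mn]]
      rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }

    # WT reference statistics per metric for this state
    wtRmsfRep <- attr(metrics$rmsf[[wtKey]], "perReplicate")
    stat3 <- function(xv) c(mean = mean(xv), sd = stats::sd(xv),
                            median = stats::median(xv))
    addWt <- function(metric, s) {
      wtRows[[paste(metric, st)]] <<- data.frame(
        metric = metric, nucleotide = st,
        mean = s[["mean"]], sd = s[["sd"]], median = s[["median"]],
        stringsAsFactors = FALSE)
    }
    unit <- c(mean = 0, sd = 1, median = 0)
    for (m in c("pc1_score", "pc2_score", "pc3_score")) addWt(m, unit)
    for (mn in colnames(wtMon)) addWt(paste0("mon_", mn), unit)
    if (!isTRUE(wells[[st]]$unimodal) && !is.null(wells[[st]]$stats)) {
      ws <- wells[[st]]$stats[[wtKey]]
      ratios <- ws@countII / (ws@countI + ws@countII)
      # a degenerate WT spread (all replicates on one side) cannot be
      # used as a sigma reference; the metric then stays unclassified
      if (stats::sd(ratios) > 0) addWt("pc1_fraction", stat3(ratios))
    }
    addWt("rmsf_mean", stat3(colMeans(wtRmsfRep)))
    ssrRep <- apply(wtRmsfRep, 2, function(p)
      rmsfSSR(p, metrics$meanProfile[[st]]))
    addWt("ssr", stat3(ssrRep))
    for (nm in names(rmsdSer)) {
      ser <- rmsdSer[[nm]][[wtKey]]
      repMeans <- tapply(ser$rmsd, ser$replicate, mean)
      addWt(paste0("rmsd_", nm), stat3(as.numeric(repMeans)))
    }
    if (!is.null(energies)) addWt("eint", stat3(energies[[wtKey]]))
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  wt <- do.call(rbind, wtRows)
  rownames(wt) <- NULL
  scoreTable(scores, wt)
}

#' Classification subcommand: score table to meta-classes and groups
#'
#' @param table a [ScoreTable-class] (e.g. from [readScoreTable()]).
#' @param k groups per state; default 6 capped at the variant count.
#' @param seed,nRestarts,threshold,topN see [pipelineConfig()].
#' @return List with `matrix`, `groups`, `signatures` per state.
#' @export
classifyScores <- function(table, k = 6L, seed = 1L, nRestarts = 50L,
                           threshold = 1, topN = 10L) {
  cfgC <- defaultClassifierConfig(table)
  cfgC$threshold <- threshold
  M <- buildMetaclassMatrix(table, cfgC)
  states <- unique(scoreData(table)$nucleotide)
  kUse <- min(k, length(unique(scoreData(table)$variant)))
  groups <- list(); sigs <- list()
  for (st in states) {
    groups[[st]] <- kmeansGroups(table, st, k = kUse, seed = seed,
                                 nRestarts = nRestarts)
    sigs[[st]] <- groupSignatures(groups[[st]]$assignments, M, topN = topN)
  }
  list(matrix = M, groups = groups, signatures = sigs)
}

#' Thermostability subcommand: melting curves to Tm records
#'
#' @param manifest `data.frame` with columns `variant`, `state`
#'   (`GDP`/`PNP`), `path` (curve CSV).
#' @param wtId wild-type label, default `"WT"`.
#' @return A `"TmRecord"` table (see [tmStatistics()]).
#' @export
tmFromCurves <- function(manifest, wtId = "WT") {
  calls <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    data.frame(variant = manifest$variant[i], state = manifest$state[i],
               tm = as.numeric(fitTm(readMeltingCurve(manifest$path[i]))),
               stringsAsFactors = FALSE)
  }))
  tmStatistics(calls, wtId = wtId)
}

#' Synthetic-fixture subcommand: write a landscape to disk
#'
#' Generates the synthetic ensembles of a configuration and writes
#' each as PDB topology + multi-model PDB replicates, plus the planted
#' ground truth as JSON. Identical seeds give identical fixture trees.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @param ... synthetic-spec overrides (see `synthetic` in
#'   [pipelineConfig()]).
#' @return Invisibly, the manifest `data.frame` describing the files.
#' @export
synthFixtures <- function(outdir, seed = 1L, ...) {
  cfg <- pipelineConfig(seed = seed, outdir = outdir,
                        synthetic = utils::modifyList(list(), list(...)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  land <- .syntheticEnsembles(cfg)
  mf <- list()
  for (k in names(land$ensembles)) {
    d <- file.path(outdir, k)
    p <- writeEnsemble(land$ensembles[[k]], d)
    tr <- land$truths[[k]]
    tr$modes <- NULL; tr$twoWell <- NULL; tr$stateSeq <- NULL
    jsonlite::write_json(tr, file.path(d, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    mf[[k]] <- data.frame(
      variant = variantId(land$ensembles[[k]]),
      nucleotide = nucleotideState(land$ensembles[[k]]),
      topology = p$topology,
      trajectories = paste(p$trajectories, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, mf)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
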