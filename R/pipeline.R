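pipelineDefaults <- function() {
  list(
    nSubjects = 20L,
    layout = "default",
    effect = list(couplingStrength = 0.5, fracInformative = 0.5,
                  patternSnr = 0.3, activationGain = 1, noiseSd = 1,
                  baseline = 100),
    k = 100L,
    kSeed = 100L,
    nRuns = 6L,
    nDraws = 10000L,
    nPerm = 10000L,
    seed = 1L,
    analyses = list(main = TRUE,
                    matched = c("liberal", "intermediate", "strict"),
                    snr = TRUE,
                    searchlight = FALSE),
    searchlightComparison = c("tools", "faces"),
    outDir = "connsel-out"
  )
}

#' Read a pipeline configuration file
#'
#' @param path a YAML (.yml/.yaml) or JSON (.json) file.
#' @return the parsed configuration list (not yet validated).
#' @export
readConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path,
                                              simplifyVector = TRUE)
  else stop("config must be YAML or JSON")
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (k = 100, 6 runs, 10000 draws and permutations, all
#' three matched thresholds), rejects unknown keys by name, and checks
#' that 2k voxels fit into the smallest target region of the chosen
#' layout.
#'
#' @param config a (possibly partial) configuration list; an empty list
#'   yields the full default configuration.
#' @return the normalized configuration with an attached layout object.
#' @export
validateConfig <- function(config = list()) {
  def <- pipelineDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- def
  for (nm in names(config)) {
    if (nm %in% c("effect", "analyses") && is.list(config[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(bad))
        stop("unknown ", nm, " key(s): ", paste(bad, collapse = ", "))
      cfg[[nm]][names(config[[nm]])] <- config[[nm]]
    } else cfg[[nm]] <- config[[nm]]
  }
  cfg$nSubjects <- as.integer(cfg$nSubjects)
  if (cfg$nSubjects < 2L) stop("nSubjects must be at least 2")
  if (cfg$nRuns != 6L) stop("the split scheme requires 6 runs")

  layout <- if (is(cfg$layout, "RegionLayout")) cfg$layout
  else if (is.list(cfg$layout)) {
    # config-defined geometry: gridDims plus named sphere specs
    if (is.null(cfg$layout$gridDims) || is.null(cfg$layout$regions))
      stop("a layout block needs 'gridDims' and 'regions'")
    makeLayout(unlist(cfg$layout$gridDims), cfg$layout$regions,
               minTargetVoxels = if (is.null(cfg$layout$minTargetVoxels))
                 300L else cfg$layout$minTargetVoxels)
  } else switch(cfg$layout,
              default = defaultLayout(),
              compact = compactLayout(),
              stop("layout must be 'default', 'compact', a layout ",
                   "block or a RegionLayout"))
  smallest <- min(vapply(targetRegions(layout), function(r)
    nrow(layout@regions[[r]]), 1L))
  if (2L * cfg$k > smallest)
    stop("2k = ", 2L * cfg$k, " exceeds the smallest target region (",
         smallest, " voxels)")
  attr(cfg, "layoutObject") <- layout
  cfg
}

configHash <- function(cfg) {
  if (is(cfg$layout, "RegionLayout")) {
    ly <- cfg$layout
    cfg$layout <- list(gridDims = gridDims(ly),
                       regions = lapply(ly@regions, nrow),
                       roles = as.list(ly@roles),
                       gray = nrow(ly@gray))
  }
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort, runs the GLM / connectivity / selection /
#' decoding stages per subject (each subject's GLM and residual products
#' are computed once and reused by every enabled analysis), performs
#' group inference, and writes tidy CSV tables, optional searchlight
#' NIfTI maps, and a reproducibility manifest to the output directory.
#' Outputs are deterministic given the configuration.
#'
#' @param config configuration list (see \code{\link{validateConfig}})
#'   or a path to a YAML/JSON file.
#' @return invisibly, a list with every produced table, the group
#'   results and the manifest.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- validateConfig(config)
  layout <- attr(cfg, "layoutObject")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  effect <- do.call(effectSpec,
                    c(cfg$effect, list(seed = cfg$seed)))
  scheme <- makeSplitScheme(cfg$nRuns)
  cohort <- simulateCohort(cfg$nSubjects, layout, effect,
                           seed = cfg$seed)
  matchedModes <- cfg$analyses$matched
  drawSeeds <- childSeeds(cfg$seed + 1L, length(matchedModes))
  names(drawSeeds) <- matchedModes

  dec <- list(); conn <- list(); snr <- list()
  matched <- setNames(vector("list", length(matchedModes)), matchedModes)
  slMaps <- list()
  neighborhoods <- NULL
  if (isTRUE(cfg$analyses$searchlight))
    neighborhoods <- searchlightNeighborhoods(layout, cfg$k)

  for (i in seq_along(cohort)) {
    prep <- prepareSubject(cohort[[i]])
    if (isTRUE(cfg$analyses$main)) {
      r <- decodeSubject(cohort[[i]], scheme, cfg$k, cfg$kSeed,
                         prep = prep, subjectId = i)
      dec[[i]] <- r$decoding
      conn[[i]] <- r$connectivity
      snr[[i]] <- r$snr
    }
    for (m in matchedModes) {
      matched[[m]][[i]] <- matchedDecodeSubject(
        cohort[[i]], scheme, m, cfg$k, cfg$kSeed, cfg$nDraws,
        seed = drawSeeds[[m]] + i, prep = prep, subjectId = i)
    }
    if (isTRUE(cfg$analyses$searchlight)) {
      slMaps[[i]] <- goodSeedMaps(
        cohort[[i]], targetRegions(layout)[1],
        cfg$searchlightComparison, k = cfg$k, kSelect = cfg$k,
        neighborhoods = neighborhoods, prep = prep)
    }
  }

  out <- list(config = cfg)
  wcsv <- function(d, name) {
    write.csv(d, file.path(cfg$outDir, name), row.names = FALSE)
    d
  }

  if (isTRUE(cfg$analyses$main)) {
    decoding <- do.call(rbind, dec)
    out$decoding <- wcsv(decoding, "decoding.csv")
    out$connectivity <- wcsv(do.call(rbind, conn),
                             "connectivity_sets.csv")
    fa <- foldAverage(decoding)
    anovas <- list()
    for (cc in intersect(DECODED_CATEGORIES, unique(fa$category))) {
      sub <- fa[fa$category == cc &
                  fa$mode %in% c("most_connected", "least_connected"), ]
      hasRegions <- length(unique(sub$region)) > 1L
      within <- c("mode", if (hasRegions) "region", "comparison")
      an <- rmAnova(sub, "accuracy", within)
      an$category <- cc
      an$contrastPair <- "most_vs_least"
      anovas[[length(anovas) + 1L]] <- an
      sub2 <- fa[fa$category == cc &
                   fa$mode %in% c("most_connected", "most_activated"), ]
      an2 <- rmAnova(sub2, "accuracy", within)
      an2$category <- cc
      an2$contrastPair <- "most_vs_activated"
      anovas[[length(anovas) + 1L]] <- an2
    }
    out$anova <- wcsv(do.call(rbind, anovas), "anova.csv")
  }

  if (isTRUE(cfg$analyses$snr) && length(snr)) {
    snrTab <- do.call(rbind, snr)
    out$snr <- wcsv(snrTab, "tsnr_sets.csv")
    snrAvg <- aggregate(tsnr ~ subject + region + mode, snrTab, mean)
    wide <- merge(snrAvg[snrAvg$mode == "most_connected", ],
                  snrAvg[snrAvg$mode == "least_connected", ],
                  by = c("subject", "region"))
    byS <- aggregate(cbind(tsnr.x, tsnr.y) ~ subject, wide, mean)
    tt <- pairedT(byS$tsnr.x, byS$tsnr.y)
    out$snrTest <- wcsv(data.frame(contrast = "most_vs_least_tsnr",
                                   t = tt$t, df = tt$df, p = tt$p),
                        "tsnr_test.csv")
  }

  for (m in matchedModes) {
    tab <- do.call(rbind, matched[[m]])
    out$matched[[m]] <- wcsv(tab, paste0("matched_", m, ".csv"))
  }
  if (length(matchedModes)) {
    out$matchedCounts <- wcsv(
      do.call(rbind, lapply(matchedModes, function(m) {
        tab <- out$matched[[m]]
        ok <- aggregate(nRetained ~ subject + region, tab, min)
        agg <- aggregate(nRetained ~ region, ok,
                         function(x) sum(x > 0))
        data.frame(mode = m, region = agg$region,
                   nSubjectsRetained = agg$nRetained)
      })), "matched_retained_subjects.csv")
  }

  if (isTRUE(cfg$analyses$searchlight)) {
    sd <- searchlightDiffs(slMaps)
    gm <- signFlipGroupMap(sd$diffs, sd$dims, sd$centers,
                           nPerm = cfg$nPerm, seed = cfg$seed + 2L)
    out$searchlight <- gm
    writeMapNifti(gm@z, gm@centers, gm@dims,
                  file.path(cfg$outDir, "searchlight_z.nii.gz"))
  }

  manifest <- list(package = "connsel",
                   version = as.character(utils::packageVersion("connsel")),
                   rVersion = as.character(getRversion()),
                   seed = cfg$seed,
                   configHash = configHash(
                     cfg[setdiff(names(cfg), "outDir")]))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE)
  out$manifest <- manifest
  invisible(out)
}
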