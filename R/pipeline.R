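## Reproducible end-to-end runs: JSON run configuration, master-seed
## fan-out, config hashing, and the two pipeline drivers
## (mechanics: simulate/read -> characterize -> group table;
##  imaging: render/read stacks -> orientation + straightness outputs).

#' Default run configuration
#'
#' A nested list controlling both pipelines; serializes losslessly to JSON
#' via [writeRunConfig()]. All stochastic stages derive their seeds from
#' `master_seed` (see [deriveSeed()]).
#'
#' @param masterSeed integer master seed
#' @param outputDir output directory
#' @return a named list (class `"RunConfig"`)
#' @export
defaultRunConfig <- function(masterSeed = 1L, outputDir = "artery-run") {
  structure(list(
    master_seed = as.integer(masterSeed),
    output_dir = outputDir,
    mechanics = list(
      groups = c("CTL", "HT", "RDN"),
      n_specimens = 3L,
      pressure_grid = seq(0, 120, by = 10),
      stretch_factors = c(0.95, 1, 1.05),
      diameter_noise_sd_um = 5,
      force_noise_sd_mN = 0.05,
      force_threshold_mN = 0.05,
      input_csvs = character(0)),
    imaging = list(
      image_size_px = 128L,
      n_fibers = 40L,
      fiber_length_um = 80,
      pixel_size_um = 425 / 512,
      orientation_shallow = list(mean = 0, kappa = 8),
      orientation_deep = list(mean = 90, kappa = 8),
      interface_depth_um = 14,
      n_slices = 30L,
      amplitude_um = 4,
      wavelength_um = 40,
      qc_axial_halfwidth_deg = 20,
      qc_circ_halfwidth_deg = 20,
      input_stacks = character(0))),
    class = "RunConfig")
}

#' Read / write a run configuration
#' @param config a `"RunConfig"` list
#' @param path JSON path
#' @return `readRunConfig`: the config list; `writeRunConfig`: the path,
#'   invisibly
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # empty character vectors serialize as [] and come back as lists
  for (f in c("input_csvs", "input_stacks")) {
    for (m in c("mechanics", "imaging")) {
      if (!is.null(cfg[[m]][[f]]) && length(cfg[[m]][[f]]) == 0) {
        cfg[[m]][[f]] <- character(0)
      } else if (!is.null(cfg[[m]][[f]])) {
        cfg[[m]][[f]] <- as.character(unlist(cfg[[m]][[f]]))
      }
    }
  }
  structure(cfg, class = "RunConfig")
}

#' Deterministic per-stage seed from the master seed
#'
#' A 32-bit FNV-style mix keeping results inside the signed-integer range,
#' so every stochastic stage is reproducible from one integer.
#'
#' @param masterSeed the run's master seed
#' @param stage integer stage tag
#' @param index integer within-stage index (specimen, slice, ...)
#' @return a positive integer seed < 2^31
#' @export
deriveSeed <- function(masterSeed, stage, index = 0L) {
  x <- (as.numeric(masterSeed) * 16777619 + stage * 2654435761 +
          index * 40503) %% 2147483629
  as.integer(x) + 1L
}

#' Short content hash of a configuration
#'
#' 32-bit FNV-1a over the JSON serialization; embedded in every output file
#' so results can be traced back to the exact configuration. The output
#' directory is excluded: it does not influence any computed number, and
#' identical analyses must hash identically wherever they are written.
#'
#' @param config a `"RunConfig"` list
#' @return an 8-character hex string
#' @export
configHash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  # FNV-1a in double arithmetic (the xor only ever touches the low byte)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Run the mechanics pipeline
#'
#' Either reads myograph CSVs (`config$mechanics$input_csvs`) or simulates
#' virtual specimens for each configured group, characterizes every
#' specimen (in vivo stretch, state at MAP, tangent modulus), writes
#' per-specimen JSON summaries and deformed-state CSVs plus a group
#' comparison table, and returns everything invisibly.
#'
#' @param config a `"RunConfig"` list (see [defaultRunConfig()])
#' @param quiet suppress progress messages, default TRUE
#' @return (invisibly) list with `perSpecimen` (data.frame), `table`
#'   (from [buildGroupTable()]) and `hash`
#' @export
runMechanics <- function(config = defaultRunConfig(), quiet = TRUE) {
  mc <- config$mechanics
  hash <- configHash(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  say("mechanics run, config ", hash, ", master seed ", config$master_seed)
  datasets <- list()
  groupOf <- character(0)
  if (length(mc$input_csvs) > 0) {
    errs <- character(0)
    for (f in mc$input_csvs) {
      d <- tryCatch(readMyographCsv(f), error = function(e) {
        errs <<- c(errs, paste0(f, ": ", conditionMessage(e)))
        NULL
      })
      if (!is.null(d)) {
        datasets[[length(datasets) + 1L]] <- d
        groupOf <- c(groupOf, groupLabel(d))
      }
    }
    if (length(errs) > 0) {
      stop("input errors:\n", paste(errs, collapse = "\n"), call. = FALSE)
    }
  } else {
    for (gi in seq_along(mc$groups)) {
      g <- mc$groups[gi]
      base <- arteryPreset(g)
      lzs <- findForceInvariantStretch(
        base, pressures = mc$pressure_grid)$lambdaZStar
      for (si in seq_len(mc$n_specimens)) {
        sd <- deriveSeed(config$master_seed, gi, si)
        p <- randomPreset(sd, base = g)
        prot <- SimulationProtocol(mc$pressure_grid, mc$stretch_factors,
                                   mc$diameter_noise_sd_um,
                                   mc$force_noise_sd_mN, seed = sd)
        # per-specimen geometry scale shifts lambda_z* negligibly; reuse
        # the group's designed stretch as the sweep center
        datasets[[length(datasets) + 1L]] <-
          simulateDataset(p, prot, lambdaZStar = lzs)
        groupOf <- c(groupOf, g)
      }
    }
  }
  rows <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    ch <- suppressWarnings(
      characterizeSpecimen(ds, forceThreshold = mc$force_threshold_mN))
    id <- sprintf("%s_%02d", groupOf[i], i)
    writeSpecimenSummary(ch, file.path(config$output_dir,
                                       paste0(id, "_summary.json")),
                         extra = list(specimen = id, config_hash = hash))
    writeDeformedStates(ch$curve, file.path(config$output_dir,
                                            paste0(id, "_states.csv")))
    rows[[i]] <- data.frame(
      group = groupOf[i], specimen = id,
      metric = c("in_vivo_stretch", "circ_stretch_at_map",
                 "circ_stress_at_map_kPa", "axial_stress_at_map_kPa",
                 "tangent_modulus_MPa"),
      value = c(stretchValue(ch$inVivoStretch),
                ch$mapState$circ_stretch,
                ch$mapState$circ_stress_kPa,
                ch$mapState$axial_stress_kPa,
                ch$tangentModulusMPa))
    say("  ", id, ": lambda_z* = ",
        round(stretchValue(ch$inVivoStretch), 3))
  }
  per <- do.call(rbind, rows)
  tab <- buildGroupTable(per, convention = "SEM")
  tab$config_hash <- hash
  utils::write.csv(tab, file.path(config$output_dir, "group_table.csv"),
                   row.names = FALSE)
  invisible(list(perSpecimen = per, table = tab, hash = hash))
}

#' Run the imaging pipeline
#'
#' Renders (or reads) a depth-graded elastin-like stack and a wavy
#' collagen-like stack, then writes the stack-mean orientation histogram,
#' the depth orientation map with its detected axial-to-circumferential
#' interface, the Qc/Qa summary, and the straightness (Ps) summary.
#'
#' @param config a `"RunConfig"` list
#' @param quiet suppress progress messages, default TRUE
#' @return (invisibly) list with `orientationHistogram`, `depthMap`,
#'   `interfaceDepth_um`, `qcQa`, `psSummary`, `hash`
#' @export
runImaging <- function(config = defaultRunConfig(), quiet = TRUE) {
  im <- config$imaging
  hash <- configHash(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  say("imaging run, config ", hash, ", master seed ", config$master_seed)
  if (length(im$input_stacks) > 0) {
    elastin <- readFiberStack(im$input_stacks[1])
    collagen <- if (length(im$input_stacks) > 1) {
      readFiberStack(im$input_stacks[2])
    } else {
      NULL
    }
  } else {
    spec <- fiberFieldSpec(size = im$image_size_px,
                           pixelSize = im$pixel_size_um,
                           nFibers = im$n_fibers,
                           fiberLength = im$fiber_length_um,
                           seed = deriveSeed(config$master_seed, 101))
    elastin <- renderDepthStack(im$orientation_shallow, im$orientation_deep,
                                im$interface_depth_um, im$n_slices,
                                spec)$stack
    cspec <- fiberFieldSpec(size = max(256L, im$image_size_px),
                            pixelSize = im$pixel_size_um,
                            nFibers = max(12L, im$n_fibers %/% 3L),
                            amplitude = im$amplitude_um,
                            wavelength = im$wavelength_um,
                            fiberLength = 4 * im$wavelength_um,
                            seed = deriveSeed(config$master_seed, 102))
    collagen <- FiberImageStack(
      vapply(1:4, function(i) {
        s <- cspec
        s$seed <- deriveSeed(config$master_seed, 102, i)
        renderFiberImage(s)$image
      }, matrix(0, cspec$size, cspec$size)),
      cspec$pixelSize, channel = "collagen")
  }
  mh <- stackMeanHistogram(elastin)
  dm <- depthOrientationMap(elastin)
  qq <- qcQaRatio(mh, im$qc_axial_halfwidth_deg, im$qc_circ_halfwidth_deg)
  writeOrientationCsv(mh, file.path(config$output_dir,
                                    "orientation_mean.csv"))
  writeOrientationCsv(dm, file.path(config$output_dir, "depth_map.csv"))
  utils::write.csv(
    data.frame(channel = channel(elastin), qc_qa = as.numeric(qq),
               axial_halfwidth_deg = im$qc_axial_halfwidth_deg,
               circ_halfwidth_deg = im$qc_circ_halfwidth_deg,
               config_hash = hash),
    file.path(config$output_dir, "qc_qa.csv"), row.names = FALSE)
  ps <- if (!is.null(collagen)) stackPsAnalysis(collagen) else NULL
  if (!is.null(ps)) {
    jsonlite::write_json(
      list(mean_of_medians = ps$meanOfMedians,
           sd_of_medians = ps$sdOfMedians,
           n_fibers = sum(ps$nFibers), config_hash = hash),
      file.path(config$output_dir, "ps_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  say("  interface depth: ", interfaceDepth(dm), " um; Qc/Qa = ",
      round(as.numeric(qq), 3))
  invisible(list(orientationHistogram = mh, depthMap = dm,
                 interfaceDepth_um = interfaceDepth(dm),
                 qcQa = as.numeric(qq), psSummary = ps, hash = hash))
}
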