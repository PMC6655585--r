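# End-to-end orchestration: configuration, the staged pipeline, and the
# human-readable summary report.

#' Pipeline configuration
#'
#' Collects the knobs of the full analysis: where the universe comes from
#' (a reaction-table file or a synthetic-universe specification), which
#' carbon sources to screen, the sampling parameters, and the output
#' directory. Round-trips losslessly through YAML via [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @param universePath optional reaction-table file (see [readUniverse()]).
#' @param seedsPath JSON-lines file of per-source seed metabolisms
#'   (required with `universePath`).
#' @param synthSpec named list of [universeSpec()] arguments (used when no
#'   `universePath` is given).
#' @param sources carbon sources to screen (default: all of the universe's
#'   seed sources).
#' @param perSource metabolisms sampled per source.
#' @param nSteps MCMC steps per walk.
#' @param reduceTo optional size-reduction target.
#' @param threshold viability threshold (default 0.001).
#' @param uptakeBound carbon uptake bound (default 10).
#' @param seed base RNG seed for the whole run.
#' @param outputDir where the stage outputs are written.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(universePath = NULL, seedsPath = NULL,
                      synthSpec = list(), sources = NULL, perSource = 3,
                      nSteps = 500, reduceTo = NULL, threshold = 1e-3,
                      uptakeBound = 10, seed = 1,
                      outputDir = file.path(tempdir(), "synfba-run")) {
  if (threshold <= 0 || uptakeBound <= 0)
    stop("thresholds and bounds must be positive")
  structure(list(universePath = universePath, seedsPath = seedsPath,
                 synthSpec = synthSpec, sources = sources,
                 perSource = as.integer(perSource),
                 nSteps = as.integer(nSteps),
                 reduceTo = if (!is.null(reduceTo)) as.integer(reduceTo),
                 threshold = threshold, uptakeBound = uptakeBound,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "runConfig")
}

#' @rdname runConfig
#' @param config a `runConfig`.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

.configFingerprint <- function(config) {
  as.character(jsonlite::toJSON(unclass(config)[setdiff(names(config),
                                                        "outputDir")],
                                auto_unbox = TRUE, digits = NA))
}

#' Run the full syntrophy analysis pipeline
#'
#' Stages: obtain the reaction universe and seed metabolisms; sample the
#' population of random viable metabolisms (optionally size-reduced);
#' compute viability profiles; evaluate all pairs for syntrophy; compute
#' syntrophic potentials, the no-exchange null model with a sign test, the
#' per-carbon-source incidence, and the carbon-source network with its
#' core-periphery partition. All tabular outputs and a manifest (seed,
#' configuration fingerprint, package version) are written to
#' `config$outputDir`; rerunning with an unchanged configuration reuses the
#' stored outputs.
#'
#' @param config a [runConfig()].
#' @param quiet suppress stage messages.
#' @return A result bundle: list with `universe`, `population`,
#'   `acceptance`, `profiles`, `pairs`, `potentials`, `pairPotentials`,
#'   `nullModel`, `signTestP`, `incidence`, `network`, `partition`,
#'   `assortativity`, `sources`, `config`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[synfba] ", ...)
  out <- config$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(out, "manifest.json")
  fp <- .configFingerprint(config)
  if (file.exists(manifestPath)) {
    man <- jsonlite::fromJSON(manifestPath)
    if (identical(man$fingerprint, fp) &&
        file.exists(file.path(out, "pairs.csv"))) {
      say("configuration unchanged; reusing outputs in ", out)
      return(.reloadBundle(config))
    }
  }

  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gen <- stage("universe", {
    if (!is.null(config$universePath)) {
      uni <- readUniverse(config$universePath)
      if (is.null(config$seedsPath))
        stop("seedsPath is required with universePath")
      seeds <- readPopulation(config$seedsPath, uni)
      names(seeds) <- vapply(seeds, primaryCarbonSource, character(1))
      list(universe = uni, seeds = seeds, sources = names(seeds))
    } else {
      generateUniverse(do.call(universeSpec,
                               c(config$synthSpec,
                                 list(seed = config$seed))))
    }
  })
  sources <- if (!is.null(config$sources)) config$sources else gen$sources

  samp <- stage("sample", samplePopulation(
    gen$universe, gen$seeds[sources], perSource = config$perSource,
    nSteps = config$nSteps, seed = config$seed,
    reduceTo = config$reduceTo, threshold = config$threshold))
  pop <- samp$population

  profiles <- stage("profiles", viabilityProfileTable(
    pop, gen$universe, sources, config$threshold))
  pairs <- stage("pairs", pairSyntrophy(pop, gen$universe, sources,
                                        config$threshold))
  sbar <- stage("potentials", syntrophicPotentials(pairs))
  sp <- pairSyntrophicPotentials(pairs)
  nullTab <- stage("nullmodel", nullModelTable(pairs, profiles,
                                               length(sources)))
  signP <- signTestObservedVsNull(nullTab$observed, nullTab$expected)
  incidence <- incidenceByCarbonSource(pairs, sources)
  net <- stage("network", buildCarbonNetwork(sp))
  partition <- corePeriphery(net, seed = config$seed)
  assort <- suppressWarnings(assortativityWeighted(net))

  stage("write", {
    writeUniverse(gen$universe, file.path(out, "universe.tsv"))
    writePopulation(pop, file.path(out, "population.jsonl"))
    write.csv(samp$acceptance, file.path(out, "acceptance.csv"),
              row.names = FALSE)
    write.csv(profiles, file.path(out, "profiles.csv"), row.names = FALSE)
    write.csv(pairs, file.path(out, "pairs.csv"), row.names = FALSE)
    write.csv(data.frame(label = names(sbar), sBar = as.numeric(sbar)),
              file.path(out, "potentials.csv"), row.names = FALSE)
    write.csv(as.data.frame(sp), file.path(out, "pair_potentials.csv"))
    write.csv(nullTab, file.path(out, "nullmodel.csv"), row.names = FALSE)
    write.csv(incidence, file.path(out, "incidence.csv"), row.names = FALSE)
    ew <- which(upper.tri(net$weights, diag = TRUE), arr.ind = TRUE)
    utils::write.table(
      data.frame(from = rownames(net$weights)[ew[, 1]],
                 to = colnames(net$weights)[ew[, 2]],
                 weight = net$weights[ew]),
      file.path(out, "network_edges.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    write.csv(data.frame(node = c(partition$core, partition$periphery,
                                  partition$outliers),
                         role = rep(c("core", "periphery", "outlier"),
                                    c(length(partition$core),
                                      length(partition$periphery),
                                      length(partition$outliers)))),
              file.path(out, "partition.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(fingerprint = fp, seed = config$seed,
           package = as.character(utils::packageVersion("SynFBA")),
           signTestP = signP, assortativity = assort),
      manifestPath, auto_unbox = TRUE, digits = NA)
  })

  bundle <- list(universe = gen$universe, population = pop,
                 acceptance = samp$acceptance, profiles = profiles,
                 pairs = pairs, potentials = sbar, pairPotentials = sp,
                 nullModel = nullTab, signTestP = signP,
                 incidence = incidence, network = net,
                 partition = partition, assortativity = assort,
                 sources = sources, config = config)
  writeLines(syntrophyReport(bundle), file.path(out, "report.txt"))
  bundle
}

.reloadBundle <- function(config) {
  out <- config$outputDir
  uni <- readUniverse(file.path(out, "universe.tsv"))
  pop <- readPopulation(file.path(out, "population.jsonl"), uni)
  profiles <- utils::read.csv(file.path(out, "profiles.csv"),
                              colClasses = "character")
  profiles$viableSources[is.na(profiles$viableSources)] <- ""
  pairs <- utils::read.csv(file.path(out, "pairs.csv"),
                           stringsAsFactors = FALSE)
  pairs$syntrophicSources[is.na(pairs$syntrophicSources)] <- ""
  sources <- if (!is.null(config$sources)) config$sources else
    sort(unique(profiles$primary))
  sbar <- syntrophicPotentials(pairs)
  sp <- pairSyntrophicPotentials(pairs)
  nullTab <- nullModelTable(pairs, profiles, length(sources))
  net <- buildCarbonNetwork(sp)
  list(universe = uni, population = pop,
       acceptance = utils::read.csv(file.path(out, "acceptance.csv")),
       profiles = profiles, pairs = pairs, potentials = sbar,
       pairPotentials = sp, nullModel = nullTab,
       signTestP = signTestObservedVsNull(nullTab$observed,
                                          nullTab$expected),
       incidence = incidenceByCarbonSource(pairs, sources),
       network = net, partition = corePeriphery(net, seed = config$seed),
       assortativity = suppressWarnings(assortativityWeighted(net)),
       sources = sources, config = config)
}

#' Summarize a pipeline result bundle
#'
#' Formats the headline quantities of a run: mean additional carbon
#' sources of single metabolisms, the no-exchange null expectation, the
#' mean syntrophic gains of pairs with the fold differences and sign-test
#' p-value, and the syntrophic-potential distribution.
#'
#' @param results bundle from [runPipeline()].
#' @return character vector of report lines (also printed).
#' @export
syntrophyReport <- function(results) {
  nAdd <- vapply(strsplit(results$profiles$viableSources, ";",
                          fixed = TRUE),
                 function(v) sum(nzchar(v)), numeric(1)) - 1
  nAdd <- pmax(nAdd, 0)
  obs <- results$nullModel$observed
  expd <- results$nullModel$expected
  fold <- function(a, b) if (b > 0) sprintf("%.2f", a / b) else "Inf (null 0)"
  topInc <- results$incidence[order(-results$incidence$count), ][1, ]
  lines <- c(
    sprintf("population: %d metabolisms, %d carbon sources, %d pairs",
            nrow(results$profiles), length(results$sources), nrow(results$pairs)),
    sprintf("swap acceptance rate: %.1f%% - %.1f%%",
            100 * min(results$acceptance$acceptanceRate),
            100 * max(results$acceptance$acceptanceRate)),
    sprintf("mean additional sources, single metabolism: %.3f (sd %.3f)",
            mean(nAdd), sd(nAdd)),
    sprintf("null expectation for pairs (no exchange): %.3f (sd %.3f)",
            mean(expd), sd(expd)),
    sprintf("mean additional sources gained by pairs: %.3f (sd %.3f)",
            mean(obs), sd(obs)),
    sprintf("fold vs single: %s | fold vs null: %s",
            fold(mean(obs), mean(nAdd)), fold(mean(obs), mean(expd))),
    sprintf("sign test observed vs null: p = %.3g", results$signTestP),
    sprintf("syntrophic potential: median %.3f, range [%.3f, %.3f]",
            median(results$potentials), min(results$potentials),
            max(results$potentials)),
    sprintf("most syntrophic carbon source: %s (share %.1f%%)",
            topInc$carbonSource, 100 * topInc$share),
    sprintf("network: %d core / %d periphery / %d outlier nodes, assortativity %.3f",
            length(results$partition$core),
            length(results$partition$periphery),
            length(results$partition$outliers), results$assortativity))
  cat(lines, sep = "\n")
  invisible(lines)
}
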