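# End-to-end orchestration: a single configuration drives the synthetic
# generators and every analysis stage in order, writing per-stage TSV
# outputs and a JSON run manifest.  (config, seed) fully determines every
# output.

#' Default pipeline configuration
#'
#' Every stage threshold defaults to the module-level default; the
#' configuration round-trips unchanged through YAML.
#'
#' @param seed master seed for the run
#' @param outdir output directory
#' @return nested configuration list
#' @export
defaultPipelineConfig <- function(seed = 1, outdir = tempfile("svadapt_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = list(synthetic = TRUE, catalog = TRUE, annotation = TRUE,
                  qc = TRUE, popgen = TRUE, scan = TRUE,
                  haploview = TRUE),
    synthetic = list(
      genome_length = 5e5, n_sv = 60, n_long_read_samples = 25,
      jitter_sd = 20, genotype_error = 0, dropout = 0,
      scan_length = 1e6, pulse_frac = 0.05,
      samples_per_pop = list(TIB = 20, HAN = 20, AFR = 10, ARC = 2),
      panel = list(TIB = 78, HAN = 174, AFR = 24),
      n_stratified = 6, delta_af = 0.4),
    catalog = list(max_dist = 1000, size_sim = 0.7, min_support = 2,
                   min_qual = 0),
    annotation = list(junction_window = 50, n_perm = 200,
                      anchor_proximity = 10000),
    qc = list(mr_threshold = 0.05, hwe_alpha = 1e-3,
              concordance_alpha = 1e-3, max_failures = 1),
    popgen = list(fst_threshold = 0.1, estimator = "wc"),
    scan = list(window_size = 50000, radius = 5e5, alpha = 0.05,
                ehh_cutoff = 0.05, maf_min = 0.05, n_null = 3,
                sweep_carrier_fraction = 0.9, sweep_decay = 2e5),
    haploview = list(statistic = "xpehh", threshold = 2, flank = 2.5e5)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file
#' @return configuration list
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)

#' @rdname readPipelineConfig
#' @param config configuration list
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.writeTSV <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Executes stages in order synthetic -> catalog -> annotation -> qc ->
#' popgen -> scan -> haploview (each toggleable), writing per-stage TSV
#' outputs under \code{config$outdir} and a JSON manifest recording the
#' seed, per-stage record counts and completion.  Rerunning with the same
#' configuration reproduces identical outputs.
#'
#' @param config configuration list, see [defaultPipelineConfig()]
#' @return the manifest (invisibly also written to manifest.json)
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   package_version = as.character(
                     utils::packageVersion("svadapt")))
  state <- new.env(parent = emptyenv())
  done <- function(stage, counts) {
    manifest$stages[[stage]] <<- c(list(completed = TRUE), counts)
    message("[", stage, "] done: ",
            paste(names(counts), unlist(counts), sep = "=",
                  collapse = ", "))
  }
  runStage <- function(stage, fn) {
    if (!isTRUE(config$stages[[stage]])) return(invisible(NULL))
    fn()
  }

  runStage("synthetic", function() {
    sc <- config$synthetic
    state$truth <- generateTruthSVs(sc$n_sv, sc$genome_length,
                                    seed = config$seed)
    sim <- generateSVCallsets(state$truth, sc$n_long_read_samples,
                              jitterSd = sc$jitter_sd,
                              genotypeError = sc$genotype_error,
                              dropout = sc$dropout,
                              seed = config$seed + 1)
    state$callsets <- sim$callsets
    state$tracks <- generateTracks(sc$genome_length,
                                   seed = config$seed + 2)
    state$gm <- generateGenotypeMatrix(
      state$truth, unlist(sc$panel), seed = config$seed + 3,
      stratified = seq_len(min(sc$n_stratified, nrow(state$truth))),
      deltaAF = sc$delta_af, focalPop = "TIB")
    .writeTSV(state$truth, config$outdir, "truth_svs")
    done("synthetic", list(n_truth = nrow(state$truth),
                           n_callsets = length(state$callsets)))
  })

  runStage("catalog", function() {
    cc <- config$catalog
    cat0 <- mergeCalls(state$callsets, maxDist = cc$max_dist,
                       sizeSim = cc$size_sim)
    cat0 <- categorizeDiscovery(cat0)
    filt <- filterUnreliableGenotypes(cat0, minSupport = cc$min_support,
                                      minQual = cc$min_qual)
    state$catalog <- filt$catalog
    conc <- breakpointConcordance(state$catalog, 100)
    mc <- mcols(svLoci(state$catalog))
    .writeTSV(data.frame(chrom = as.character(
      seqnames(svLoci(state$catalog))),
      start = start(svLoci(state$catalog)),
      end = end(svLoci(state$catalog)), as.data.frame(mc)),
      config$outdir, "catalog")
    .writeTSV(filt$removed, config$outdir, "removed_genotypes")
    done("catalog", list(n_loci = length(state$catalog),
                         n_removed = nrow(filt$removed),
                         concordance_100bp = round(conc, 4)))
  })

  runStage("annotation", function() {
    ac <- config$annotation
    mech <- classifyMechanism(state$catalog, state$tracks$repeats,
                              state$tracks$tandem,
                              junctionWindow = ac$junction_window)
    enr <- permutationEnrichment(
      state$catalog, state$tracks$repeats,
      chromLengths = c(chr1 = config$synthetic$genome_length),
      nPerm = ac$n_perm, seed = config$seed + 4,
      junctionWindow = ac$junction_window)
    cons <- functionalConsequence(state$catalog, state$tracks$genes)
    d3 <- apply3DRules(state$catalog, state$tracks$loops,
                       state$tracks$genes$tss,
                       anchorProximity = ac$anchor_proximity)
    .writeTSV(mech, config$outdir, "mechanisms")
    .writeTSV(enr, config$outdir, "enrichment")
    .writeTSV(cons, config$outdir, "consequences")
    .writeTSV(d3, config$outdir, "interactions_3d")
    done("annotation", list(n_mech = sum(mech$mechanism != "unclassified"),
                            n_labels = nrow(enr)))
  })

  runStage("qc", function() {
    qc <- config$qc
    flags <- qcMissingAndRecall(state$gm, qc$mr_threshold)
    hwe <- hweFilter(state$gm, alpha = qc$hwe_alpha)
    conc <- datasetConcordanceFilter(state$gm,
                                     alpha = qc$concordance_alpha,
                                     maxFailures = qc$max_failures)
    state$qcPass <- flags$pass_mr & flags$recalled & !hwe$violates &
      conc$pass
    .writeTSV(cbind(flags, violates_hwe = hwe$violates,
                    concordant = conc$pass, pass = state$qcPass),
              config$outdir, "genotype_qc")
    done("qc", list(n_pass = sum(state$qcPass),
                    n_hwe_violations = sum(hwe$violates)))
  })

  runStage("popgen", function() {
    pc <- config$popgen
    fst <- fstScan(state$gm, "TIB", "HAN", estimator = pc$estimator)
    if (!is.null(state$qcPass)) fst <- fst[state$qcPass, , drop = FALSE]
    strat <- stratifySVs(fst, pc$fst_threshold)
    state$fst <- fst
    state$stratified <- strat
    .writeTSV(fst, config$outdir, "fst")
    .writeTSV(strat, config$outdir, "stratified_svs")
    done("popgen", list(n_tested = sum(!is.na(fst$fst)),
                        n_stratified = nrow(strat)))
  })

  runStage("scan", function() {
    sc <- config$scan
    sy <- config$synthetic
    model <- tibHanAfrModel(pulseFrac = sy$pulse_frac)
    spp <- unlist(sy$samples_per_pop)
    obs <- simulateArchaicIntrogression(model, spp, sy$scan_length,
                                        seed = config$seed + 5)
    tib <- subsetByPop(obs$haps, "TIB")
    daf <- derivedFreq(tib)
    mid <- which.min(abs(positions(obs$haps) - sy$scan_length / 2)[
      daf > 0.2 & daf < 0.6])
    focal <- which(daf > 0.2 & daf < 0.6)[mid]
    swept <- implantSweep(tib, focal, sc$sweep_carrier_fraction,
                          sc$sweep_decay, seed = config$seed + 6)
    m <- hapMatrix(obs$haps)
    m[popLabels(obs$haps) == "TIB", ] <- hapMatrix(swept$haps)
    full <- HaplotypeMatrix(m, positions(obs$haps),
                            genPos = genPositions(obs$haps),
                            samples = sampleIds(obs$haps),
                            populations = popLabels(obs$haps))
    obsWin <- scanWindows(full, "TIB", "HAN", "ARC", "AFR",
                          sy$scan_length, sc$window_size,
                          mafMin = sc$maf_min, cutoff = sc$ehh_cutoff)
    # the neutral null needs archaic samples too: keep the archaic branch
    # but make the pulse negligible
    nullModel <- tibHanAfrModel(pulseFrac = 1e-9)
    nulls <- simulateNeutral(nullModel, spp, sy$scan_length,
                             seed = config$seed + 7,
                             replicates = sc$n_null)
    if (sc$n_null == 1) nulls <- list(nulls)
    nullWin <- do.call(rbind, lapply(nulls, function(r)
      scanWindows(r$haps, "TIB", "HAN", "ARC", "AFR", sy$scan_length,
                  sc$window_size, mafMin = sc$maf_min,
                  cutoff = sc$ehh_cutoff)))
    state$windows <- windowPValues(obsWin, nullWin)
    svs <- data.frame(locus_id = "SV_sweep",
                      pos = positions(full)[focal], fst = NA_real_)
    state$calls <- classifyAdaptation(svs, state$windows,
                                      radius = sc$radius,
                                      alpha = sc$alpha)
    state$scanHaps <- full
    state$focal <- focal
    .writeTSV(state$windows, config$outdir, "scan_windows")
    .writeTSV(state$calls, config$outdir, "adaptation_calls")
    done("scan", list(n_windows = nrow(state$windows),
                      class = state$calls$class[1]))
  })

  runStage("haploview", function() {
    hv <- config$haploview
    if (is.null(state$scanHaps)) {
      message("[haploview] skipped: scan stage outputs unavailable")
      return(invisible(NULL))
    }
    tib <- subsetByPop(state$scanHaps, "TIB")
    han <- subsetByPop(state$scanHaps, "HAN")
    xp <- xpehhScan(tib, han)
    sel <- selectSignalSNVs(xp, positions(state$scanHaps)[state$focal],
                            flank = hv$flank, statistic = hv$statistic,
                            threshold = hv$threshold)
    if (nrow(sel) >= 1) {
      sites <- match(sel$position, positions(state$scanHaps))
      sub <- state$scanHaps[, sites]
      cl <- clusterHaplotypes(sub)
      net <- tryCatch(haplotypeNetwork(sub), error = function(e) NULL)
      .writeTSV(data.frame(haplotype = cl$labels[cl$order],
                           rank = seq_along(cl$order)),
                config$outdir, "haplotype_order")
      .writeTSV(as.data.frame(hapMatrix(sub)), config$outdir,
                "haplotype_heatmap")
      if (!is.null(net))
        .writeTSV(net$edges, config$outdir, "haplotype_network_edges")
      done("haploview", list(n_signal_snvs = nrow(sel),
                             n_nodes = if (is.null(net)) 0
                             else nrow(net$nodes)))
    } else {
      done("haploview", list(n_signal_snvs = 0))
    }
  })

  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
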