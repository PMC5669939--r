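#' Pipeline run configuration
#'
#' Assembles per-stage parameters for [runPipeline()]. All randomness flows
#' from the single `seed`; stage parameters are those of the underlying
#' functions.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (created if absent).
#' @param sim named list of [simConfig()] overrides.
#' @param assignment named list of [assignmentParams()] overrides.
#' @param threshold expression floor in percent (see [thresholdFilter()]).
#' @param top_n per-group top-N size for the miRNA cargo profile.
#' @param sno_top_n per-group top-N size for the snoRNA profile.
#' @param pseudocount log2 pseudocount in percent units.
#' @param linkage clustering linkage method.
#' @param histogram_denominator `"isomir"` or `"all"` (see
#'   [variantClassHistogram()]).
#' @param spectrum optional UV-Vis spectrum TSV path for the biophysics
#'   stage.
#' @param size_histogram optional particle size histogram TSV path.
#' @param min_diameter exclusion threshold (nm) for the weighted mean
#'   diameter.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, out_dir = "evcargo-run",
                      sim = list(), assignment = list(),
                      threshold = 0.05, top_n = 10L, sno_top_n = 20L,
                      pseudocount = 0.01, linkage = "average",
                      histogram_denominator = "isomir",
                      spectrum = NULL, size_histogram = NULL,
                      min_diameter = 30) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
              assignment = assignment, threshold = threshold,
              top_n = as.integer(top_n), sno_top_n = as.integer(sno_top_n),
              pseudocount = pseudocount, linkage = linkage,
              histogram_denominator = histogram_denominator,
              spectrum = spectrum, size_histogram = size_histogram,
              min_diameter = min_diameter)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML-style key:value file; keys mirror the arguments of [runConfig()],
#' with `sim` and `assignment` either nested mappings or flat keys of the
#' form `sim_reads_per_sample: 1000`.
#'
#' @param path configuration file path.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  flatten <- function(prefix) {
    keys <- grep(paste0("^", prefix, "_"), names(raw), value = TRUE)
    sub <- raw[keys]
    names(sub) <- sub(paste0("^", prefix, "_"), "", keys)
    c(if (is.list(raw[[prefix]])) raw[[prefix]] else list(), sub)
  }
  args <- raw[intersect(names(raw), names(formals(runConfig)))]
  args$sim <- flatten("sim")
  args$assignment <- flatten("assignment")
  do.call(runConfig, args)
}

logLine <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  writeLines(line, con)
  flush(con)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  path
}

#' Run the full EV cargo profiling pipeline
#'
#' Executes, in dependency order: simulate (reference + abundances + reads
#' with truth), assign, classify, quantify, cluster, snorna and (when
#' spectrum/size-histogram inputs are configured) biophys, writing every
#' stage output plus a manifest of file digests. Identical configuration and
#' seed yield byte-identical outputs and therefore an identical manifest.
#' Any stage failure aborts with the stage name and cause.
#'
#' @param config a [runConfig()] object.
#' @return invisibly, the manifest as a data.frame (`path`, `bytes`, `md5`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  for (p in c(config$spectrum, config$size_histogram))
    if (!is.null(p) && !file.exists(p))
      stop("configured input path does not exist: ", p)
  out <- config$out_dir
  for (d in c("", "reference", "sim", "reads", "assign", "isomir",
              "quantify", "cluster", "snorna", "biophys"))
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)
  log <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(log), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  ## ---- simulate ----
  sim <- stage("simulate", {
    sc <- do.call(simConfig, c(list(seed = config$seed), config$sim))
    logLine(log, "simulate",
            sprintf("seed=%d groups=%d replicates=%d mirnas=%d reads/sample=%d",
                    sc$seed, sc$n_groups, sc$n_replicates, sc$n_mirnas,
                    sc$reads_per_sample))
    ds <- simulateDataset(sc)
    ref <- ds$reference
    # matures written in the miRBase dialect (U), re-read as DNA downstream
    rna <- Biostrings::RNAStringSet(matureSeqs(ref))
    Biostrings::writeXStringSet(rna, file.path(out, "reference/mature.fa"))
    Biostrings::writeXStringSet(hairpinSeqs(ref),
                                file.path(out, "reference/hairpin.fa"))
    writeTsv(as.data.frame(matureMap(ref)),
             file.path(out, "reference/mature_map.tsv"))
    writeTsv(ds$sno_annotation, file.path(out, "reference/sno_annotation.tsv"))
    Biostrings::writeXStringSet(ds$sno_seqs, file.path(out, "reference/sno.fa"))
    writeTsv(data.frame(mirna_id = rownames(ds$abundances),
                        ds$abundances, check.names = FALSE),
             file.path(out, "sim/abundances.tsv"))
    writeTsv(ds$reads$truth, file.path(out, "sim/truth.tsv"))
    writeSampleSheet(ds$reads$sheet, file.path(out, "sample_sheet.tsv"))
    for (s in names(ds$reads$samples))
      writeSampleFastq(ds$reads$samples[[s]],
                       file.path(out, "reads", paste0(s, ".fastq")))
    writeCountsTsv(ds$sno_counts$WTA, file.path(out, "snorna/counts_wta.tsv"))
    writeCountsTsv(ds$sno_counts$SMALL,
                   file.path(out, "snorna/counts_small.tsv"))
    logLine(log, "simulate", sprintf("%d samples written",
                                     length(ds$reads$samples)))
    c(ds, list(config = sc))
  })

  ## ---- assign ----
  assignments <- stage("assign", {
    matures <- readMatureFasta(file.path(out, "reference/mature.fa"))
    hairpins <- readHairpinFasta(file.path(out, "reference/hairpin.fa"))
    map <- read.delim(file.path(out, "reference/mature_map.tsv"))
    ref <- linkMatureToHairpin(matures, hairpins,
                               setNames(map$hairpin_id, map$mature_id))
    idx <- buildIndex(ref)
    params <- do.call(assignmentParams, config$assignment)
    all <- lapply(names(sim$reads$samples), function(s) {
      res <- assignLibrary(file.path(out, "reads", paste0(s, ".fastq")),
                           idx, params)
      writeAssignmentsTsv(res$assignments,
                          file.path(out, "assign", paste0(s, ".tsv")))
      logLine(log, "assign",
              sprintf("%s: reads=%d assigned=%d unassigned=%d", s,
                      sum(res$counters), res$counters["assigned"],
                      res$counters["unassigned"]))
      cbind(sample_id = s, res$assignments, stringsAsFactors = FALSE)
    })
    do.call(rbind, all)
  })

  ## ---- classify ----
  stage("classify", {
    writeTsv(isomirCountTable(assignments),
             file.path(out, "isomir/isomir_counts.tsv"))
    writeTsv(variantClassHistogram(assignments,
                                   config$histogram_denominator),
             file.path(out, "isomir/class_histogram.tsv"))
    frac <- isomirFraction(assignments)
    writeTsv(data.frame(sample_id = names(frac), isomir_fraction = frac),
             file.path(out, "isomir/isomir_fraction.tsv"))
    logLine(log, "classify",
            sprintf("isomiR fraction %.3f-%.3f across samples",
                    min(frac), max(frac)))
  })

  ## ---- quantify ----
  quant <- stage("quantify", {
    counts <- mirnaCountMatrix(assignments,
                               names(matureSeqs(sim$reference)))
    writeCountsTsv(counts, file.path(out, "quantify/mirna_counts.tsv"))
    pct <- percentOfTotal(counts)
    gp <- groupMean(pct, sim$reads$sheet)
    retained <- thresholdFilter(gp, config$threshold)
    writeTsv(data.frame(feature_id = retained),
             file.path(out, "quantify/retained.tsv"))
    tn <- topN(gp[retained, , drop = FALSE], config$top_n)
    writeTsv(tn, file.path(out, "quantify/top_n.tsv"))
    share <- cumulativeTopShare(gp, config$top_n)
    writeTsv(data.frame(group = names(share), percent = share),
             file.path(out, "quantify/cumulative_share.tsv"))
    logLine(log, "quantify",
            sprintf("features in=%d retained=%d (threshold %.3f%%)",
                    nrow(counts), length(retained), config$threshold))
    list(pct = pct, gp = gp, retained = retained)
  })

  ## ---- cluster ----
  stage("cluster", {
    mat <- log2Transform(quant$pct[quant$retained, , drop = FALSE],
                         config$pseudocount)
    tree <- hierarchicalCluster(mat, config$linkage)
    writeNewick(tree, file.path(out, "cluster/samples.nwk"))
    coh <- replicateCoherence(tree, sim$reads$sheet)
    writeTsv(data.frame(group = names(coh), coherent = coh),
             file.path(out, "cluster/coherence.tsv"))
    logLine(log, "cluster", sprintf("coherent groups: %d/%d", sum(coh),
                                    length(coh)))
  })

  ## ---- snorna ----
  stage("snorna", {
    prof <- snoProfile(sim$sno_counts$WTA, sim$sno_counts$SMALL,
                       sim$reads$sheet, sim$sno_annotation,
                       config$sno_top_n)
    writeTsv(data.frame(library = rep(c("WTA", "SMALL"),
                                      c(length(prof$WTA$union),
                                        length(prof$SMALL$union))),
                        sno_id = c(prof$WTA$union, prof$SMALL$union)),
             file.path(out, "snorna/top_union.tsv"))
    cs <- rbind(data.frame(library = "WTA", box_class = SNO_CLASSES,
                           count = unname(prof$WTA$class_summary)),
                data.frame(library = "SMALL", box_class = SNO_CLASSES,
                           count = unname(prof$SMALL$class_summary)))
    writeTsv(cs, file.path(out, "snorna/class_summary.tsv"))
    writeTsv(data.frame(intersection = prof$overlap$intersection,
                        jaccard = prof$overlap$jaccard),
             file.path(out, "snorna/overlap.tsv"))
    logLine(log, "snorna",
            sprintf("union sizes WTA=%d SMALL=%d overlap=%d",
                    length(prof$WTA$union), length(prof$SMALL$union),
                    prof$overlap$intersection))
  })

  ## ---- biophys ----
  if (!is.null(config$spectrum) || !is.null(config$size_histogram))
    stage("biophys", {
      rows <- list()
      if (!is.null(config$spectrum))
        rows$ai <- data.frame(quantity = "aggregation_index",
                              value = aggregationIndex(
                                readSpectrumTsv(config$spectrum)))
      if (!is.null(config$size_histogram))
        rows$wmd <- data.frame(quantity = "weighted_mean_diameter_nm",
                               value = weightedMeanDiameter(
                                 readSizeHistogramTsv(config$size_histogram),
                                 minDiameter = config$min_diameter))
      writeTsv(do.call(rbind, rows), file.path(out, "biophys/biophysics.tsv"))
      logLine(log, "biophys", "computed")
    })

  ## ---- manifest ----
  manifest <- stage("manifest", {
    files <- list.files(out, recursive = TRUE)
    files <- setdiff(files, c("run.log", "manifest.json"))
    files <- sort(files)
    info <- file.info(file.path(out, files))
    df <- data.frame(path = files, bytes = as.integer(info$size),
                     md5 = unname(tools::md5sum(file.path(out, files))),
                     stringsAsFactors = FALSE)
    jsonlite::write_json(df, file.path(out, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
    df
  })
  logLine(log, "done", sprintf("%d output files", nrow(manifest)))
  invisible(manifest)
}
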