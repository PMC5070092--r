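#' Format a count with its per-Mb density
#'
#' Report cell format used in the region summary table: `"count (density)"`
#' with the density rounded half-up to 2 decimals, e.g. `"121 (13.75)"`.
#'
#' @param count integer count.
#' @param densityPerMb density in events per Mb.
#' @return character vector.
#' @examples
#' formatCountDensity(121, 121 / 8.8)  # "121 (13.75)"
#' @export
formatCountDensity <- function(count, densityPerMb) {
    sprintf("%d (%s)", as.integer(count),
            formatC(roundHalfUp(densityPerMb, 2), format = "f", digits = 2))
}

#' Assemble a region summary table
#'
#' Formats per-region summaries ([summarizeRegion()] rows, optionally from
#' several species) into the report layout: one row per region with mean FST
#' over polymorphic sites and `"count (per-Mb density)"` cells for
#' sex-patterned SNPs, enriched windows and (when annotated) missense,
#' deleterious and synonymous SNPs, plus a totals row per species summing the
#' counts.
#'
#' @param summaries data.frame of [summarizeRegion()] rows; an optional
#'   `species` column groups rows into per-species blocks.
#' @return a data.frame of formatted report rows.
#' @export
makeTable1 <- function(summaries) {
    if (!"species" %in% names(summaries)) summaries$species <- "pool"
    hasAnn <- "n_missense" %in% names(summaries)
    blocks <- lapply(split(summaries, summaries$species), function(s) {
        row <- data.frame(
            species = s$species, region = s$label,
            mean_fst = formatC(roundHalfUp(s$mean_fst_polymorphic, 3),
                               format = "f", digits = 3),
            sex_patterned = formatCountDensity(s$n_sex_patterned,
                                               s$density_per_mb),
            enriched_windows = formatCountDensity(s$n_enriched_windows,
                                                  s$enriched_density_per_mb))
        if (hasAnn) {
            row$missense <- formatCountDensity(s$n_missense, s$missense_per_mb)
            row$deleterious <- formatCountDensity(s$n_deleterious,
                                                  s$deleterious_per_mb)
            row$synonymous <- formatCountDensity(s$n_synonymous,
                                                 s$synonymous_per_mb)
        }
        tot <- data.frame(species = s$species[1], region = "Total",
                          mean_fst = "",
                          sex_patterned = as.character(sum(s$n_sex_patterned)),
                          enriched_windows =
                              as.character(sum(s$n_enriched_windows)))
        if (hasAnn) {
            tot$missense <- as.character(sum(s$n_missense))
            tot$deleterious <- as.character(sum(s$n_deleterious))
            tot$synonymous <- as.character(sum(s$n_synonymous))
        }
        rbind(row, tot)
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
}

parseRegionString <- function(s) {
    m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(m) != 4L) abort("bad region string: ", s,
                               " (expected chrom:start-end)")
    GRanges(m[2], IRanges(as.integer(m[3]), as.integer(m[4])))
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages in order: simulate (or load) the two species'
#' pooled counts, per-site scan for each species, windowing and enrichment,
#' region comparisons, cross-species shared-SNP classification with the null
#' expectation, conserved-CNV merging, optional allele-specific TFBS scan,
#' and the region summary report. Each stage writes its TSV beside `outdir`
#' so any stage can be re-run from intermediates; a run manifest with all
#' parameter values and per-stage record counts is written as YAML. Re-running
#' with the same configuration reproduces every output byte for byte.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognised fields: `outdir`; `seed`; `simulate` (two [simConfig()]
#'   argument lists `a` and `b` plus `shared_fraction`, `switch_fraction`,
#'   `y_replace_fraction`) or `inputs` (`sync_a`, `sync_b` paths); `detector`
#'   ([detectorParams()] arguments); `window_size`; `min_snps`; `sd_region`
#'   (string `chrom:start-end` for the shared-SNP null); `cnv` (list of
#'   VarScan segment paths in `tracks`, or `simulate: yes` reusing the SD
#'   region); `tfbs` (`pfm` path, `fasta` path, `threshold`).
#' @param dryRun validate the configuration and report the planned stages
#'   without reading data or writing outputs.
#' @return invisibly, a list with the main in-memory results (`statsA`,
#'   `statsB`, `windowsA`, `windowsB`, `shared`, `expected`, `cnv`,
#'   `table1`, `files`).
#' @export
runPipeline <- function(config, dryRun = FALSE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    need <- function(field) {
        if (is.null(config[[field]])) abort("config is missing '", field, "'")
        config[[field]]
    }
    outdir <- need("outdir")
    seed <- as.integer(config$seed %||% 1L)
    det <- do.call(detectorParams, config$detector %||% list())
    windowSize <- config$window_size %||% 10000
    minSnps <- config$min_snps %||% 10
    sdRegion <- if (!is.null(config$sd_region))
        parseRegionString(config$sd_region) else NULL
    if (is.null(config$simulate) && is.null(config$inputs))
        abort("config needs either 'simulate' or 'inputs'")
    if (dryRun) {
        message("dry run: config valid; stages: ",
                paste(c("counts", "scan", "windows", "shared", "cnv",
                        if (!is.null(config$tfbs)) "tfbs", "report"),
                      collapse = " -> "))
        return(invisible(NULL))
    }
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outdir, f)
    files <- character()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            abort("stage '", name, "' failed: ", conditionMessage(e)))
    }
    ## counts
    pair <- NULL
    stage("counts", {
        if (!is.null(config$simulate)) {
            sc <- config$simulate
            mkCfg <- function(x) {
                x$chromLengths <- unlist(x$chromLengths)
                if (!is.null(x$sdRegion) && is.character(x$sdRegion))
                    x$sdRegion <- parseRegionString(x$sdRegion)
                do.call(simConfig, x)
            }
            pair <- simulateSpeciesPair(
                mkCfg(sc$a), mkCfg(sc$b),
                sharedFraction = sc$shared_fraction %||% 0.5,
                switchFraction = sc$switch_fraction %||% 0,
                yReplaceFraction = sc$y_replace_fraction %||% 0,
                seed = seed)
            countsA <- sortSites(pair$a$counts)
            countsB <- sortSites(pair$b$counts)
            writeSyncTable(countsA, fp("counts_a.tsv"))
            writeSyncTable(countsB, fp("counts_b.tsv"))
            writeTruthTable(pair$shared_truth, fp("shared_truth.tsv"))
        } else {
            countsA <- sortSites(readSyncTable(config$inputs$sync_a))
            countsB <- sortSites(readSyncTable(config$inputs$sync_b))
        }
    })
    ## per-site scan
    statsA <- statsB <- NULL
    stage("scan", {
        statsA <- scanSites(countsA, det, quiet = TRUE)
        statsB <- scanSites(countsB, det, quiet = TRUE)
        files <- c(files, writeSiteStats(statsA, fp("sitestats_a.tsv")),
                    writeSiteStats(statsB, fp("sitestats_b.tsv")))
    })
    ## windows
    windowsA <- windowsB <- NULL
    stage("windows", {
        gaps <- if (!is.null(config$gaps)) readBedGaps(config$gaps)
                else GRanges()
        windowsA <- callEnriched(windowCounts(statsA, windowSize, gaps),
                                  minSnps)
        windowsB <- callEnriched(windowCounts(statsB, windowSize, gaps),
                                  minSnps)
        wdf <- function(w) data.frame(chrom = as.character(seqnames(w)),
                                      start = start(w), end = end(w),
                                      as.data.frame(mcols(w)))
        files <- c(files, writeResultsTsv(wdf(windowsA), fp("windows_a.tsv")),
                    writeResultsTsv(wdf(windowsB), fp("windows_b.tsv")))
    })
    ## shared SNPs
    shared <- NULL; expct <- NULL
    stage("shared", {
        shared <- intersectAndClassify(statsA, statsB)
        if (!is.null(sdRegion)) {
            inReg <- function(s) sum(
                mcols(s)$sex_patterned %in% TRUE &
                    IRanges::overlapsAny(s, sdRegion))
            expct <- expectedShared(inReg(statsA), inReg(statsB),
                                     sum(width(sdRegion)))
        }
        files <- c(files, writeResultsTsv(shared, fp("shared.tsv")))
    })
    ## CNV
    cnv <- NULL
    stage("cnv", {
        tracks <- NULL
        if (!is.null(config$cnv$tracks))
            tracks <- lapply(config$cnv$tracks, readVarscanSegments)
        else if (isTRUE(config$cnv$simulate) && !is.null(sdRegion)) {
            true <- GRanges(seqnames(sdRegion),
                            IRanges(start(sdRegion) + c(0, 2000),
                                    width = 800),
                            direction = c("AMP", "DEL"))
            tracks <- simulateCnvTracks(2L, true, seed = seed)$tracks
            tracks <- lapply(tracks, thresholdSegments)
        }
        if (!is.null(tracks)) {
            if (is.null(mcols(tracks[[1]])$direction))
                tracks <- lapply(tracks, thresholdSegments,
                                 ampThreshold = config$cnv$amp %||% 0.2,
                                 delThreshold = config$cnv$del %||% 0.2)
            cnv <- conservedCnvs(tracks)
            files <- c(files,
                        writeConservedCnvs(cnv, fp("conserved_cnv.tsv")))
        }
    })
    ## TFBS
    stage("tfbs", {
        if (!is.null(config$tfbs)) {
            pfms <- readJasparPfm(config$tfbs$pfm)
            pwms <- lapply(pfms, pfmToPwm)
            fa <- Biostrings::readDNAStringSet(config$tfbs$fasta)
            names(fa) <- sub("\\s.*$", "", names(fa))
            radius <- config$tfbs$flank_radius %||% 20L
            thr <- config$tfbs$threshold %||% 0.80
            rows <- list()
            cons <- shared[shared$class == "CONSERVED", , drop = FALSE]
            for (i in seq_len(nrow(cons))) {
                chr <- cons$chrom[i]
                if (!chr %in% names(fa)) next
                pos <- cons$pos[i]
                from <- max(1L, pos - radius)
                to <- min(Biostrings::width(fa[chr]), pos + radius)
                flank <- as.character(Biostrings::subseq(fa[[chr]], from, to))
                d <- alleleDiff(flank, pos - from, cons$x_a[i], cons$y_a[i],
                                pwms, thr)
                d <- cbind(chrom = chr, pos = pos, d)
                rows[[length(rows) + 1L]] <- d
            }
            diffs <- if (length(rows)) do.call(rbind, rows) else
                data.frame(chrom = character(), pos = integer(),
                           motif = character(), name = character(),
                           status = character(), best_rel_x = numeric(),
                           best_rel_y = numeric())
            files <- c(files, writeResultsTsv(diffs, fp("allele_diff.tsv")))
        }
    })
    ## report
    table1 <- NULL
    stage("report", {
        mkSummary <- function(stats, windows, species) {
            sl <- seqlengths(stats)
            sl <- sl[!is.na(sl)]
            regs <- list()
            if (!is.null(sdRegion)) {
                regs$sd_region <- sdRegion
                if (length(sl))
                    regs$rest_of_genome <- restOfGenome(sdRegion, sl)
            } else if (length(sl)) {
                regs$genome <- GRanges(names(sl), IRanges(1L, as.integer(sl)))
            }
            rows <- lapply(names(regs), function(nm)
                summarizeRegion(stats, windows, regs[[nm]], nm))
            s <- do.call(rbind, rows)
            s$species <- species
            s
        }
        summ <- rbind(mkSummary(statsA, windowsA, "species_a"),
                      mkSummary(statsB, windowsB, "species_b"))
        table1 <- makeTable1(summ)
        files <- c(files, writeResultsTsv(table1, fp("region_summary.tsv")))
    })
    manifest <- list(seed = seed, window_size = windowSize,
                     min_snps = minSnps,
                     detector = list(het_low = det@hetLow,
                                     het_high = det@hetHigh,
                                     homog_fixed_max = det@homogFixedMax,
                                     min_depth = det@minDepth,
                                     min_allele_count = det@minAlleleCount,
                                     max_coverage = det@maxCoverage),
                     n_sites_a = length(statsA), n_sites_b = length(statsB),
                     n_shared = nrow(shared),
                     expected_shared = if (!is.null(expct)) expct$expected,
                     outputs = basename(files))
    yaml::write_yaml(manifest, fp("run_manifest.yaml"))
    invisible(list(statsA = statsA, statsB = statsB, windowsA = windowsA,
                   windowsB = windowsB, shared = shared, expected = expct,
                   cnv = cnv, table1 = table1,
                   files = c(files, fp("run_manifest.yaml"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
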