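#' Read a sync-style table of pooled allele counts
#'
#' The sync-style table is the package's plain-text interchange format for
#' pooled biallelic counts: a tab-separated file with the header
#' `chrom pos ref alt pool1_ref pool1_alt pool2_ref pool2_alt`, where pool 1
#' is the heterogametic-sex pool and pool 2 the homogametic-sex pool (swap the
#' arguments of downstream functions for a WZ system). Malformed lines are
#' hard errors naming the offending line number; nothing is silently dropped.
#'
#' @param path file path.
#' @return a [PooledCounts-class] in file order.
#' @seealso [writeSyncTable()] for the inverse.
#' @examples
#' f <- tempfile()
#' writeLines(c("chrom\tpos\tref\talt\tpool1_ref\tpool1_alt\tpool2_ref\tpool2_alt",
#'              "chr1\t100\tA\tG\t18\t12\t30\t0"), f)
#' readSyncTable(f)
#' @export
readSyncTable <- function(path) {
    cols <- c("chrom", "pos", "ref", "alt",
              "pool1_ref", "pool1_alt", "pool2_ref", "pool2_alt")
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (!identical(hdr, cols))
        abort("sync table header must be: ", paste(cols, collapse = " "),
              " (got: ", paste(hdr, collapse = " "), ")")
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer", "character",
                                           "character", rep("character", 4)),
                            quote = "", comment.char = "")
    checkLine <- function(ok, what) {
        if (any(!ok))
            abort(what, " at line ", which(!ok)[1] + 1L)
    }
    cnt <- lapply(df[cols[5:8]], function(v) suppressWarnings(as.integer(v)))
    for (j in seq_along(cnt))
        checkLine(!is.na(cnt[[j]]) & cnt[[j]] >= 0 &
                      grepl("^[0-9]+$", df[[cols[4 + j]]]),
                  paste0("non-integer count in column ", cols[4 + j]))
    checkLine(!is.na(df$pos) & df$pos >= 1, "invalid position")
    checkLine(df$ref %in% DNA_BASES, "invalid ref allele")
    checkLine(df$alt %in% DNA_BASES, "invalid alt allele")
    checkLine(df$ref != df$alt, "ref equals alt")
    PooledCounts(df$chrom, df$pos, df$ref, df$alt,
                 cnt$pool1_ref, cnt$pool1_alt, cnt$pool2_ref, cnt$pool2_alt)
}

#' Write pooled counts as a sync-style table
#'
#' Inverse of [readSyncTable()]; output is deterministic so that two identical
#' writes produce identical bytes, and `writeSyncTable(readSyncTable(f))`
#' reproduces `f`.
#'
#' @param x a [PooledCounts-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSyncTable <- function(x, path) {
    rr <- rowRanges(x)
    df <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                     ref = mcols(rr)$ref, alt = mcols(rr)$alt,
                     pool1_ref = refCounts(x)[, "het"],
                     pool1_alt = altCounts(x)[, "het"],
                     pool2_ref = refCounts(x)[, "hom"],
                     pool2_alt = altCounts(x)[, "hom"])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read pooled allele counts from a two-sample VCF
#'
#' Adapter from a conventional variant-calling workflow: reads a VCF whose two
#' named samples are the male and female pools and converts the per-allele
#' read depths (`AD` genotype field) of biallelic SNPs into a
#' [PooledCounts-class]. Multiallelic records and indels are skipped; the
#' number skipped is reported in a message and stored in
#' `metadata(x)$n_skipped`.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param pool1Sample sample name of the heterogametic (male, in XY) pool.
#' @param pool2Sample sample name of the homogametic (female) pool.
#' @return a [PooledCounts-class] in file order.
#' @export
readPooledVcf <- function(path, pool1Sample, pool2Sample) {
    vcf <- VariantAnnotation::readVcf(path)
    smp <- colnames(vcf)
    for (s in c(pool1Sample, pool2Sample))
        if (!s %in% smp)
            abort("sample '", s, "' not present in ", path,
                  " (samples: ", paste(smp, collapse = ", "), ")")
    nIn <- nrow(vcf)
    keep <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
    vcf <- vcf[keep, ]
    nSkip <- nIn - nrow(vcf)
    if (nSkip > 0L)
        message("readPooledVcf: skipped ", nSkip,
                " multiallelic/indel record(s)")
    ad <- VariantAnnotation::geno(vcf)$AD
    if (is.null(ad)) abort("VCF has no AD (allelic depth) genotype field")
    getAD <- function(sample, k)
        vapply(ad[, sample], function(v) as.integer(v[k]), integer(1))
    rr <- SummarizedExperiment::rowRanges(vcf)
    x <- PooledCounts(
        chrom = as.character(seqnames(rr)), pos = start(rr),
        ref = as.character(rr$REF),
        alt = as.character(unlist(rr$ALT)),
        hetRef = getAD(pool1Sample, 1L), hetAlt = getAD(pool1Sample, 2L),
        homRef = getAD(pool2Sample, 1L), homAlt = getAD(pool2Sample, 2L))
    metadata(x)$n_skipped <- nSkip
    x
}

#' Read assembly gaps from a BED file
#'
#' BED3 intervals (0-based half-open on disk) of assembly gaps, returned as a
#' 1-based [GenomicRanges::GRanges]. Overlapping or duplicate gap lines are
#' merged with a warning.
#'
#' @param path BED file path.
#' @return a `GRanges` of disjoint gap intervals.
#' @export
readBedGaps <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr) <- NULL
    red <- GenomicRanges::reduce(gr)
    if (length(red) < length(gr))
        warning("merged ", length(gr) - length(red) + 1L,
                " overlapping/duplicate gap intervals")
    red
}

#' Read VarScan copynumber segments
#'
#' Parses the tab-separated output of VarScan 2's `copynumber` command. The
#' expected columns, in order, are `chrom`, `chr_start`, `chr_stop` (1-based
#' inclusive), `num_positions`, `normal_depth`, `tumor_depth`,
#' `log2_ratio` — here "normal" and "tumor" are simply the two pools being
#' compared. Extra trailing columns are ignored.
#'
#' @param path file path (with header line).
#' @return a [GenomicRanges::GRanges] with mcols `n_positions`, `depth1`,
#'   `depth2`, `log2_ratio`.
#' @export
readVarscanSegments <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) < 7L)
        abort("VarScan segment file needs >= 7 columns, got ", ncol(df))
    names(df)[1:7] <- c("chrom", "chr_start", "chr_stop", "num_positions",
                        "normal_depth", "tumor_depth", "log2_ratio")
    bad <- df$chr_stop < df$chr_start
    if (any(bad))
        abort("segment end < start at line ", which(bad)[1] + 1L)
    if (any(df$num_positions < 1L))
        abort("num_positions must be >= 1 (line ",
              which(df$num_positions < 1L)[1] + 1L, ")")
    GRanges(df$chrom, IRanges(df$chr_start, df$chr_stop),
            n_positions = as.integer(df$num_positions),
            depth1 = as.numeric(df$normal_depth),
            depth2 = as.numeric(df$tumor_depth),
            log2_ratio = as.numeric(df$log2_ratio))
}

#' Write VarScan-style segments
#'
#' @param segments a `GRanges` as returned by [readVarscanSegments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVarscanSegments <- function(segments, path) {
    df <- data.frame(chrom = as.character(seqnames(segments)),
                     chr_start = start(segments), chr_stop = end(segments),
                     num_positions = mcols(segments)$n_positions,
                     normal_depth = fmtNum(mcols(segments)$depth1, 2),
                     tumor_depth = fmtNum(mcols(segments)$depth2, 2),
                     log2_ratio = fmtNum(mcols(segments)$log2_ratio, 4))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read JASPAR 2016 position frequency matrices
#'
#' Parses the JASPAR 2016 text format: each motif is a header line
#' `>ID name` followed by four rows like `A [ 4 19 0 ... ]`. Rows may appear
#' in any order; they are returned in A,C,G,T order. Rows of unequal length
#' within a motif are a hard error naming the motif.
#'
#' @param path file path.
#' @return a named list of [PFMatrix-class] objects (names = matrix IDs).
#' @export
readJasparPfm <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    starts <- grep("^>", lines)
    if (!length(starts)) abort("no motif headers ('>') found in ", path)
    out <- list()
    for (i in seq_along(starts)) {
        from <- starts[i]
        to <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
        hdr <- strsplit(sub("^>\\s*", "", lines[from]), "\\s+")[[1]]
        id <- hdr[1]
        nm <- if (length(hdr) > 1L) paste(hdr[-1], collapse = " ") else id
        body <- lines[(from + 1L):to]
        if (length(body) != 4L)
            abort("motif ", id, ": expected 4 count rows, got ", length(body))
        rows <- list()
        for (b in body) {
            base <- sub("^\\s*([ACGTacgt]).*$", "\\1", b)
            if (!toupper(base) %in% DNA_BASES)
                abort("motif ", id, ": unrecognised count row '", b, "'")
            nums <- sub("^\\s*[ACGTacgt]\\s*\\[?", "", b)
            nums <- sub("\\]\\s*$", "", nums)
            vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
            if (any(is.na(vals)))
                abort("motif ", id, ": non-numeric counts in row '", b, "'")
            rows[[toupper(base)]] <- vals
        }
        if (!setequal(names(rows), DNA_BASES))
            abort("motif ", id, ": need one row for each of A, C, G, T")
        lens <- vapply(rows, length, integer(1))
        if (length(unique(lens)) != 1L)
            abort("motif ", id, ": rows of unequal length")
        m <- do.call(rbind, rows[DNA_BASES])
        out[[id]] <- PFMatrix(id, nm, m)
    }
    out
}

#' Write a results table with deterministic formatting
#'
#' All tabular result writers in the package funnel through this helper:
#' deterministic column order (as given), tab separation, fixed 6-decimal
#' formatting for floating-point columns, `NA` for missing values. Two
#' identical calls produce byte-identical files.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param digits decimal places for numeric (double) columns.
#' @return `path`, invisibly.
#' @export
writeResultsTsv <- function(df, path, digits = 6) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- fmtNum(out[[j]], digits)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    invisible(path)
}
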