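#' @include AllClasses.R
NULL

#' Read a per-sample study table
#'
#' Reads a tab-delimited table with a header and columns `sample`, `D`
#' (primary disease, 0/1), `T` (secondary trait, 0/1), and one 0/1/2
#' genotype column per SNP (missing genotypes empty or `NA`). Rows with a
#' missing phenotype are dropped with a message; missing genotypes are
#' excluded per-SNP when counting.
#'
#' @param path Path to the file.
#' @return A validated data frame; attribute `snps` lists the genotype
#'   column names.
#' @export
readStudyTable <- function(path) {
    tbl <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample", "D", "T")
    if (!all(need %in% names(tbl)))
        stop("study table must have columns: ", paste(need, collapse = ", "))
    if (nrow(tbl) == 0) stop("no samples")
    drop <- is.na(tbl$D) | is.na(tbl$T)
    if (any(drop)) {
        message("dropping ", sum(drop), " row(s) with missing phenotype")
        tbl <- tbl[!drop, , drop = FALSE]
        if (nrow(tbl) == 0) stop("no samples")
    }
    for (v in c("D", "T")) {
        bad <- which(!(tbl[[v]] %in% c(0, 1)))
        if (length(bad))
            stop("non-binary ", v, " at row ", bad[1])
    }
    snps <- setdiff(names(tbl), need)
    for (v in snps) {
        bad <- which(!(is.na(tbl[[v]]) | tbl[[v]] %in% c(0, 1, 2)))
        if (length(bad))
            stop("unknown genotype code in ", v, " at row ", bad[1])
    }
    attr(tbl, "snps") <- snps
    tbl
}

#' Stratified genotype counts of one SNP from a study table
#'
#' @param tbl A study table (see [readStudyTable]).
#' @param snp Name of the genotype column.
#' @return A [BlockCounts-class]; missing genotypes are excluded from the
#'   counts.
#' @export
blocksFromTable <- function(tbl, snp) {
    if (!snp %in% names(tbl)) stop("no such SNP column: ", snp)
    g <- tbl[[snp]]
    keep <- !is.na(g)
    g <- as.integer(g[keep])
    Tv <- tbl$T[keep]; Dv <- tbl$D[keep]
    cnt <- function(i, j) tabulate(g[Tv == i & Dv == j] + 1L, 3L)
    blockCounts(cnt(0, 0), cnt(1, 0), cnt(0, 1), cnt(1, 1))
}

#' Write HWP test results as a tab-delimited table
#'
#' Deterministic column order `snp`, `method`, `statistic`, `p_value`,
#' `converged`, `flags`; p-values are serialized with full precision so a
#' round-trip read reproduces them.
#'
#' @param results A named list of [HWPTestResult-class] objects (names are
#'   SNP ids), or a data frame already in the output schema.
#' @param path Output path.
#' @return The written data frame, invisibly.
#' @export
writeResults <- function(results, path) {
    if (length(results) == 0) stop("results must be nonempty")
    df <- if (is.data.frame(results)) results else {
        snp <- names(results)
        if (is.null(snp)) snp <- paste0("snp", seq_along(results))
        data.frame(
            snp = snp,
            method = vapply(results, function(r) r@method, character(1)),
            statistic = vapply(results, statistic, numeric(1)),
            p_value = vapply(results, pValue, numeric(1)),
            converged = vapply(results, function(r) r@converged, logical(1)),
            flags = vapply(results, function(r) {
                fl <- r@diagnostics$flags
                if (is.null(fl)) "" else paste(fl, collapse = ";")
            }, character(1)),
            row.names = NULL)
    }
    write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Extract 0/1/2 genotypes from a VCF file
#'
#' Convenience on-ramp from VCF: reads the GT field of diploid biallelic
#' records and codes genotypes as the count of ALT alleles. Multiallelic
#' records and half-calls are skipped with a warning. Requires the `vcfR`
#' package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Integer matrix samples x SNPs with entries 0/1/2 or `NA`.
#' @export
readVcfGenotypes <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("readVcfGenotypes requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcfR::getALT(v))
    if (any(multi)) {
        warning("skipping ", sum(multi), " multiallelic record(s)")
        v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- function(x) {
        x <- sub("\\|", "/", x)
        out <- rep(NA_integer_, length(x))
        out[x %in% c("0/0")] <- 0L
        out[x %in% c("0/1", "1/0")] <- 1L
        out[x %in% c("1/1")] <- 2L
        out
    }
    m <- apply(gt, 2, code)
    half <- sum(!is.na(gt) & is.na(m))
    if (half > 0) warning(half, " half-call/invalid GT value(s) set missing")
    rn <- rownames(gt)
    out <- t(matrix(m, nrow = nrow(gt),
                    dimnames = list(rn, colnames(gt))))
    out
}
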