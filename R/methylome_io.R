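#' Read per-CpG methylation calls
#'
#' Parses a bedGraph-dialect tab-separated file with four columns:
#' chromosome, 0-based position, methylated read count, total read count.
#' Every malformed row (wrong column count, non-integer counts, negative
#' counts, methylated count exceeding total) is rejected with its line
#' number.
#'
#' @param path path to the calls file for one embryo.
#' @return a `data.frame` with columns `chrom`, `pos`, `meth`, `total`.
#'   An empty file yields an empty frame with a warning.
#' @export
readCpgCalls <- function(path) {
  if (!file.exists(path)) stop("CpG call file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    warning("empty CpG call file: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer()))
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("malformed CpG row (expected 4 tab-separated fields) at line ",
         bad[1L], " of ", path)
  flat <- unlist(parts, use.names = FALSE)
  chrom <- flat[c(TRUE, FALSE, FALSE, FALSE)]
  pos <- suppressWarnings(as.integer(flat[c(FALSE, TRUE, FALSE, FALSE)]))
  meth <- suppressWarnings(as.integer(flat[c(FALSE, FALSE, TRUE, FALSE)]))
  total <- suppressWarnings(as.integer(flat[c(FALSE, FALSE, FALSE, TRUE)]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(total) |
                 pos < 0L | meth < 0L | total <= 0L)
  if (length(bad))
    stop("malformed CpG row (non-numeric or out-of-range field) at line ",
         bad[1L], " of ", path)
  bad <- which(meth > total)
  if (length(bad))
    stop("methylated count exceeds total count at line ", bad[1L],
         " of ", path)
  data.frame(chrom = chrom, pos = pos, meth = meth, total = total)
}

#' Read a BED-like promoter annotation
#'
#' Expects six tab-separated columns (chrom, start, end, gene id, score,
#' strand) with 0-based half-open coordinates. The TSS is taken as `start`
#' on the plus strand and `end - 1` on the minus strand, and each gene is
#' assigned the symmetric promoter window `[tss - 1000, tss + 1000)`:
#' "1000 bp upstream and downstream" of the TSS defines the same interval
#' on either strand, strand only locates the TSS within the gene record.
#'
#' @param path path to the annotation file.
#' @param flank half-width of the promoter window in bp (default 1000).
#' @return a [GenomicRanges::GRanges] of promoter windows, names and
#'   `gene_id` column set to the gene ids, with a `tss` metadata column.
#' @export
readPromoterAnnotation <- function(path, flank = 1000L) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "gene_id", "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character"))
  if (nrow(tab) == 0L) stop("annotation file has no records: ", path)
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(tab$gene_id))
    stop("duplicated gene ids in annotation")
  tss <- ifelse(tab$strand == "+", tab$start, tab$end - 1L)
  promoterWindows(tab$chrom, tss, tab$strand, tab$gene_id, flank = flank)
}

#' Build promoter windows around TSS positions
#'
#' @param chrom,tss,strand,gene_id parallel vectors describing each TSS
#'   (0-based positions).
#' @param flank half-width in bp; the window is `[tss - flank, tss + flank)`
#'   in 0-based half-open coordinates regardless of strand.
#' @return a [GenomicRanges::GRanges] with one window per gene.
#' @export
promoterWindows <- function(chrom, tss, strand, gene_id, flank = 1000L) {
  tss <- as.integer(tss)
  # GRanges is 1-based closed; 0-based half-open [tss-flank, tss+flank)
  # maps to 1-based [tss-flank+1, tss+flank]
  gr <- GRanges(chrom,
                IRanges(start = tss - flank + 1L, end = tss + flank),
                strand = strand)
  gr$gene_id <- as.character(gene_id)
  gr$tss <- tss
  names(gr) <- gr$gene_id
  gr
}

#' Read a sample sheet
#'
#' Header CSV with columns `embryo_id`, `patient_id`, `outcome`
#' (`Birth`/`Failed`), `transfer_order`, `selected` (logical), and
#' `maternal_age`.
#'
#' @param path path to the CSV file.
#' @return a `data.frame`, one row per embryo.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  ss <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "patient_id", "outcome", "transfer_order",
            "selected", "maternal_age")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (!all(ss$outcome %in% c("Birth", "Failed")))
    stop("outcome must be 'Birth' or 'Failed'")
  if (anyDuplicated(ss$embryo_id)) stop("duplicated embryo ids")
  ss$selected <- as.logical(ss$selected)
  ss
}

#' Whole-genome methylation level of one embryo
#'
#' The unweighted mean, over all sequencing-covered CpGs, of the per-CpG
#' methylation fraction (methylated count / total count). This is the
#' summary the ML-score deviates from the 0.26 optimum.
#'
#' @param calls a CpG call `data.frame` as returned by [readCpgCalls()].
#' @return a fraction in \[0, 1\].
#' @export
wholeGenomeML <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L)
    stop("cannot compute a whole-genome methylation level from zero CpGs")
  mean(calls$meth / calls$total)
}

#' Build the embryo x promoter methylation matrix
#'
#' For each embryo and promoter window, the cell value is the unweighted
#' mean methylation fraction over the CpGs falling inside the half-open
#' window, and the cell coverage is the sum of their total read counts.
#' Cells whose summed coverage is below `minCoverage` (default 30x, i.e.
#' promoters with less than 30 reads of total CpG coverage) are set to
#' missing; the filter is applied per embryo-promoter cell. CpGs on
#' chromosomes absent from the annotation are skipped (a count is
#' reported via `message`).
#'
#' @param callsList named list of CpG call frames, one per embryo; names
#'   are embryo ids.
#' @param promoters a [GenomicRanges::GRanges] of promoter windows (see
#'   [readPromoterAnnotation()]); windows may overlap and a CpG may be
#'   counted in several.
#' @param sampleSheet optional sample sheet `data.frame`; when given, its
#'   rows are matched to `names(callsList)` by `embryo_id` and stored as
#'   `colData`, and the whole-genome level of each embryo is added as an
#'   `ml` column.
#' @param minCoverage per-cell total-coverage threshold (default 30).
#' @return a [MethylomeSet].
#' @export
buildPromoterMatrix <- function(callsList, promoters, sampleSheet = NULL,
                                minCoverage = 30) {
  stopifnot(is.list(callsList), length(callsList) > 0L,
            !is.null(names(callsList)), minCoverage >= 0)
  ids <- names(callsList)
  np <- length(promoters)
  meth <- matrix(NA_real_, np, length(ids),
                 dimnames = list(promoters$gene_id, ids))
  cov <- matrix(0L, np, length(ids),
                dimnames = list(promoters$gene_id, ids))
  ml <- numeric(length(ids))
  knownChrom <- as.character(unique(seqnames(promoters)))
  skipped <- 0L
  for (j in seq_along(ids)) {
    calls <- callsList[[j]]
    if (nrow(calls) == 0L) stop("embryo ", ids[j], " has no CpG calls")
    ml[j] <- wholeGenomeML(calls)
    keep <- calls$chrom %in% knownChrom
    skipped <- skipped + sum(!keep)
    calls <- calls[keep, , drop = FALSE]
    if (nrow(calls) == 0L) next
    cpg <- GRanges(calls$chrom, IRanges(calls$pos + 1L, width = 1L))
    hits <- findOverlaps(cpg, promoters, ignore.strand = TRUE)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    beta <- calls$meth[qi] / calls$total[qi]
    nCpg <- tabulate(si, np)
    sumBeta <- unname(rowsum(beta, si, reorder = TRUE))
    sumCov <- unname(rowsum(calls$total[qi], si, reorder = TRUE))
    idx <- sort(unique(si))
    meth[idx, j] <- sumBeta[, 1L] / nCpg[idx]
    cov[idx, j] <- as.integer(sumCov[, 1L])
  }
  if (skipped > 0L)
    message(skipped, " CpG calls on chromosomes absent from the annotation",
            " were skipped")
  meth[cov < minCoverage] <- NA_real_
  cd <- DataFrame(embryo_id = ids, ml = ml, row.names = ids)
  if (!is.null(sampleSheet)) {
    m <- match(ids, sampleSheet$embryo_id)
    if (anyNA(m)) stop("embryos missing from sample sheet: ",
                       paste(ids[is.na(m)], collapse = ", "))
    extra <- sampleSheet[m, setdiff(names(sampleSheet), "embryo_id"),
                         drop = FALSE]
    cd <- cbind(cd, DataFrame(extra, row.names = ids))
  }
  se <- SummarizedExperiment(assays = list(meth = meth, coverage = cov),
                             rowRanges = promoters, colData = cd)
  new("MethylomeSet", se, minCoverage = as.numeric(minCoverage))
}

#' Assemble a MethylomeSet from precomputed matrices
#'
#' Constructor used by the cohort simulator and by callers who already hold
#' a promoter methylation matrix. Cells below `minCoverage` are masked.
#'
#' @param meth promoters x embryos methylation matrix in \[0, 1\].
#' @param coverage matching total-coverage matrix.
#' @param promoters promoter [GenomicRanges::GRanges].
#' @param sampleSheet sample sheet `data.frame` with one row per embryo;
#'   must contain `embryo_id` matching `colnames(meth)`.
#' @param minCoverage per-cell coverage threshold (default 30).
#' @return a [MethylomeSet].
#' @export
MethylomeSet <- function(meth, coverage, promoters, sampleSheet,
                         minCoverage = 30) {
  stopifnot(identical(dim(meth), dim(coverage)),
            nrow(meth) == length(promoters))
  meth[coverage < minCoverage] <- NA_real_
  ids <- colnames(meth)
  m <- match(ids, sampleSheet$embryo_id)
  if (anyNA(m)) stop("embryos missing from sample sheet")
  cd <- DataFrame(sampleSheet[m, , drop = FALSE], row.names = ids)
  se <- SummarizedExperiment(assays = list(meth = meth, coverage = coverage),
                             rowRanges = promoters, colData = cd)
  new("MethylomeSet", se, minCoverage = as.numeric(minCoverage))
}
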