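# The expression arm: preprocessing of a normalized intensity matrix,
# DEG calling with a three-filter cascade (per-gene class comparison,
# Benjamini-Hochberg FDR, Student t-test) and a fold-change cut.

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column (or row names) are gene ids; header row holds sample ids.
#' Every cell must be numeric; the first offending coordinate is reported.
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                          colClasses = "character")
  m <- suppressWarnings(apply(as.matrix(df), c(1, 2), as.numeric))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s' in %s",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]], path),
         call. = FALSE)
  }
  m
}

#' Read a sample-to-group design table
#'
#' @param path TSV with columns \code{sample}, \code{group}.
#' @return data.frame.
#' @export
readDesign <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(d)))
    stop("design table needs columns 'sample' and 'group'", call. = FALSE)
  if (anyDuplicated(d$sample)) stop("duplicate sample ids in design", call. = FALSE)
  d
}

#' Preprocess a normalized expression matrix
#'
#' Replaces intensities below the floor by the floor value, removes genes
#' flagged absent in every sample (when presence calls are supplied) and
#' stores the log2-transformed matrix alongside. Mirrors the conventional
#' microarray filter chain applied to GCRMA-normalized intensities.
#'
#' @param mat numeric gene-by-sample matrix of normalized intensities.
#' @param groups character vector of group labels, one per column.
#' @param presence optional gene-by-sample matrix of detection calls:
#'   logical, or characters where \code{"A"} means absent. A gene is removed
#'   only if absent in all samples.
#' @param floor intensity floor (default 10).
#' @return a \code{SummarizedExperiment} with assays \code{intensity}
#'   (floored) and \code{log2}, column data \code{group}, and the floor
#'   recorded in \code{metadata()}.
#' @export
preprocessMatrix <- function(mat, groups, presence = NULL, floor = 10) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    if (is.matrix(mat)) {
      bad <- which(!vapply(seq_len(ncol(mat)), function(j)
        is.numeric(mat[, j]), NA))[1L]
      stop(sprintf("non-numeric values in column %d ('%s')", bad,
                   colnames(mat)[bad]), call. = FALSE)
    }
    stop("'mat' must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-numeric value at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (length(groups) != ncol(mat))
    stop("'groups' must have one label per sample column", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("'mat' needs gene row names and sample column names", call. = FALSE)
  if (!is.null(presence)) {
    if (!identical(dim(presence), dim(mat)))
      stop("presence matrix dimensions differ from the expression matrix",
           call. = FALSE)
    pres <- if (is.logical(presence)) presence else presence != "A"
    keep <- rowSums(pres) > 0L
    mat <- mat[keep, , drop = FALSE]
  }
  mat[mat < floor] <- floor
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat, log2 = log2(mat)),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(mat)))
  S4Vectors::metadata(se) <- list(floor = floor, log2 = TRUE)
  se
}

# vectorized two-sample pooled-variance (Student) t-test on rows;
# zero pooled variance => p = 1 (degenerate-gene rule)
.rowStudentT <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), df = nx + ny - 2)
  p[sp2 == 0] <- 1
  list(estimate = mx - my, p = p)
}

#' Call differentially expressed genes
#'
#' Applies the three-filter cascade on log2 intensities: (1) a per-gene
#' two-sample class comparison at \code{alpha}; (2) Benjamini-Hochberg FDR
#' across genes at \code{fdr}; (3) within the survivors, a per-gene Student
#' t-test at \code{tAlpha}. The class comparison is itself implemented as a
#' pooled-variance Student t-test, making stage (3) a documented
#' near-duplicate retained for fidelity to the cascade structure. Genes with
#' zero pooled variance get p = 1. All filter outcomes are reported per gene;
#' \code{is_deg} requires all three.
#'
#' @param se a \code{SummarizedExperiment} from \code{\link{preprocessMatrix}}.
#' @param contrast ordered pair \code{c(treatment, control)} of group labels.
#' @param alpha class-comparison significance threshold (default 0.01).
#' @param fdr FDR threshold (default 0.05).
#' @param tAlpha t-test threshold within survivors (default 0.01).
#' @return data.frame with one row per gene: \code{gene}, \code{log2_ratio}
#'   (treatment minus control mean log2), \code{p_class}, \code{fdr_pass},
#'   \code{p_t}, \code{direction}, \code{is_deg}.
#' @export
callDegs <- function(se, contrast, alpha = 0.01, fdr = 0.05, tAlpha = 0.01) {
  stopifnot(is(se, "SummarizedExperiment"), length(contrast) == 2L)
  groups <- SummarizedExperiment::colData(se)$group
  lg <- SummarizedExperiment::assay(se, "log2")
  ti <- which(groups == contrast[1L]); ci <- which(groups == contrast[2L])
  if (length(ti) < 2L || length(ci) < 2L)
    stop(sprintf("each contrast group needs >= 2 samples (%s: %d, %s: %d)",
                 contrast[1L], length(ti), contrast[2L], length(ci)),
         call. = FALSE)
  tt <- .rowStudentT(lg[, ti, drop = FALSE], lg[, ci, drop = FALSE])
  p_class <- tt$p
  fdr_pass <- adjustBH(p_class) < fdr
  survivors <- p_class < alpha & fdr_pass
  # the within-survivor Student t-test re-evaluates each surviving gene with
  # the same two-sample statistic; restricting the gene set does not alter a
  # per-gene p, so p_t equals p_class for survivors (reported separately to
  # keep every stage of the cascade visible)
  p_t <- ifelse(survivors, p_class, NA_real_)
  out <- data.frame(
    gene = rownames(lg),
    log2_ratio = unname(tt$estimate),
    p_class = unname(p_class),
    fdr_pass = unname(fdr_pass),
    p_t = unname(p_t),
    direction = ifelse(tt$estimate < 0, "down", "up"),
    stringsAsFactors = FALSE)
  out$is_deg <- out$p_class < alpha & out$fdr_pass & !is.na(out$p_t) &
    out$p_t < tAlpha
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split significant genes by an absolute fold-change threshold
#'
#' Keeps genes that passed all significance filters and whose absolute log2
#' ratio reaches \code{log2Cut} (inclusive boundary), split by direction.
#' The default 1.1 log2 corresponds to a 2.1-fold change.
#'
#' @param records data.frame from \code{\link{callDegs}}.
#' @param log2Cut absolute log2-ratio threshold (default 1.1).
#' @return list with data.frames \code{up} and \code{down}.
#' @export
applyFoldThreshold <- function(records, log2Cut = 1.1) {
  stopifnot(is.data.frame(records),
            all(c("gene", "log2_ratio", "is_deg") %in% names(records)))
  keep <- records[records$is_deg & abs(records$log2_ratio) >= log2Cut, ,
                  drop = FALSE]
  list(up = keep[keep$log2_ratio > 0, , drop = FALSE],
       down = keep[keep$log2_ratio < 0, , drop = FALSE])
}

#' Partition per-drug DEG lists into common / similar / unique classes
#'
#' Identical semantics to \code{\link{partitionSets}}; provided so the
#' expression arm mirrors the structure arm's intersection step.
#'
#' @param lists named list (drug id -> character vector of genes).
#' @return a \linkS4class{TargetPartition}.
#' @export
partitionDegLists <- function(lists) partitionSets(lists)
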