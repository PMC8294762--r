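#' Annotate binding peaks with gene-model region labels
#'
#' Each peak receives the region label(s) (`five_prime_utr`, `cds`,
#' `three_prime_utr`, `intron`) of every gene-model interval it overlaps by at
#' least one base. Peaks use 0-based half-open (BED) coordinates; gene-model
#' intervals use 1-based inclusive coordinates (GTF-like) and are converted
#' internally. Strand is required to match when both records are stranded; a
#' `.` strand on either side matches anything.
#'
#' Overlap is computed with [GenomicRanges::findOverlaps()] (the `*` strand
#' there has exactly the "match anything" semantics needed).
#'
#' @param peaks data frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open), e.g. from [read_bed()].
#' @param models data frame with columns `gene`, `region`, `chrom`, `start`,
#'   `end`, `strand` (1-based inclusive), e.g. from [read_gene_models()].
#' @return a long data frame of class `peak_annotation` with one row per
#'   (peak, overlapping interval) pair: `peak` (row index into `peaks`),
#'   `gene`, `region`. Peaks with no overlap contribute no rows; the number
#'   of input peaks is kept in attribute `n_peaks`.
#' @export
annotate_peaks <- function(peaks, models) {
  validate_peaks(peaks)
  validate_models(models)
  std <- function(s) ifelse(is.na(s) | s == ".", "*", s)
  gr_p <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L, peaks$end),
                                 strand = std(peaks$strand))
  gr_m <- GenomicRanges::GRanges(models$chrom,
                                 IRanges::IRanges(models$start, models$end),
                                 strand = std(models$strand))
  hits <- GenomicRanges::findOverlaps(gr_p, gr_m)
  out <- data.frame(peak = S4Vectors::queryHits(hits),
                    gene = models$gene[S4Vectors::subjectHits(hits)],
                    region = models$region[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  attr(out, "n_peaks") <- nrow(peaks)
  class(out) <- c("peak_annotation", "data.frame")
  out
}

region_vocabulary <- c("five_prime_utr", "cds", "three_prime_utr", "intron")
mature_regions <- c("five_prime_utr", "cds", "three_prime_utr")

validate_peaks <- function(peaks) {
  if (!is.data.frame(peaks) || !all(c("chrom", "start", "end") %in% names(peaks)))
    stop("peaks must be a data frame with chrom/start/end", call. = FALSE)
  bad <- which(!(peaks$start < peaks$end))
  if (length(bad))
    stop("malformed peak interval (start >= end) at row ", bad[1], call. = FALSE)
  if (is.null(peaks$strand)) peaks$strand <- "."
  invisible(peaks)
}

validate_models <- function(models) {
  need <- c("gene", "region", "chrom", "start", "end", "strand")
  if (!is.data.frame(models) || !all(need %in% names(models)))
    stop("gene models must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!(models$start <= models$end))
  if (length(bad))
    stop("malformed model interval (start > end) at row ", bad[1], call. = FALSE)
  badr <- which(!models$region %in% region_vocabulary)
  if (length(badr))
    stop("unknown region label '", models$region[badr[1]], "' at row ", badr[1],
         call. = FALSE)
  invisible(models)
}

#' Select target genes from annotated peaks
#'
#' `mature_only` keeps genes having at least one peak overlapping the mature
#' mRNA (5'UTR, CDS or 3'UTR) — the filter used for RBPs that predominantly
#' bind intronic pre-mRNA, so that only mature-transcript binding counts.
#' `any` keeps every gene with any overlapping peak (the appropriate mode for
#' target lists that already arrive as gene identifiers).
#'
#' @param annotation a `peak_annotation` from [annotate_peaks()].
#' @param mode `"mature_only"` or `"any"`.
#' @return character vector of unique target gene identifiers.
#' @export
select_target_genes <- function(annotation, mode = c("mature_only", "any")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(annotation))
  if (nrow(annotation) == 0) return(character(0))
  keep <- if (mode == "mature_only") annotation$region %in% mature_regions else TRUE
  sort(unique(annotation$gene[keep & !is.na(annotation$gene)]))
}

#' Expression-matched target and non-target z-score vectors
#'
#' Restricts a differential table to genes whose log10 base mean lies
#' strictly inside the window (`lo < log10(baseMean) < hi`) and splits the
#' windowed genes into targets and non-targets. The shared window removes the
#' abundance confounding between target and non-target sets; boundary values
#' are excluded on both sides.
#'
#' @param de a `de_table` containing `baseMean` and `z`.
#' @param targets character vector of target gene identifiers.
#' @param window numeric pair `c(lo, hi)` on the log10 base-mean scale
#'   (default `c(2.5, 4.25)`).
#' @return list with `target_z`, `nontarget_z`, `target_genes`,
#'   `nontarget_genes`.
#' @export
expression_matched_sets <- function(de, targets, window = c(2.5, 4.25)) {
  stopifnot(is.data.frame(de), all(c("gene", "baseMean", "z") %in% names(de)))
  check_pair(window, "window")
  if (window[1] >= window[2])
    stop("invalid configuration field 'window': lo must be < hi", call. = FALSE)
  lb <- suppressWarnings(log10(de$baseMean))
  in_win <- is.finite(lb) & lb > window[1] & lb < window[2]
  is_t <- de$gene %in% targets
  tz <- de$z[in_win & is_t]; nz <- de$z[in_win & !is_t]
  if (length(tz) == 0)
    stop("analysis error: no target genes inside the expression window",
         call. = FALSE)
  if (length(nz) == 0)
    stop("analysis error: no non-target genes inside the expression window",
         call. = FALSE)
  list(target_z = tz, nontarget_z = nz,
       target_genes = de$gene[in_win & is_t],
       nontarget_genes = de$gene[in_win & !is_t])
}

#' Two-sample Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' D is the supremum over the pooled sample points of the absolute difference
#' between the two ECDFs (ties are handled by evaluating both ECDFs at the
#' pooled sorted values). The p-value uses the asymptotic Kolmogorov
#' distribution with effective sample size `n_eff = nx * ny / (nx + ny)`:
#' `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 n_eff D^2)`.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `D`, `p`, `n_x`, `n_y`.
#' @examples
#' ks_two_sample(c(0, 0, 0), c(1, 1, 1))  # D = 1
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    stop("domain error: both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("domain error: samples must be finite", call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  Fx <- findInterval(pooled, sort(x)) / length(x)
  Fy <- findInterval(pooled, sort(y)) / length(y)
  D <- max(abs(Fx - Fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  list(D = D, p = ks_asymptotic_pvalue(sqrt(ne) * D),
       n_x = length(x), n_y = length(y))
}

# survival function of the Kolmogorov distribution, Q(lambda)
ks_asymptotic_pvalue <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 1e-300), 1)
}

#' Cumulative-distribution shift of target vs non-target z-scores
#'
#' The target-set analysis behind cumulative frequency plots: target and
#' non-target genes are expression-matched through the base-mean window, a
#' two-sample KS test compares their signed z-score distributions, and a
#' direction is called when significant — `down` (target ECDF shifted left;
#' targets translationally depleted) when the target median z is below the
#' non-target median, `up` for a rightward shift, `none` otherwise.
#'
#' @param de a `de_table` containing `baseMean` and `z`.
#' @param targets character vector of target gene identifiers.
#' @param window log10 base-mean window, see [expression_matched_sets()].
#' @param alpha significance level gating the direction call (default 0.05).
#' @return a list of class `shift_result`: `D`, `p`, `direction`,
#'   `n_targets`, `n_nontargets`, `median_z_diff`, and `curves` (a data frame
#'   of both step ECDFs evaluated on the pooled z grid: `z`, `F_target`,
#'   `F_nontarget`).
#' @export
cumulative_shift <- function(de, targets, window = c(2.5, 4.25), alpha = 0.05) {
  sets <- expression_matched_sets(de, targets, window)
  ks <- ks_two_sample(sets$target_z, sets$nontarget_z)
  med_diff <- median(sets$target_z) - median(sets$nontarget_z)
  direction <- "none"
  if (ks$p < alpha && med_diff < 0) direction <- "down"
  if (ks$p < alpha && med_diff > 0) direction <- "up"
  grid <- sort(unique(c(sets$target_z, sets$nontarget_z)))
  curves <- data.frame(
    z = grid,
    F_target = findInterval(grid, sort(sets$target_z)) / length(sets$target_z),
    F_nontarget = findInterval(grid, sort(sets$nontarget_z)) / length(sets$nontarget_z))
  structure(list(D = ks$D, p = ks$p, direction = direction,
                 n_targets = length(sets$target_z),
                 n_nontargets = length(sets$nontarget_z),
                 median_z_diff = med_diff, curves = curves),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat("cumulative shift: D =", format(x$D, digits = 3),
      ", p =", format(x$p, digits = 3), ", direction =", x$direction, "\n")
  cat("  targets:", x$n_targets, " non-targets:", x$n_nontargets,
      " median z difference:", format(x$median_z_diff, digits = 3), "\n")
  invisible(x)
}
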