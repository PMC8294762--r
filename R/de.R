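#' Median-of-ratios size factors
#'
#' DESeq2-style normalization: for each gene expressed in every sample, form
#' the ratio of each sample's count to the gene's geometric mean across
#' samples; a sample's size factor is the median of its ratios. Factors are
#' then rescaled to have geometric mean 1.
#'
#' @param x a [count_matrix()] or a plain counts matrix.
#' @return named numeric vector of per-sample size factors (geometric mean 1).
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3, dimnames = list(paste0("g", 1:3), c("a", "b")))
#' estimate_size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (!is.matrix(counts)) stop("expected a count matrix", call. = FALSE)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use))
    stop("normalization error: no gene has nonzero counts in all samples",
         call. = FALSE)
  lg <- log(counts[use, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- exp(apply(lg - loggeo, 2, median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' A self-contained stand-in for a full shrinkage-based NB analysis: counts
#' are normalized by median-of-ratios size factors, per-gene dispersion is
#' estimated by method of moments from within-group variances (floored at
#' `dispersion_floor`), the log2 fold change is
#' `log2((mu_mut + pc) / (mu_ctl + pc))` with pseudocount `pc`, and its
#' standard error comes from the delta method under the NB variance
#' \eqn{\mu + \alpha\mu^2}. Two-sided p-values use a t reference with
#' `n1 + n2 - 2` degrees of freedom — a small-sample correction to the Wald
#' normal approximation that keeps null p-values uniform at the group sizes
#' this package targets (4-5 per genotype). The reported `stat` is the signed
#' standard-normal quantile of that p-value, so `p` and `stat` satisfy
#' `p == 2 * pnorm(-abs(stat))` exactly.
#'
#' There is deliberately no dispersion shrinkage, outlier (Cook's) filtering
#' or fold-change moderation here; the test is property-calibrated rather
#' than tuned to match any specific external implementation.
#'
#' @param x a [count_matrix()] with at least 2 samples per group.
#' @param pseudocount pseudocount added to group means for the fold change
#'   (default 0.5; guards zero-count groups).
#' @param dispersion_floor lower bound for the method-of-moments dispersion.
#' @return a `de_table` data frame with columns `gene`, `baseMean`, `log2FC`,
#'   `SE`, `stat`, `p`, `padj` (Benjamini-Hochberg).
#' @seealso [translatome_de()] to append signed z-scores.
#' @export
nb_wald_test <- function(x, pseudocount = 0.5, dispersion_floor = 1e-8) {
  stopifnot(inherits(x, "count_matrix"))
  grp <- x$design$group
  nc <- sum(grp == "control"); nm <- sum(grp == "mutant")
  if (nc < 2 || nm < 2)
    stop("need >= 2 samples per group for testing", call. = FALSE)
  sf <- estimate_size_factors(x)
  if (any(colSums(x$counts) == 0))
    stop("a sample library is all zero", call. = FALSE)
  N <- sweep(x$counts, 2, sf, "/")
  ic <- grp == "control"; im <- grp == "mutant"
  mc <- rowMeans(N[, ic, drop = FALSE]); mm <- rowMeans(N[, im, drop = FALSE])
  vc <- apply(N[, ic, drop = FALSE], 1, var)
  vm <- apply(N[, im, drop = FALSE], 1, var)
  # normalized counts have variance mu/s_j + alpha*mu^2; pool excess variance
  # over both groups for the method-of-moments dispersion
  inv_sc <- mean(1 / sf[ic]); inv_sm <- mean(1 / sf[im])
  num <- (nc - 1) * (vc - mc * inv_sc) + (nm - 1) * (vm - mm * inv_sm)
  den <- (nc - 1) * mc^2 + (nm - 1) * mm^2
  alpha <- pmax(ifelse(den > 0, num / den, dispersion_floor), dispersion_floor)
  l2fc <- log2((mm + pseudocount) / (mc + pseudocount))
  var_mc <- (mc * inv_sc + alpha * mc^2) / nc
  var_mm <- (mm * inv_sm + alpha * mm^2) / nm
  se <- sqrt(var_mc / (mc + pseudocount)^2 + var_mm / (mm + pseudocount)^2) / log(2)
  w <- ifelse(se > 0, l2fc / se, 0)
  p <- 2 * pt(-abs(w), df = nc + nm - 2)
  p <- pmin(pmax(p, 1e-300), 1)
  dead <- mc == 0 & mm == 0
  p[dead] <- 1
  stat <- sign(l2fc) * qnorm(p / 2, lower.tail = FALSE)
  stat[dead] <- 0
  se[dead] <- NA_real_
  res <- data.frame(gene = rownames(x$counts), baseMean = rowMeans(N),
                    log2FC = l2fc, SE = se, stat = stat, p = p,
                    padj = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("de_table", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper around [stats::p.adjust()] with
#' `method = "BH"`); an empty input returns an empty vector.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, monotone non-decreasing in p rank.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Convert a two-sided p-value into a signed z-score
#'
#' `z = sign(log2fc) * qnorm(1 - p / 2)`: the nominal two-sided p-value is
#' mapped to a standard-normal quantile and given the sign of the log2 fold
#' change. p-values below 1e-300 are clipped before inversion to avoid
#' infinities.
#'
#' @param p two-sided p-value(s) in (0, 1].
#' @param log2fc log2 fold change(s) supplying the sign (0 gives z = 0).
#' @return signed z-score(s).
#' @examples
#' pvalue_to_z(0.05, 1)   #  1.96
#' pvalue_to_z(0.05, -2)  # -1.96
#' pvalue_to_z(1, 3)      #  0
#' @export
pvalue_to_z <- function(p, log2fc) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("domain error: p must lie in (0, 1]", call. = FALSE)
  stopifnot(length(p) == length(log2fc) || length(log2fc) == 1L)
  sign(log2fc) * qnorm(pmax(p, 1e-300) / 2, lower.tail = FALSE)
}

#' Differential translatome table with signed z-scores
#'
#' Runs [nb_wald_test()] and appends the signed z-score column
#' (`z = sign(log2FC) * qnorm(1 - p/2)`, from the nominal p-value).
#'
#' @inheritParams nb_wald_test
#' @return a `de_table` with columns `gene`, `baseMean`, `log2FC`, `SE`,
#'   `stat`, `p`, `padj`, `z`.
#' @export
translatome_de <- function(x, pseudocount = 0.5, dispersion_floor = 1e-8) {
  de <- nb_wald_test(x, pseudocount, dispersion_floor)
  de$z <- pvalue_to_z(de$p, de$log2FC)
  de
}

#' Compare signed z-scores between two contrasts
#'
#' Restricts to shared genes, computes the Pearson correlation of the two
#' z-score vectors, and labels each gene by significance pattern: `both`
#' (padj < alpha in both contrasts), `A_only`/`B_only` (padj < alpha in one
#' and >= alpha in the other) or `neither`. Equality with alpha resolves to
#' the non-significant side.
#'
#' @param a,b `de_table`s (from [translatome_de()], i.e. containing `z`).
#' @param alpha FDR threshold defining condition-specific genes (default 0.1).
#' @return a list of class `contrast_comparison`: `table` (gene, z_a, z_b,
#'   padj_a, padj_b, class), `pearson_r`, `n_shared`, `class_counts`, `alpha`.
#' @export
compare_contrasts <- function(a, b, alpha = 0.1) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (!"z" %in% names(a) || !"z" %in% names(b))
    stop("both tables must contain a z column (use translatome_de)", call. = FALSE)
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < 3)
    stop("correlation undefined: fewer than 3 shared genes", call. = FALSE)
  ia <- match(shared, a$gene); ib <- match(shared, b$gene)
  sig_a <- a$padj[ia] < alpha; sig_b <- b$padj[ib] < alpha
  cls <- ifelse(sig_a & sig_b, "both",
                ifelse(sig_a, "A_only", ifelse(sig_b, "B_only", "neither")))
  tab <- data.frame(gene = shared, z_a = a$z[ia], z_b = b$z[ib],
                    padj_a = a$padj[ia], padj_b = b$padj[ib], class = cls,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, pearson_r = cor(tab$z_a, tab$z_b),
                 n_shared = length(shared),
                 class_counts = table(factor(cls, levels = c("both", "A_only",
                                                             "B_only", "neither"))),
                 alpha = alpha),
            class = "contrast_comparison")
}

#' @export
print.contrast_comparison <- function(x, ...) {
  cat("contrast comparison over", x$n_shared, "shared genes\n")
  cat("  Pearson r =", format(x$pearson_r, digits = 3), "\n")
  cc <- x$class_counts
  cat("  classes (alpha =", x$alpha, "): both =", cc[["both"]],
      ", A_only =", cc[["A_only"]], ", B_only =", cc[["B_only"]],
      ", neither =", cc[["neither"]], "\n")
  invisible(x)
}
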