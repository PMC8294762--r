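#' Configuration for the RiboTag-style count simulator
#'
#' Defines a two-genotype (control vs mutant) negative-binomial count
#' experiment with a planted fold change on a flagged subset of "target"
#' genes. Defaults mirror the study design the package is built around:
#' litter-matched groups of 4-5 embryos per genotype, moderate biological
#' dispersion, and per-gene abundances whose log10 base mean is centred
#' inside the expression window used downstream (2.5-4.25).
#'
#' The negative binomial is parameterized by its mean \eqn{\mu} and dispersion
#' \eqn{\alpha}, with variance \eqn{\mu + \alpha \mu^2}.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per genotype; a scalar or a pair
#'   `c(control, mutant)` (e.g. `c(5, 5)` or `c(4, 4)`).
#' @param mean_log10_basemean,sd_log10_basemean log10-normal abundance model.
#' @param dispersion NB dispersion \eqn{\alpha} (variance \eqn{\mu + \alpha\mu^2}).
#' @param target_fraction fraction of genes flagged as RBP targets.
#' @param target_log2fc planted log2 fold change applied to targets in the
#'   mutant group (negative = depletion).
#' @param size_factor_range range of per-sample library size factors
#'   (drawn uniformly).
#' @param seed integer seed; the generator is a pure function of config + seed.
#' @return a list of class `sim_count_config`.
#' @seealso [simulate_counts()]
#' @export
sim_count_config <- function(n_genes = 2000L, n_per_group = c(5L, 5L),
                             mean_log10_basemean = 3, sd_log10_basemean = 0.7,
                             dispersion = 0.05, target_fraction = 0.2,
                             target_log2fc = -0.5,
                             size_factor_range = c(0.8, 1.25), seed = 1L) {
  check_scalar(n_genes, "n_genes", positive = TRUE, integerish = TRUE)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (!is.numeric(n_per_group) || length(n_per_group) != 2L ||
      any(n_per_group < 1) || any(abs(n_per_group - round(n_per_group)) > 1e-8))
    stop("invalid configuration field 'n_per_group': must be one or two positive integers",
         call. = FALSE)
  check_scalar(mean_log10_basemean, "mean_log10_basemean")
  check_scalar(sd_log10_basemean, "sd_log10_basemean", positive = TRUE)
  check_scalar(dispersion, "dispersion", positive = TRUE)
  check_scalar(target_fraction, "target_fraction", min = 0, max = 1)
  check_scalar(target_log2fc, "target_log2fc")
  check_pair(size_factor_range, "size_factor_range", positive = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(round(n_per_group)),
                 mean_log10_basemean = mean_log10_basemean,
                 sd_log10_basemean = sd_log10_basemean,
                 dispersion = dispersion, target_fraction = target_fraction,
                 target_log2fc = target_log2fc,
                 size_factor_range = size_factor_range,
                 seed = as.integer(seed)),
            class = "sim_count_config")
}

#' Simulate a RiboTag-style count matrix with planted target depletion
#'
#' Draws per-gene abundances from a log10-normal, flags
#' `round(target_fraction * n_genes)` genes as targets, multiplies their mean
#' in the mutant group by `2^target_log2fc`, applies per-sample size factors
#' and samples negative-binomial counts.
#'
#' @param cfg a [sim_count_config()].
#' @return a list with components:
#'   \describe{
#'     \item{counts}{a [count_matrix()] (genes x samples, with design).}
#'     \item{ground_truth}{data frame with per-gene `gene`, `base_mu`
#'       (control-group mean), `true_log2fc` and `is_target`; the per-sample
#'       size factors are attached as attribute `size_factors`.}
#'   }
#' @examples
#' sim <- simulate_counts(sim_count_config(n_genes = 50, n_per_group = 3, seed = 7))
#' dim(sim$counts$counts)
#' table(sim$ground_truth$is_target)
#' @export
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "sim_count_config")) cfg <- do.call(sim_count_config, cfg)
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  nc <- cfg$n_per_group[1]; nm <- cfg$n_per_group[2]
  genes <- sprintf("gene%05d", seq_len(ng))
  mu <- 10^rnorm(ng, cfg$mean_log10_basemean, cfg$sd_log10_basemean)
  n_target <- round(cfg$target_fraction * ng)
  is_target <- logical(ng)
  if (n_target > 0) is_target[sample.int(ng, n_target)] <- TRUE
  true_lfc <- ifelse(is_target, cfg$target_log2fc, 0)
  sf <- runif(nc + nm, cfg$size_factor_range[1], cfg$size_factor_range[2])
  group <- rep(c("control", "mutant"), c(nc, nm))
  samples <- paste0(substr(group, 1, 3), "_", c(seq_len(nc), seq_len(nm)))
  counts <- matrix(0L, ng, nc + nm, dimnames = list(genes, samples))
  for (j in seq_len(nc + nm)) {
    m <- if (group[j] == "mutant") mu * 2^true_lfc else mu
    counts[, j] <- as.integer(rnbinom(ng, mu = sf[j] * m, size = 1 / cfg$dispersion))
  }
  truth <- data.frame(gene = genes, base_mu = mu, true_log2fc = true_lfc,
                      is_target = is_target, stringsAsFactors = FALSE)
  attr(truth, "size_factors") <- stats::setNames(sf, samples)
  list(counts = count_matrix(counts, data.frame(sample = samples, group = group,
                                                stringsAsFactors = FALSE)),
       ground_truth = truth)
}

#' Count matrix with sample design
#'
#' Container for a gene x sample non-negative integer matrix plus a design
#' table labelling each sample `control` or `mutant`.
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param design data frame with columns `sample` and `group`
#'   (levels `control`/`mutant`), one row per column of `counts`.
#' @return a list of class `count_matrix` with elements `counts` and `design`.
#' @export
count_matrix <- function(counts, design) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene rownames", call. = FALSE)
  if (!is.data.frame(design) || !all(c("sample", "group") %in% names(design)))
    stop("design must be a data frame with columns 'sample' and 'group'",
         call. = FALSE)
  if (nrow(design) != ncol(counts))
    stop("design must have one row per sample column", call. = FALSE)
  if (!all(design$group %in% c("control", "mutant")))
    stop("design group labels must be 'control' or 'mutant'", call. = FALSE)
  if (!is.null(colnames(counts)) && !identical(colnames(counts), design$sample))
    design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  if (anyNA(design$sample))
    stop("design samples must match count matrix columns", call. = FALSE)
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      sum(x$design$group == "control"), "control /",
      sum(x$design$group == "mutant"), "mutant )\n")
  invisible(x)
}
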