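test_that("peak annotation honours half-open coordinates and strand rules", {
  models <- data.frame(gene = "geneA", region = "cds", chrom = "chr1",
                       start = 121, end = 200, strand = "+",
                       stringsAsFactors = FALSE)  # CDS [120,200) half-open
  hit <- data.frame(chrom = "chr1", start = 100, end = 150, strand = "+",
                    stringsAsFactors = FALSE)
  ann <- annotate_peaks(hit, models)
  expect_equal(ann$region, "cds")
  # peak [100,120) touches but does not overlap CDS [120,200)
  miss <- data.frame(chrom = "chr1", start = 100, end = 120, strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(annotate_peaks(miss, models)), 0)
  # strand mismatch blocks; '.' on either side matches
  minus <- hit; minus$strand <- "-"
  expect_equal(nrow(annotate_peaks(minus, models)), 0)
  dot <- hit; dot$strand <- "."
  expect_equal(nrow(annotate_peaks(dot, models)), 1)
  bad <- data.frame(chrom = "chr1", start = 150, end = 100, strand = "+")
  expect_error(annotate_peaks(bad, models), "row 1")
})

test_that("peak annotation agrees with a brute-force all-pairs oracle", {
  set.seed(301)
  for (rep in 1:20) {
    fx <- random_peak_fixture(n_peaks = 20, n_genes = 10)
    got <- annotate_peaks(fx$peaks, fx$models)
    want <- brute_annotate(fx$peaks, fx$models)
    key <- function(d) if (is.null(d) || nrow(d) == 0) character(0) else
      sort(paste(d$peak, d$gene, d$region))
    expect_identical(key(got), key(want))
  }
})

test_that("target selection filters intronic-only genes in mature_only mode", {
  ann <- data.frame(peak = 1:3,
                    gene = c("gA", "gA", "gB"),
                    region = c("intron", "intron", "cds"),
                    stringsAsFactors = FALSE)
  class(ann) <- c("peak_annotation", "data.frame")
  expect_equal(select_target_genes(ann, "mature_only"), "gB")
  expect_equal(select_target_genes(ann, "any"), c("gA", "gB"))
  empty <- ann[0, ]
  expect_equal(select_target_genes(empty, "mature_only"), character(0))
})

test_that("expression matching applies the strict base-mean window", {
  de <- data.frame(gene = c("t1", "t2", "n1", "n2", "n3"),
                   baseMean = 10^c(3.0, 2.0, 3.0, 2.5, 4.25),
                   z = c(-2, -3, 0.5, 1, 2))
  sets <- expression_matched_sets(de, targets = c("t1", "t2"))
  expect_equal(sets$target_z, -2)            # t2 at log10 2.0 excluded
  expect_equal(sets$nontarget_z, 0.5)        # boundaries 2.5 / 4.25 excluded
  expect_error(expression_matched_sets(de, targets = character(0)),
               "analysis error")
  expect_error(expression_matched_sets(de, targets = de$gene),
               "analysis error")
  expect_error(expression_matched_sets(de, c("t1"), window = c(4, 3)), "window")
})

test_that("KS statistic matches pooled-grid evaluation and stats::ks.test", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 3))$D, 0.5)
  set.seed(77)
  for (i in 1:25) {
    x <- sample(rnorm(30), sample(3:30, 1), replace = TRUE)
    y <- sample(c(rnorm(20), x), sample(3:30, 1), replace = TRUE)  # force ties
    got <- ks_two_sample(x, y)
    expect_equal(got$D, brute_ks_D(x, y), tolerance = 1e-12)
  }
  # asymptotic p agrees with ks.test(exact = FALSE) on tie-free samples
  set.seed(78)
  x <- rnorm(200); y <- rnorm(300, 0.2)
  got <- ks_two_sample(x, y)
  ref <- stats::ks.test(x, y, exact = FALSE)
  expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  expect_error(ks_two_sample(numeric(0), 1), "domain error")
})

test_that("KS D is invariant under common strictly monotone transforms", {
  set.seed(90)
  x <- rnorm(50); y <- rnorm(60, 0.5)
  d0 <- ks_two_sample(x, y)$D
  expect_equal(ks_two_sample(exp(x), exp(y))$D, d0)
  expect_equal(ks_two_sample(x^3, y^3)$D, d0)
  expect_equal(ks_two_sample(-x, -y)$D, d0)  # reversal preserves sup distance
})

test_that("cumulative shift detects planted depletion and stays quiet under the null", {
  run_shift <- function(delta, seed) {
    sim <- simulate_counts(sim_count_config(n_genes = 2000, n_per_group = 5,
                                            dispersion = 0.05,
                                            target_fraction = 0.2,
                                            target_log2fc = delta, seed = seed))
    de <- translatome_de(sim$counts)
    targets <- sim$ground_truth$gene[sim$ground_truth$is_target]
    cumulative_shift(de, targets)
  }
  res <- run_shift(-1, 101)
  expect_equal(res$direction, "down")
  expect_lt(res$p, 0.05)
  expect_lt(res$median_z_diff, 0)
  null <- run_shift(0, 102)
  expect_lt(null$D, 0.12)
  # identical target and non-target z distributions give D = 0
  de <- data.frame(gene = paste0("g", 1:40), baseMean = rep(1000, 40),
                   z = rep(c(-1, 0, 1, 2), 10))
  flat <- cumulative_shift(de, targets = paste0("g", 1:20))
  expect_equal(flat$D, 0)
  expect_equal(flat$direction, "none")
  # ECDF curves rise from 0 to 1 monotonically
  expect_true(all(diff(res$curves$F_target) >= 0))
  expect_equal(max(res$curves$F_target), 1)
  expect_equal(max(res$curves$F_nontarget), 1)
})

test_that("expression matching removes abundance confounding", {
  # depletion planted only above the window: after windowing no shift remains
  set.seed(55)
  n <- 1500
  high <- rep(c(TRUE, FALSE), length.out = n)
  bm <- ifelse(high, 10^4.6, 10^3)
  de <- data.frame(gene = paste0("g", 1:n), baseMean = bm,
                   z = rnorm(n) + ifelse(high, -2, 0))
  # target set: every shifted high-abundance gene plus unshifted in-window genes
  targets <- c(paste0("g", which(high)), paste0("g", which(!high)[1:150]))
  res <- cumulative_shift(de, targets, window = c(2.5, 4.25))
  expect_equal(res$direction, "none")
})
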