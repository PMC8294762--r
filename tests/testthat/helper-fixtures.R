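# shared fixtures built in code

# small count matrix with prescribed group means (exact integer counts)
fixed_counts <- function(mc, mm, n = 3L) {
  ng <- length(mc)
  counts <- cbind(matrix(rep(mc, n), ng), matrix(rep(mm, n), ng))
  mode(counts) <- "integer"
  rownames(counts) <- sprintf("g%03d", seq_len(ng))
  colnames(counts) <- c(paste0("c", 1:n), paste0("m", 1:n))
  count_matrix(counts, data.frame(sample = colnames(counts),
                                  group = rep(c("control", "mutant"), each = n)))
}

# rasterized disk mask in an n x n frame
disk_mask <- function(r_px, n = 2 * ceiling(r_px) + 9, center = (n + 1) / 2) {
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - center)^2 + (j - center)^2 <= r_px^2)
}

# brute-force two-sample KS D: evaluate both ECDFs at every pooled point
brute_ks_D <- function(x, y) {
  pooled <- sort(c(x, y))
  Fx <- vapply(pooled, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(pooled, function(v) mean(y <= v), numeric(1))
  max(abs(Fx - Fy))
}

# brute-force half-open interval overlap with strand rule
brute_annotate <- function(peaks, models) {
  out <- NULL
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(models))) {
    if (peaks$chrom[i] != models$chrom[j]) next
    ps <- peaks$start[i]; pe <- peaks$end[i]                # 0-based half-open
    ms <- models$start[j] - 1L; me <- models$end[j]         # to half-open
    if (max(ps, ms) >= min(pe, me)) next
    s1 <- peaks$strand[i]; s2 <- models$strand[j]
    if (s1 != "." && s2 != "." && s1 != s2) next
    out <- rbind(out, data.frame(peak = i, gene = models$gene[j],
                                 region = models$region[j],
                                 stringsAsFactors = FALSE))
  }
  out
}

# random peak/model fixture on a toy genome
random_peak_fixture <- function(n_peaks = 20, n_genes = 10) {
  chroms <- c("chr1", "chr2")
  strands <- c("+", "-", ".")
  regions <- c("five_prime_utr", "cds", "three_prime_utr", "intron")
  models <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    k <- sample(1:3, 1)
    st <- sort(sample(1:500, k))
    data.frame(gene = paste0("gene", g), region = sample(regions, k, TRUE),
               chrom = sample(chroms, 1), start = st,
               end = st + sample(5:80, k, TRUE),
               strand = sample(strands, 1), stringsAsFactors = FALSE)
  }))
  peaks <- data.frame(chrom = sample(chroms, n_peaks, TRUE),
                      start = sample(0:550, n_peaks, TRUE),
                      strand = sample(strands, n_peaks, TRUE),
                      stringsAsFactors = FALSE)
  peaks$end <- peaks$start + sample(5:60, n_peaks, TRUE)
  list(peaks = peaks, models = models)
}
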