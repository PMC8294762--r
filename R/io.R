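# TSV / BED / TIFF input-output
#
# Conventions: BED is 0-based half-open; gene-model tables are 1-based
# inclusive (GTF-like) and converted on use; TIFF images are written as
# 32-bit multi-page files in [0, 1] with a sidecar JSON recording the pixel
# size and the intensity scale.

#' Read a counts TSV (plus design) into a count matrix
#'
#' The counts file is tab-separated with a header row; the first column holds
#' gene identifiers, the remaining columns one sample each. The design file
#' has columns `sample` and `group` (`control`/`mutant`).
#'
#' @param path counts TSV path.
#' @param design_path design TSV path.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, design_path) {
  raw <- tryCatch(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("parse error reading '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("parse error: '", path, "' holds no count data", call. = FALSE)
  genes <- as.character(raw[[1]])
  dup <- which(duplicated(genes))
  if (length(dup))
    stop("parse error: duplicate gene id '", genes[dup[1]], "' at row ", dup[1],
         call. = FALSE)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!apply(raw[, -1, drop = FALSE], 1,
                        function(r) all(grepl("^\\s*-?\\d+\\s*$", r))))
    stop("parse error: non-integer count at row ", bad[1], call. = FALSE)
  }
  if (any(abs(mat - round(mat)) > 1e-8)) {
    bad <- which(apply(abs(mat - round(mat)) > 1e-8, 1, any))
    stop("parse error: non-integer count at row ", bad[1], call. = FALSE)
  }
  if (any(mat < 0)) {
    bad <- which(apply(mat < 0, 1, any))
    stop("parse error: negative count at row ", bad[1], call. = FALSE)
  }
  rownames(mat) <- genes
  mode(mat) <- "integer"
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  count_matrix(mat, design)
}

#' Write a data frame or count matrix as TSV
#'
#' Tab-separated, no quoting; a `count_matrix` is written with its gene
#' column first (round-tripping through [read_counts()] losslessly).
#'
#' @param obj data frame, matrix, or [count_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table <- function(obj, path) {
  if (inherits(obj, "count_matrix")) obj <- obj$counts
  if (is.matrix(obj))
    obj <- data.frame(gene = rownames(obj), obj, check.names = FALSE,
                      stringsAsFactors = FALSE)
  write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of binding peaks
#'
#' BED3-BED6; coordinates are kept 0-based half-open. Missing strand becomes
#' `"."`.
#'
#' @param path BED path.
#' @return data frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  raw <- tryCatch(read.delim(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("parse error reading '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  if (ncol(raw) < 3)
    stop("parse error: BED needs at least 3 columns", call. = FALSE)
  peaks <- data.frame(chrom = as.character(raw[[1]]),
                      start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
                      name = if (ncol(raw) >= 4) as.character(raw[[4]]) else ".",
                      score = if (ncol(raw) >= 5) raw[[5]] else 0,
                      strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else ".",
                      stringsAsFactors = FALSE)
  bad <- which(!(peaks$start < peaks$end))
  if (length(bad))
    stop("parse error: start >= end at line ", bad[1], call. = FALSE)
  if (any(peaks$start < 0))
    stop("parse error: negative coordinate at line ",
         which(peaks$start < 0)[1], call. = FALSE)
  peaks
}

#' Write peaks as BED6
#' @param peaks data frame with chrom/start/end (0-based half-open) and
#'   optional name/score/strand.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    peaks$name %||% ".", peaks$score %||% 0,
                    peaks$strand %||% ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated with header `gene, region, chrom, start, end, strand`;
#' coordinates 1-based inclusive (converted to half-open internally by the
#' annotation step). Region labels must be `five_prime_utr`, `cds`,
#' `three_prime_utr` or `intron`.
#'
#' @param path TSV path.
#' @return validated data frame.
#' @export
read_gene_models <- function(path) {
  models <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                     error = function(e)
                       stop("parse error reading '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  validate_models(models)
  models
}

#' Write / read an image raster as multi-page TIFF with sidecar metadata
#'
#' Channels are written as 32-bit pages scaled into `[0, 1]`; the sidecar
#' `<path>.meta.json` records the channel names, pixel size and the intensity
#' scale so that [read_raster()] restores physical intensities (to 32-bit
#' float precision).
#'
#' @param raster an [image_raster()].
#' @param path TIFF path.
#' @return the path, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "image_raster"))
  scale <- max(1e-12, max(vapply(raster$channels, max, numeric(1))))
  tiff::writeTIFF(lapply(raster$channels, function(m) m / scale), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(channels = names(raster$channels),
                            pixel_size_um = raster$pixel_size_um,
                            intensity_scale = scale),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata '", meta_path, "'", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) p * meta$intensity_scale)
  names(channels) <- meta$channels
  image_raster(channels, meta$pixel_size_um)
}
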