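#' Chromosome map
#'
#' A chromosome map fixes the genome frame for every downstream step: the
#' ordered chromosomes, their lengths, and the diploid pair count. The female
#' mouse frame used throughout is 20 homolog pairs (19 autosomes + X), i.e.
#' 40 single-chromatid homologs in a nonreplicated (2n2c) somatic genome.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length_bp Integer vector of chromosome lengths (bp), same order.
#' @return An object of class `chrom_map`: a data.frame with columns
#'   `chrom` and `length_bp`, plus attributes `n_pairs` and `n_chromatids`.
#' @examples
#' cm <- chromosome_map(c("chr1", "chr2"), c(2e7, 1.5e7))
#' cm
#' @export
chromosome_map <- function(chrom, length_bp) {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  if (length(chrom) == 0L) stop("chromosome map needs at least one chromosome")
  if (length(chrom) != length(length_bp)) {
    stop("`chrom` and `length_bp` must have equal length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length_bp)) || any(length_bp < 1)) {
    stop("chromosome lengths must be strictly positive")
  }
  map <- data.frame(chrom = chrom, length_bp = length_bp,
                    stringsAsFactors = FALSE)
  structure(map,
            n_pairs = length(chrom),
            n_chromatids = 2L * length(chrom),
            class = c("chrom_map", "data.frame"))
}

#' @export
print.chrom_map <- function(x, ...) {
  cat(sprintf("chromosome map: %d pairs (%d chromatids), %.1f Mb total\n",
              attr(x, "n_pairs"), attr(x, "n_chromatids"),
              sum(x$length_bp) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 25L), row.names = FALSE)
  invisible(x)
}

#' Mouse (GRCm38) chromosome map
#'
#' The 19 autosomes plus X of the mm10/GRCm38 assembly; chromosome Y is
#' excluded, matching the female 20-pair frame the segregation analysis
#' assumes.
#'
#' @return A [chromosome_map()] with 20 entries.
#' @export
mouse_chrom_map <- function() {
  path <- system.file("extdata", "mouse_chrom_lengths_grcm38.tsv",
                      package = "haploidtrace", mustWork = TRUE)
  read_chrom_map(path)
}

#' Read / write a chromosome map as TSV
#'
#' Plain two-column TSV with header `chrom\tlength_bp`.
#'
#' @param path File path.
#' @return `read_chrom_map()` returns a [chromosome_map()].
#' @export
read_chrom_map <- function(path) {
  if (!file.exists(path)) stop("chromosome map file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length_bp") %in% names(tab))) {
    stop("chromosome map TSV must have columns 'chrom' and 'length_bp'")
  }
  chromosome_map(tab$chrom, tab$length_bp)
}

#' @param map A [chromosome_map()].
#' @rdname read_chrom_map
#' @export
write_chrom_map <- function(map, path) {
  stopifnot(inherits(map, "chrom_map"))
  utils::write.table(as.data.frame(map)[, c("chrom", "length_bp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: validate that chrom/pos fall inside a map; names the first
# offending site so malformed inputs are diagnosable
check_positions <- function(chrom, pos, map, what = "site") {
  idx <- match(chrom, map$chrom)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unknown chromosome '%s' at %s %s:%s",
                 chrom[bad], what, chrom[bad], format(pos[bad])))
  }
  off <- which(pos < 1 | pos > map$length_bp[idx])
  if (length(off) > 0L) {
    b <- off[1L]
    stop(sprintf("position out of range at %s %s:%s", what,
                 chrom[b], format(pos[b])))
  }
  invisible(TRUE)
}
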