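#' Strain callsets and the consensus strain-diagnostic catalog
#'
#' A *strain callset* holds pre-called genotypes of one strain-A sample and
#' one strain-B sample (e.g. B6 and FVB fibroblast DNA called by one
#' pipeline) at biallelic SNV sites. Several callsets from independent
#' callers are intersected into a *consensus catalog* of strain-diagnostic
#' variants: sites where strain A is homozygous reference and strain B
#' homozygous alternate, consistently across callers. Those sites are what
#' the targeted amplicon panel genotypes to tell homologs apart.
#'
#' @name catalog
NULL

GT_LEVELS <- c("HOM_REF", "HOM_ALT", "HET", "MISSING")

#' Construct a strain callset
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param ref,alt Single-base reference and alternate alleles.
#' @param gt_a,gt_b Genotype of the strain-A and strain-B sample at each
#'   site, each one of `"HOM_REF"`, `"HOM_ALT"`, `"HET"`, `"MISSING"`.
#' @param source_name Label identifying the calling pipeline.
#' @param strain_a,strain_b Strain labels (defaults `"B6"`, `"FVB"`).
#' @return A `strain_callset` data.frame.
#' @export
strain_callset <- function(chrom, pos, ref, alt, gt_a, gt_b,
                           source_name = "callset",
                           strain_a = "B6", strain_b = "FVB") {
  cs <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   gt_a = as.character(gt_a), gt_b = as.character(gt_b),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(c(cs$gt_a, cs$gt_b)), GT_LEVELS)
  if (length(bad) > 0L) stop("unknown genotype code(s): ",
                             paste(bad, collapse = ", "))
  structure(cs, source_name = source_name,
            strain_a = strain_a, strain_b = strain_b,
            class = c("strain_callset", "data.frame"))
}

new_catalog <- function(df, provenance = character(),
                        strain_a = "B6", strain_b = "FVB") {
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            strain_a = strain_a, strain_b = strain_b,
            class = c("consensus_catalog", "data.frame"))
}

#' @export
print.consensus_catalog <- function(x, ...) {
  cat(sprintf(
    "consensus catalog: %d strain-diagnostic variants on %d chromosome(s)\n",
    nrow(x), length(unique(x$chrom))))
  cat(sprintf("  ref allele = %s, alt allele = %s; sources: %s\n",
              attr(x, "strain_a"), attr(x, "strain_b"),
              paste(attr(x, "provenance"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x)), row.names = FALSE)
  invisible(x)
}

#' Build the consensus strain-diagnostic variant catalog
#'
#' A site enters the catalog iff it is supported — called `HOM_REF` in the
#' strain-A sample and `HOM_ALT` in the strain-B sample — in at least
#' `min_sources` callsets, and is never contradicted in any callset. A
#' contradiction is a heterozygous call, an opposite homozygote, or
#' disagreeing REF/ALT alleles; `MISSING` neither supports nor contradicts.
#'
#' @param callsets List of [strain_callset()] objects (at least one).
#' @param chrom_map A [chromosome_map()]; sites outside it are rejected.
#' @param min_sources Minimum number of supporting callsets (default 2).
#' @return A `consensus_catalog`: data.frame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `n_support`, sorted by (chrom, pos) in map order, no
#'   duplicate positions. The reference allele is diagnostic for strain A,
#'   the alternate for strain B.
#' @export
build_consensus_catalog <- function(callsets, chrom_map, min_sources = 2L) {
  if (!is.list(callsets) || length(callsets) == 0L) {
    stop("need at least one strain callset")
  }
  if (min_sources < 1L || min_sources > length(callsets)) {
    stop("`min_sources` must be between 1 and the number of callsets")
  }
  strain_a <- attr(callsets[[1L]], "strain_a") %||% "B6"
  strain_b <- attr(callsets[[1L]], "strain_b") %||% "FVB"
  for (cs in callsets) check_positions(cs$chrom, cs$pos, chrom_map, "variant")

  all <- do.call(rbind, lapply(callsets, function(cs) {
    data.frame(chrom = cs$chrom, pos = cs$pos, ref = cs$ref, alt = cs$alt,
               gt_a = cs$gt_a, gt_b = cs$gt_b, stringsAsFactors = FALSE)
  }))
  if (nrow(all) == 0L) {
    return(new_catalog(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), n_support = integer(),
                 stringsAsFactors = FALSE),
      provenance = vapply(callsets, function(cs)
        attr(cs, "source_name") %||% "callset", character(1)),
      strain_a = strain_a, strain_b = strain_b))
  }

  key <- paste(all$chrom, all$pos, sep = ":")
  support <- all$gt_a == "HOM_REF" & all$gt_b == "HOM_ALT"
  contra <- all$gt_a %in% c("HET", "HOM_ALT") | all$gt_b %in% c("HET", "HOM_REF")
  n_support <- tapply(support, key, sum)
  any_contra <- tapply(contra, key, any)
  # allele consistency across sources counts as a contradiction
  allele_ok <- tapply(paste(all$ref, all$alt), key,
                      function(a) length(unique(a)) == 1L)
  keep_keys <- names(n_support)[n_support >= min_sources &
                                  !any_contra & allele_ok]
  first <- all[!duplicated(key) & key %in% keep_keys, , drop = FALSE]
  first$n_support <- as.integer(n_support[paste(first$chrom, first$pos,
                                                sep = ":")])
  ord <- order(match(first$chrom, chrom_map$chrom), first$pos)
  out <- first[ord, c("chrom", "pos", "ref", "alt", "n_support")]
  new_catalog(out,
              provenance = vapply(callsets, function(cs)
                attr(cs, "source_name") %||% "callset", character(1)),
              strain_a = strain_a, strain_b = strain_b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a strain callset from VCF
#'
#' Expects a VCF 4.x file with a `GT` FORMAT field and two sample columns
#' (strain A first, strain B second). Multi-allelic records and indels are
#' skipped; their count is reported via a message and the
#' `n_skipped` attribute.
#'
#' @param path VCF file path (plain or gzipped).
#' @param source_name Label for the callset; defaults to the file name.
#' @param strain_a,strain_b Strain labels for the two sample columns.
#' @return A [strain_callset()].
#' @export
read_vcf_callset <- function(path, source_name = basename(path),
                             strain_a = "B6", strain_b = "FVB") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(v@fix) == 0L) {
    return(strain_callset(character(), integer(), character(), character(),
                          character(), character(),
                          source_name = source_name,
                          strain_a = strain_a, strain_b = strain_b))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!snv)
  if (n_skipped > 0L) {
    message(sprintf("read_vcf_callset: skipped %d multi-allelic/indel record(s) in %s",
                    n_skipped, basename(path)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF must carry GT calls for two samples (strain A, strain B): ", path)
  }
  decode <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep("MISSING", length(g))
    out[g %in% c("0/0")] <- "HOM_REF"
    out[g %in% c("1/1")] <- "HOM_ALT"
    out[g %in% c("0/1", "1/0")] <- "HET"
    out
  }
  cs <- strain_callset(fix$CHROM[snv], as.integer(fix$POS[snv]),
                       ref[snv], alt[snv],
                       decode(gt[snv, 1L]), decode(gt[snv, 2L]),
                       source_name = source_name,
                       strain_a = strain_a, strain_b = strain_b)
  attr(cs, "n_skipped") <- n_skipped
  cs
}

#' Write / read a consensus catalog as VCF
#'
#' The catalog is serialized as a plain-text VCF 4.2 with two sample
#' columns: the strain-A sample homozygous reference (`0/0`) and the
#' strain-B sample homozygous alternate (`1/1`) at every site, which makes
#' a written catalog re-readable with [read_vcf_callset()] as a perfectly
#' supporting callset.
#'
#' @param catalog A `consensus_catalog`.
#' @param path Output / input path.
#' @return `write_catalog_vcf()` returns `path`; `read_catalog_vcf()` a
#'   `consensus_catalog`.
#' @export
write_catalog_vcf <- function(catalog, path) {
  stopifnot(inherits(catalog, "consensus_catalog"))
  sa <- attr(catalog, "strain_a") %||% "B6"
  sb <- attr(catalog, "strain_b") %||% "FVB"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haploidtrace consensus catalog",
           sprintf("##catalog_sources=%s",
                   paste(attr(catalog, "provenance"), collapse = ";")),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sa, sb), collapse = "\t"))
  body <- character(0)
  if (nrow(catalog) > 0L) {
    body <- paste(catalog$chrom, catalog$pos, ".", catalog$ref, catalog$alt,
                  ".", "PASS", ".", "GT", "0/0", "1/1", sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_catalog_vcf
#' @export
read_catalog_vcf <- function(path) {
  cs <- read_vcf_callset(path)
  keep <- cs$gt_a == "HOM_REF" & cs$gt_b == "HOM_ALT"
  df <- data.frame(chrom = cs$chrom[keep], pos = cs$pos[keep],
                   ref = cs$ref[keep], alt = cs$alt[keep],
                   n_support = 1L, stringsAsFactors = FALSE)
  new_catalog(df, provenance = attr(cs, "source_name"),
              strain_a = attr(cs, "strain_a"),
              strain_b = attr(cs, "strain_b"))
}
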