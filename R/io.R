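#' Write anomaly regions as BED5
#'
#' One row per region: part, start, end (0-based half-open), the
#' accession name, and the direction (`High`/`Low`) in the score column —
#' the layout of the published per-accession anomaly files.
#'
#' @param regions A tibble with `part`, `start`, `end`, `direction`.
#' @param path Output path.
#' @param name Value for the BED name column (default `"region"`),
#'   typically the accession.
#' @return `path`, invisibly.
#' @export
write_bed5 <- function(regions, path, name = "region") {
  check_columns(regions, c("part", "start", "end", "direction"), "regions")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                   regions$part, as.integer(regions$start),
                   as.integer(regions$end), name, regions$direction)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED5 file of regions
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return A tibble `part`, `start`, `end`, `name`, `direction` (missing
#'   columns filled with `NA`).
#' @export
read_bed5 <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(bed) == 0) {
    return(tibble(part = character(), start = numeric(), end = numeric(),
                  name = character(), direction = character()))
  }
  tibble(
    part = as.character(bed[[1]]),
    start = as.numeric(bed[[2]]),
    end = as.numeric(bed[[3]]),
    name = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA_character_,
    direction = if (ncol(bed) >= 5) as.character(bed[[5]]) else
      NA_character_
  )
}

#' Write a depth profile as bedGraph
#'
#' Consecutive equal-depth positions are collapsed into one interval
#' (0-based half-open), the standard bedGraph run-length layout.
#'
#' @param profile A [coverage_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  r <- rle(profile$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  lines <- sprintf("%s\t%d\t%d\t%d", profile$part, starts, ends, r$values)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph depth track into a coverage profile
#'
#' @param path Path to a bedGraph file covering one part.
#' @param part_length Optional total part length (bp); positions past the
#'   last interval get depth 0.
#' @return A [coverage_profile()].
#' @export
read_bedgraph <- function(path, part_length = NULL) {
  bg <- readr::read_tsv(path, col_names = c("part", "start", "end",
                                            "depth"),
                        comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (length(unique(bg$part)) != 1) {
    abort("bedGraph must cover exactly one part")
  }
  L <- part_length %||% max(bg$end)
  depth <- integer(L)
  for (i in seq_len(nrow(bg))) {
    depth[(bg$start[i] + 1):bg$end[i]] <- bg$depth[i]
  }
  coverage_profile(bg$part[1], depth)
}

#' Write a density track as bedGraph
#'
#' @param track A [variant_density()] track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_bedgraph <- function(track, path) {
  check_columns(track, c("part", "start", "end", "count"), "track")
  lines <- sprintf("%s\t%d\t%d\t%d", track$part,
                   as.integer(track$start), as.integer(track$end),
                   as.integer(track$count))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference FASTA into named character strings
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path
  )
  invisible(path)
}

#' Write classified variant records as VCF
#'
#' Emits a minimal single-sample VCF with each record's quality/zygosity
#' class (`PASS`/`Het`/`LowQualHom`/`LowQualHet`) in the FILTER column,
#' the layout the browser tracks filter on.
#'
#' @param records Classified records ([classify_variants()]).
#' @param path Output path (`.vcf`).
#' @param sample Sample column name (default `"sample1"`).
#' @return `path`, invisibly.
#' @export
write_classified_vcf <- function(records, path, sample = "sample1") {
  check_columns(records, c("part", "pos", "ref", "alt", "qual", "gt",
                           "class"), "records")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"High quality homozygous\">",
    "##FILTER=<ID=Het,Description=\"High quality heterozygous\">",
    "##FILTER=<ID=LowQualHom,Description=\"Low quality homozygous\">",
    "##FILTER=<ID=LowQualHet,Description=\"Low quality heterozygous\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  recs <- sprintf("%s\t%d\t.\t%s\t%s\t%.6g\t%s\t.\tGT\t%s",
                  records$part, as.integer(records$pos), records$ref,
                  records$alt, records$qual, records$class, records$gt)
  writeLines(c(header, recs), path)
  invisible(path)
}
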