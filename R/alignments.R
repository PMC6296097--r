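#' Read alignments into a tibble
#'
#' Loads SAM or BAM alignment records via Rsamtools.  A `.sam` file is
#' converted to a temporary BAM first, so plain-text fixtures work
#' transparently.
#'
#' @param path Path to a SAM or BAM file with `@SQ` headers.
#' @return A tibble with columns `qname`, `flag`, `part` (reference name),
#'   `pos` (1-based leftmost), `mapq`, `cigar`.  Unmapped records appear
#'   with `NA` position and are removed by [filter_alignments()].
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
    )
  )[[1]]
  tibble(
    qname = b$qname,
    flag = as.integer(b$flag),
    part = as.character(b$rname),
    pos = as.numeric(b$pos),
    mapq = as.integer(b$mapq),
    cigar = b$cigar,
    seq = as.character(b$seq)
  )
}

#' Filter alignments by mapping quality
#'
#' Removes unmapped records and records below the MAPQ floor.  Low-MAPQ
#' alignments are placements the aligner itself distrusts (multi-mapping
#' reads in a highly repetitive genome); dropping them before computing
#' depth keeps the coverage tracks interpretable.
#'
#' @param alignments A tibble from [read_alignments()] (any data frame
#'   with `flag`, `pos`, `mapq` columns).
#' @param min_mapq Minimum MAPQ kept; records with `mapq < min_mapq` are
#'   removed.  Default 5.
#' @return The filtered tibble.  Malformed mapped records (missing
#'   position or CIGAR) are skipped with a warning giving the count.
#' @export
filter_alignments <- function(alignments, min_mapq = 5) {
  check_columns(alignments, c("flag", "pos", "mapq"), "alignments")
  alignments <- as_tibble(alignments)
  mapped <- !is.na(alignments$pos) &
    bitwAnd(alignments$flag, 4L) == 0L
  alignments <- alignments[mapped, ]
  if ("cigar" %in% names(alignments)) {
    malformed <- is.na(alignments$cigar) | alignments$cigar == "*"
    if (any(malformed)) {
      warn(sprintf("skipped %d malformed mapped record(s) without CIGAR",
                   sum(malformed)))
      alignments <- alignments[!malformed, ]
    }
  }
  alignments[!is.na(alignments$mapq) & alignments$mapq >= min_mapq, ]
}

#' MAPQ distribution table
#'
#' Per-MAPQ alignment counts with the cumulative number (and percentage)
#' of alignments at or above each MAPQ, the summary used to choose and
#' report a MAPQ filtering threshold.
#'
#' @param alignments A data frame with a `mapq` column (mapped records).
#' @param raw_total Total raw reads sequenced, for the `% of raw` column;
#'   defaults to the number of aligned records (the two columns then
#'   coincide).
#' @return A tibble sorted by MAPQ descending with columns `mapq`, `n`,
#'   `cum_n` (records with MAPQ >= this row's), `pct_aligned`, `pct_raw`.
#' @export
mapq_table <- function(alignments, raw_total = NULL) {
  check_columns(alignments, "mapq", "alignments")
  mapq <- alignments$mapq[!is.na(alignments$mapq)]
  aligned_total <- length(mapq)
  raw_total <- raw_total %||% aligned_total
  out <- tibble(mapq = mapq) %>%
    count(.data$mapq, name = "n") %>%
    arrange(desc(.data$mapq)) %>%
    mutate(
      cum_n = cumsum(.data$n),
      pct_aligned = 100 * .data$cum_n / aligned_total,
      pct_raw = 100 * .data$cum_n / raw_total
    )
  out
}

# Parse CIGAR strings into per-record operation tables.
# Returns a tibble (record index, op, len).
cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  toks <- regmatches(cigar, m)
  tibble(
    rec = rep(seq_along(cigar), lengths(toks)),
    len = as.integer(sub("[MIDNSHP=X]$", "", unlist(toks))),
    op = sub("^\\d+", "", unlist(toks))
  )
}

# Reference spans covered by aligned bases (M, =, X ops only; deletions
# and skips consume reference but do not cover it; clipped/inserted bases
# consume no reference).  Returns tibble (rec, start, end), 1-based closed
# reference coordinates.
covered_spans <- function(pos, cigar) {
  ops <- cigar_ops(cigar)
  consumes_ref <- ops$op %in% c("M", "=", "X", "D", "N")
  # reference offset of each op within its record: cumulative consumed
  # length of preceding ops, reset per record
  adv <- ifelse(consumes_ref, ops$len, 0L)
  cum <- cumsum(adv)
  rec_first <- !duplicated(ops$rec)
  base <- cum[rec_first] - adv[rec_first]     # cumulative total before rec
  offset_before <- (cum - adv) - base[match(ops$rec, ops$rec[rec_first])]
  ref_start <- pos[ops$rec] + offset_before
  keep <- ops$op %in% c("M", "=", "X")
  tibble(rec = ops$rec[keep], start = ref_start[keep],
         end = ref_start[keep] + ops$len[keep] - 1)
}
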