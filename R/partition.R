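#' Partition schemes: pseudomolecule to "part" coordinate algebra
#'
#' Chromosome-scale pseudomolecules of large genomes (wheat being the
#' motivating case) exceed the 2^29-1 position limit of the classic
#' BAI/tabix index formats, so each pseudomolecule is split into smaller
#' "parts" and all browser-facing files are addressed in part coordinates.
#' A `partition_scheme` records, for every chromosome, the ordered parts
#' that exactly tile it, and backs all liftover arithmetic in the package.
#'
#' Internally every coordinate is 1-based closed; the BED representation
#' on disk (0-based half-open) is converted only at the I/O edge.
#'
#' @param parts A data frame with columns `chrom`, `start`, `end` (1-based
#'   closed positions on the full pseudomolecule) and optionally `part`
#'   (part name; defaults to `"<chrom>_part<k>"` numbering parts along the
#'   chromosome).
#' @return A `partition_scheme`: a tibble with columns `chrom`, `part`,
#'   `start`, `end`, `part_length`, `chrom_length`, validated so that the
#'   parts of each chromosome are contiguous, non-overlapping and exactly
#'   tile `[1, chrom_length]`, and part names are unique scheme-wide.
#' @examples
#' sc <- partition_scheme(data.frame(
#'   chrom = c("chr1", "chr1"), start = c(1, 61), end = c(60, 100)
#' ))
#' to_part(sc, "chr1", 61) # chr1_part2, position 1
#' @export
partition_scheme <- function(parts) {
  check_columns(parts, c("chrom", "start", "end"), "scheme definition")
  parts <- as_tibble(parts)
  if (nrow(parts) == 0) abort("scheme definition has no rows")
  parts$start <- as.numeric(parts$start)
  parts$end <- as.numeric(parts$end)
  if (any(is.na(parts$start)) || any(is.na(parts$end))) {
    abort("scheme definition contains missing coordinates")
  }
  if (any(parts$start > parts$end)) {
    bad <- parts$chrom[parts$start > parts$end]
    abort(sprintf("scheme-invalid: start > end for chromosome(s) %s",
                  paste(unique(bad), collapse = ", ")))
  }

  parts <- parts %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(.k = row_number()) %>%
    ungroup()

  if (!"part" %in% names(parts) || all(is.na(parts$part))) {
    parts$part <- paste0(parts$chrom, "_part", parts$.k)
  } else {
    parts$part <- ifelse(
      is.na(parts$part) | parts$part == "",
      paste0(parts$chrom, "_part", parts$.k),
      as.character(parts$part)
    )
  }

  # tiling check: within each chromosome, parts must start at 1 and each
  # subsequent part must start one past the previous end
  bad <- parts %>%
    group_by(.data$chrom) %>%
    summarise(
      ok = first(.data$start) == 1 &&
        all(diff_ok(.data$start, .data$end)),
      .groups = "drop"
    ) %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "scheme-invalid: parts do not contiguously tile chromosome(s) %s",
      paste(bad$chrom, collapse = ", ")
    ))
  }
  dup <- parts$part[duplicated(parts$part)]
  if (length(dup) > 0) {
    abort(sprintf("scheme-invalid: duplicate part name(s) %s",
                  paste(unique(dup), collapse = ", ")))
  }

  out <- parts %>%
    group_by(.data$chrom) %>%
    mutate(chrom_length = max(.data$end)) %>%
    ungroup() %>%
    mutate(part_length = .data$end - .data$start + 1) %>%
    select(all_of(c("chrom", "part", "start", "end",
                    "part_length", "chrom_length")))
  class(out) <- c("partition_scheme", class(out))
  out
}

diff_ok <- function(start, end) {
  if (length(start) == 1) return(TRUE)
  start[-1] == end[-length(end)] + 1
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("<partition_scheme: %d chromosome(s), %d part(s)>\n",
              length(unique(x$chrom)), nrow(x)))
  NextMethod()
}

#' Read a partition scheme from a BED file
#'
#' The on-disk representation is BED: one row per part with 0-based
#' half-open coordinates on the full pseudomolecule and the part name in
#' column 4 (optional).  A chromosome with a single row is unsplit.
#'
#' @param path Path to a BED file (3 or more columns, tab-separated).
#' @return A validated [partition_scheme()].
#' @export
read_partition_scheme <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = FALSE, comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  if (ncol(bed) < 3) abort("scheme BED needs at least 3 columns")
  df <- tibble(
    chrom = as.character(bed[[1]]),
    start = as.numeric(bed[[2]]) + 1,  # BED 0-based -> 1-based closed
    end = as.numeric(bed[[3]])
  )
  if (ncol(bed) >= 4) df$part <- as.character(bed[[4]])
  partition_scheme(df)
}

#' Write a partition scheme as BED
#'
#' @param scheme A [partition_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "partition_scheme"))
  lines <- sprintf("%s\t%d\t%d\t%s",
                   scheme$chrom, as.integer(scheme$start) - 1L,
                   as.integer(scheme$end), scheme$part)
  writeLines(lines, path)
  invisible(path)
}

#' Lift pseudomolecule positions to part coordinates
#'
#' @param scheme A [partition_scheme()].
#' @param chrom,position Vectors (recycled to common length) of chromosome
#'   names and 1-based positions on the full pseudomolecule.
#' @return A tibble with columns `chrom`, `position`, `part`,
#'   `part_position` where `part_position = position - part_start + 1`.
#' @export
to_part <- function(scheme, chrom, position) {
  stopifnot(inherits(scheme, "partition_scheme"))
  n <- max(length(chrom), length(position))
  chrom <- rep_len(as.character(chrom), n)
  position <- rep_len(as.numeric(position), n)

  unknown <- setdiff(chrom, scheme$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("unknown chromosome(s): %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  # match each (chrom, position) to the containing part
  idx <- vapply(seq_len(n), function(i) {
    rows <- which(scheme$chrom == chrom[i] &
                    scheme$start <= position[i] & scheme$end >= position[i])
    if (length(rows) == 0) NA_integer_ else rows[1]
  }, integer(1))
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    abort(sprintf("position %g out of range for chromosome %s",
                  position[i], chrom[i]))
  }
  tibble(
    chrom = chrom,
    position = position,
    part = scheme$part[idx],
    part_position = position - scheme$start[idx] + 1
  )
}

#' Lift part positions back to pseudomolecule coordinates
#'
#' Exact inverse of [to_part()] on every in-range coordinate.
#'
#' @param scheme A [partition_scheme()].
#' @param part,part_position Vectors (recycled) of part names and 1-based
#'   positions within the part.
#' @return A tibble with columns `part`, `part_position`, `chrom`,
#'   `position`.
#' @export
from_part <- function(scheme, part, part_position) {
  stopifnot(inherits(scheme, "partition_scheme"))
  n <- max(length(part), length(part_position))
  part <- rep_len(as.character(part), n)
  part_position <- rep_len(as.numeric(part_position), n)

  idx <- match(part, scheme$part)
  if (anyNA(idx)) {
    abort(sprintf("unknown part name(s): %s",
                  paste(unique(part[is.na(idx)]), collapse = ", ")))
  }
  bad <- part_position < 1 | part_position > scheme$part_length[idx]
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("position %g beyond length of part %s",
                  part_position[i], part[i]))
  }
  tibble(
    part = part,
    part_position = part_position,
    chrom = scheme$chrom[idx],
    position = scheme$start[idx] + part_position - 1
  )
}

#' Interval width
#'
#' Width of coordinate intervals.  For coordinate pairs quoted in a common
#' unit (e.g. Mbp positions of centromere borders) the width is
#' `end - start`; for 1-based closed base-pair intervals it is
#' `end - start + 1`.
#'
#' @param start,end Numeric vectors of interval ends, same unit.
#' @param closed If `TRUE`, treat intervals as 1-based closed base-pair
#'   intervals (`end - start + 1`); default `FALSE` gives `end - start`.
#' @return Numeric vector of widths.
#' @examples
#' interval_width(300, 410)            # 110 (Mbp-style coordinates)
#' interval_width(61, 100, closed = TRUE)  # 40 bp
#' @export
interval_width <- function(start, end, closed = FALSE) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end < start, na.rm = TRUE)) abort("interval end < start")
  if (closed) end - start + 1 else end - start
}

#' Split reference-addressed records into per-part sets
#'
#' Chunk a record stream (already addressed in part coordinates) into one
#' set per part of the scheme, preserving within-part order.  Every part of
#' the scheme is present in the output, empty sets included, so the number
#' of output sets always equals the number of parts.
#'
#' @param records A data frame with a `part` column.
#' @param scheme A [partition_scheme()].
#' @return A named list of tibbles, one per scheme part, in scheme order.
#' @export
chunk_by_part <- function(records, scheme) {
  stopifnot(inherits(scheme, "partition_scheme"))
  check_columns(records, "part", "records")
  records <- as_tibble(records)
  unknown <- setdiff(unique(records$part), scheme$part)
  if (length(unknown) > 0) {
    abort(sprintf("record(s) reference unknown part(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- lapply(scheme$part, function(p) records[records$part == p, ])
  setNames(out, scheme$part)
}

#' Bundled predicted centromere intervals
#'
#' Predicted centromeric regions (Mbp borders on the full pseudomolecules)
#' for the 21 bread wheat chromosomes of the IWGSC RefSeq v1.0 assembly,
#' as used in the package examples of interval arithmetic.
#'
#' @return A tibble with columns `chrom`, `start_mbp`, `end_mbp`.
#' @export
centromere_intervals <- function() {
  path <- system.file("extdata", "centromere_intervals.tsv",
                      package = "seqtracks", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Bundled landmark regions
#'
#' A handful of published part-coordinate regions on the IWGSC RefSeq
#' v1.0 parts (a terminal introgression on 7A, a vernalisation gene, a
#' copy-number gain on 6D) used in examples of coordinate arithmetic.
#'
#' @return A tibble with columns `name`, `part`, `start`, `end`
#'   (1-based bp).
#' @export
landmark_regions <- function() {
  path <- system.file("extdata", "landmark_regions.tsv",
                      package = "seqtracks", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
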