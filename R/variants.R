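#' Read VCF records into a tibble
#'
#' Thin tidy wrapper over `vcfR`: one row per VCF record with the fields
#' the classifier and density track need.  The genotype is taken from the
#' named sample (default: first sample column).
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param sample Sample name; default first sample.
#' @return A tibble with columns `part` (CHROM), `pos`, `ref`, `alt`
#'   (comma-joined alternatives), `qual`, `gt`.
#' @export
read_vcf_records <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- NULL
  if (ncol(v@gt) >= 2) {
    gtm <- vcfR::extract.gt(v, element = "GT")
    sample <- sample %||% colnames(gtm)[1]
    if (!sample %in% colnames(gtm)) {
      abort(sprintf("sample %s not in VCF", sample))
    }
    gt <- unname(gtm[, sample])
  }
  tibble(
    part = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    gt = gt %||% NA_character_
  )
}

variant_colours <- c(A = "green", T = "red", C = "blue", G = "yellow")

# Zygosity from a diploid GT string: "het", "hom", or NA if uncalled.
gt_zygosity <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == ".") || anyNA(a)) return(NA_character_)
    if (length(unique(a)) > 1) "het" else "hom"
  }, character(1))
}

#' Classify variant records by quality and zygosity
#'
#' Assigns each record exactly one of the four track filter classes:
#' `PASS` (high-quality homozygous), `Het` (high-quality heterozygous),
#' `LowQualHom`, `LowQualHet`.  "High quality" means `QUAL >=
#' qual_threshold`; zygosity is judged from the genotype field alone,
#' never from allele balance.  The published pipeline does not print the
#' QUAL cut-off it used; the default of 20 is the conventional
#' Phred-scaled threshold (1% error) and is deliberately configurable.
#'
#' Records without a called genotype are dropped with a warning.
#'
#' @param records A tibble of variant records ([read_vcf_records()]):
#'   columns `pos`, `ref`, `alt`, `qual`, `gt` (and usually `part`).
#' @param qual_threshold QUAL separating high from low quality
#'   (default 20).
#' @return The records tibble with added columns `zygosity`, `kind`
#'   (`SNV`/`indel`/`multiallelic`), `class`, and `colour` (per-allele
#'   display colour, black for indel/multiallelic).
#' @export
classify_variants <- function(records, qual_threshold = 20) {
  check_columns(records, c("pos", "ref", "alt", "qual", "gt"), "records")
  records <- as_tibble(records)

  zyg <- gt_zygosity(records$gt)
  n_skip <- sum(is.na(zyg) | is.na(records$qual))
  if (n_skip > 0) {
    warn(sprintf("skipped %d record(s) without a called genotype or QUAL",
                 n_skip))
    keep <- !(is.na(zyg) | is.na(records$qual))
    records <- records[keep, ]
    zyg <- zyg[keep]
  }

  multi <- grepl(",", records$alt, fixed = TRUE)
  indel <- !multi & (nchar(records$ref) != 1 |
                       nchar(records$alt) != 1 |
                       records$alt == "*")
  kind <- case_when(multi ~ "multiallelic", indel ~ "indel",
                    TRUE ~ "SNV")
  high <- records$qual >= qual_threshold

  records %>%
    mutate(
      zygosity = zyg,
      kind = kind,
      class = case_when(
        high & zyg == "hom" ~ "PASS",
        high & zyg == "het" ~ "Het",
        !high & zyg == "hom" ~ "LowQualHom",
        TRUE ~ "LowQualHet"
      ),
      colour = dplyr::if_else(
        kind == "SNV",
        unname(variant_colours[toupper(records$alt)]),
        "black"
      ),
      colour = dplyr::coalesce(.data$colour, "black")
    )
}

#' Windowed variant density
#'
#' Number of counted variant calls per non-overlapping window, window 1
#' anchored at position 1 (window `w` covers positions
#' `[(w-1)*window + 1, w*window]`).  By default only the homozygous
#' classes (`PASS`, `LowQualHom`) are counted, matching the default track
#' display.  A multiallelic record counts once.
#'
#' @param records Classified variant records ([classify_variants()]),
#'   with `part`, `pos` and `class` columns.
#' @param window Window width in bp (default 10000).
#' @param counted_classes Classes included in the count.
#' @param part_lengths Optional named vector of part lengths; when given,
#'   every window of each part is emitted (zero counts included) and the
#'   terminal partial window is flagged.  Without it the track extends to
#'   the last window containing a record and no window is flagged
#'   partial.
#' @return A tibble: `part`, `win` (1-based index), `start`, `end`
#'   (0-based half-open bp, terminal window clipped to part length),
#'   `count`, `partial`.
#' @export
variant_density <- function(records, window = 10000,
                            counted_classes = c("PASS", "LowQualHom"),
                            part_lengths = NULL) {
  check_columns(records, c("part", "pos", "class"), "records")
  counted <- records[records$class %in% counted_classes, ]

  parts <- if (!is.null(part_lengths)) names(part_lengths)
           else unique(records$part)
  out <- map(parts, function(p) {
    pos <- counted$pos[counted$part == p]
    if (!is.null(part_lengths)) {
      plen <- part_lengths[[p]]
      if (any(pos > plen)) abort(sprintf("record beyond length of %s", p))
      nw <- ceiling(plen / window)
    } else {
      plen <- NA_real_
      nw <- if (length(pos) == 0) 0L else ceiling(max(pos) / window)
    }
    if (nw == 0) return(NULL)
    w <- (pos - 1) %/% window + 1
    counts <- tabulate(w, nbins = nw)
    end <- seq_len(nw) * window
    partial <- rep(FALSE, nw)
    if (!is.na(plen)) {
      end <- pmin(end, plen)
      partial[nw] <- plen %% window != 0
    }
    tibble(part = p, win = seq_len(nw),
           start = (seq_len(nw) - 1) * window, end = end,
           count = counts, partial = partial)
  })
  list_rbind(out)
}

#' Call high/low variant-density anomaly regions
#'
#' The window-level counterpart of [call_coverage_anomalies()]: windows
#' with variant count strictly more than `k` standard deviations from the
#' mean seed High/Low runs; same-direction runs at most `merge_gap` bp
#' apart are merged (gap included); merged regions shorter than `min_len`
#' bp are dropped.  Region coordinates are window-aligned.
#'
#' Statistics default to the track's own complete (non-partial) windows;
#' pass `stats` (e.g. pooled over a whole accession) to threshold several
#' parts against one mean, mirroring the single per-accession mean of the
#' coverage rule.  Partial terminal windows never enter the statistics
#' but can still seed or extend a region.
#'
#' @param track A density track ([variant_density()]), one part.
#' @param k Multiplier on the standard deviation (default 2).
#' @param merge_gap Maximum merged gap in bp (default 40000).
#' @param min_len Minimum reported length in bp (default 500000), both
#'   directions.
#' @param stats Optional one-row data frame with `mean` and `sd`.
#' @return A tibble of regions: `part`, `start`, `end` (0-based
#'   half-open, window-aligned), `direction`, `mean_count` (mean window
#'   count inside), `length`.
#' @export
call_density_anomalies <- function(track, k = 2, merge_gap = 40000,
                                   min_len = 500000, stats = NULL) {
  check_columns(track, c("part", "win", "start", "end", "count",
                         "partial"), "track")
  if (length(unique(track$part)) > 1) {
    abort("track must cover a single part; split first")
  }
  if (nrow(track) < 2) abort("need at least 2 windows")
  if (is.null(stats)) stats <- density_stats(track)
  mu <- stats$mean[1]; sigma <- stats$sd[1]

  status <- exceedance_status(track$count, mu, sigma, k)
  regions <- segment_exceedance(status, track$start, track$end,
                                merge_gap, min_len, min_len)
  if (nrow(regions) == 0) {
    return(tibble(part = character(), start = numeric(), end = numeric(),
                  direction = character(), mean_count = numeric(),
                  length = numeric()))
  }
  regions$part <- track$part[1]
  regions$mean_count <- vapply(seq_len(nrow(regions)), function(i) {
    mean(track$count[track$start >= regions$start[i] &
                       track$end <= regions$end[i]])
  }, numeric(1))
  regions$length <- regions$end - regions$start
  regions[, c("part", "start", "end", "direction", "mean_count", "length")]
}

#' Density-track summary statistics
#'
#' Mean and population standard deviation of window counts over complete
#' (non-partial) windows, across everything in `track` (one part or an
#' accession-wide bind of parts).
#'
#' @param track A density track or row-bind of tracks.
#' @return A one-row tibble: `mean`, `sd`, `n` windows used.
#' @export
density_stats <- function(track) {
  check_columns(track, c("count", "partial"), "track")
  x <- track$count[!track$partial]
  if (length(x) < 2) abort("need at least 2 complete windows")
  mu <- mean(x)
  tibble(mean = mu, sd = sqrt(mean((x - mu)^2)), n = length(x))
}
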