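#' Per-base read-depth profiles
#'
#' A `coverage_profile` holds the per-base depth of one reference part:
#' the part name, an integer depth vector (index = 1-based position) and
#' an optional logical mask of assembly-gap (N) positions that are
#' excluded from summary statistics.
#'
#' @param part Part name.
#' @param depth Integer vector of per-base depths, length = part length.
#' @param mask Optional logical vector, `TRUE` at masked (assembly-gap)
#'   positions; same length as `depth`.
#' @return A `coverage_profile` object.
#' @export
coverage_profile <- function(part, depth, mask = NULL) {
  depth <- as.integer(depth)
  if (any(is.na(depth)) || any(depth < 0)) {
    abort("depth must be non-negative integers")
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != length(depth)) {
      abort("mask length must equal depth length")
    }
  }
  structure(
    list(part = as.character(part), depth = depth, mask = mask),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  n_mask <- if (is.null(x$mask)) 0L else sum(x$mask)
  cat(sprintf("<coverage_profile %s: %d bp, %d masked>\n",
              x$part, length(x$depth), n_mask))
  invisible(x)
}

#' @export
#' @rdname coverage_profile
#' @param x A `coverage_profile`.
#' @param ... Unused.
tidy.coverage_profile <- function(x, ...) {
  tibble(
    part = x$part,
    pos = seq_along(x$depth),
    depth = x$depth,
    masked = if (is.null(x$mask)) FALSE else x$mask
  )
}

#' @export
#' @rdname coverage_profile
glance.coverage_profile <- function(x, ...) {
  s <- depth_stats(list(x), scope = x$part)
  s$length <- length(x$depth)
  s
}

#' Compute a depth profile from filtered alignments
#'
#' Per-base depth over one part: `depth[i]` is the number of alignments
#' whose aligned reference span covers base `i`.  Deletions within a
#' read's alignment and soft/hard-clipped bases do not cover.
#'
#' @param alignments A tibble of MAPQ-filtered, coordinate-sorted
#'   alignments (`part`, `pos`, `cigar` columns; see
#'   [filter_alignments()]).
#' @param part Part name to profile; records on other parts are ignored.
#' @param part_length Length of the part in bp.
#' @param mask Optional logical mask (see [coverage_profile()]).
#' @return A [coverage_profile()].
#' @export
depth_profile <- function(alignments, part, part_length, mask = NULL) {
  check_columns(alignments, c("part", "pos", "cigar"), "alignments")
  aln <- alignments[alignments$part == part, ]
  if (nrow(aln) > 0 && is.unsorted(aln$pos)) {
    abort("alignments must be coordinate-sorted")
  }
  depth <- integer(part_length)
  if (nrow(aln) > 0) {
    spans <- covered_spans(aln$pos, aln$cigar)
    if (any(spans$end > part_length)) {
      abort(sprintf("alignment extends beyond part length %d", part_length))
    }
    # difference-array accumulation of closed spans
    diffs <- numeric(part_length + 1)
    inc <- tapply(rep(1L, nrow(spans)), spans$start, sum)
    dec <- tapply(rep(1L, nrow(spans)), spans$end + 1, sum)
    diffs[as.integer(names(inc))] <- diffs[as.integer(names(inc))] + inc
    idx <- as.integer(names(dec))
    keep <- idx <= part_length + 1
    diffs[idx[keep]] <- diffs[idx[keep]] - dec[keep]
    depth <- as.integer(cumsum(diffs)[seq_len(part_length)])
  }
  coverage_profile(part, depth, mask)
}

#' Depth summary statistics
#'
#' Mean and population standard deviation of per-base depth over the
#' unmasked positions of one or more profiles.  These are the statistics
#' the anomaly caller thresholds against; the scope (one part, one
#' chromosome, or the whole genome of an accession) is the caller's
#' choice and is recorded in the result.
#'
#' @param profiles A [coverage_profile()] or list of them.
#' @param scope Scope label recorded in the output (default `"genome"`).
#' @return A one-row tibble: `scope`, `mean`, `sd` (population), `n`
#'   (unmasked positions used).
#' @export
depth_stats <- function(profiles, scope = "genome") {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  d <- unlist(lapply(profiles, function(p) {
    if (is.null(p$mask)) p$depth else p$depth[!p$mask]
  }), use.names = FALSE)
  if (length(d) == 0) abort("all positions masked: no depth to summarise")
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))   # population SD
  tibble(scope = scope, mean = mu, sd = sigma, n = length(d))
}

#' Call high/low read-coverage anomaly regions
#'
#' Segments a depth profile against its accession-level statistics with
#' the threshold -> merge -> length-filter rule: positions with depth
#' strictly above `mean + k*sd` seed High runs, strictly below
#' `mean - k*sd` seed Low runs; same-direction runs at most `merge_gap`
#' bp apart are merged (gap included); merged regions shorter than
#' `min_len_high` (High) or `min_len_low` (Low) are dropped.
#'
#' With `window > 1`, exceedance is evaluated on non-overlapping windows
#' of mean depth instead of single bases (region bounds are then
#' window-aligned).  The per-base default follows the track definition;
#' the windowed mode suppresses shot noise at shallow depth and is much
#' faster on long parts.
#'
#' Note `sd = 0` with `k > 0` makes every off-mean position a seed; this
#' is the degenerate but well-defined limit of the rule.
#'
#' @param profile A [coverage_profile()].
#' @param stats A row from [depth_stats()] (columns `mean`, `sd`).
#' @param k Multiplier on the standard deviation (default 2).
#' @param merge_gap Maximum gap merged, bp (default 500).
#' @param min_len_high,min_len_low Minimum reported length, bp (defaults
#'   5000 and 50000: low-coverage calls need more length to be credible
#'   because shallow data drops out locally all the time).
#' @param window Exceedance unit width in bp (default 1 = per base).
#' @return A tibble of regions: `part`, `start`, `end` (0-based
#'   half-open), `direction` (`"High"`/`"Low"`), `mean_depth` (unmasked
#'   mean within the region), `length`.
#' @export
call_coverage_anomalies <- function(profile, stats, k = 2,
                                    merge_gap = 500,
                                    min_len_high = 5000,
                                    min_len_low = 50000,
                                    window = 1) {
  stopifnot(inherits(profile, "coverage_profile"))
  check_columns(stats, c("mean", "sd"), "stats")
  mu <- stats$mean[1]; sigma <- stats$sd[1]
  L <- length(profile$depth)
  mask <- profile$mask

  if (window <= 1) {
    status <- exceedance_status(profile$depth, mu, sigma, k, mask)
    unit_start <- 0:(L - 1)
    unit_end <- 1:L
  } else {
    nw <- ceiling(L / window)
    idx <- rep(seq_len(nw), each = window, length.out = L)
    if (is.null(mask) && L %% window == 0) {
      wmean <- colMeans(matrix(profile$depth, nrow = window))
      wmask <- rep(FALSE, nw)
    } else if (is.null(mask)) {
      wmean <- tapply(profile$depth, idx, mean)
      wmask <- rep(FALSE, nw)
    } else {
      d <- ifelse(mask, NA_integer_, profile$depth)
      wmean <- tapply(d, idx, mean, na.rm = TRUE)
      wmask <- tapply(mask, idx, all)
    }
    status <- exceedance_status(as.numeric(wmean), mu, sigma, k,
                                as.logical(wmask))
    unit_start <- (seq_len(nw) - 1) * window
    unit_end <- pmin(seq_len(nw) * window, L)
  }

  regions <- segment_exceedance(status, unit_start, unit_end,
                                merge_gap, min_len_high, min_len_low)
  if (nrow(regions) == 0) {
    return(tibble(part = character(), start = numeric(), end = numeric(),
                  direction = character(), mean_depth = numeric(),
                  length = numeric()))
  }
  regions %>%
    mutate(
      part = profile$part,
      mean_depth = map2_dbl_regions(.data$start, .data$end, profile),
      length = .data$end - .data$start
    ) %>%
    select(all_of(c("part", "start", "end", "direction",
                    "mean_depth", "length")))
}

map2_dbl_regions <- function(start, end, profile) {
  vapply(seq_along(start), function(i) {
    span <- (start[i] + 1):end[i]
    d <- profile$depth[span]
    if (!is.null(profile$mask)) d <- d[!profile$mask[span]]
    if (length(d) == 0) NA_real_ else mean(d)
  }, numeric(1))
}
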