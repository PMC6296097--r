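#' Threshold -> merge -> length-filter segmentation
#'
#' Both read-depth and variant-density anomaly calling reduce to the same
#' rule over a signal sampled on consecutive units (bases or windows):
#'
#' 1. seed runs: maximal runs of consecutive units exceeding the mean by
#'    more than `k` standard deviations (High) or falling more than `k`
#'    standard deviations below it (Low);
#' 2. merge: same-direction runs whose base-pair gap is at most
#'    `merge_gap` are merged, gap included;
#' 3. length filter: merged regions shorter than the direction's minimum
#'    length are dropped.
#'
#' Coordinates are 0-based half-open throughout (BED-ready); a region's
#' length is `end - start`, so gap bases absorbed by merging count toward
#' the minimum length.  Masked units cannot seed and break runs, but the
#' distance across them still counts toward the merge gap.
#'
#' @param status Integer vector per unit: `+1` (exceeds above), `-1`
#'   (below), `0` (neither or masked).
#' @param unit_start,unit_end 0-based half-open base-pair interval of each
#'   unit; units must be consecutive and non-overlapping.
#' @param merge_gap Maximum base-pair gap merged (gap `<= merge_gap`).
#' @param min_len_high,min_len_low Minimum merged length (bp) to report,
#'   per direction.
#' @return A tibble with columns `start`, `end` (0-based half-open bp),
#'   `direction` (`"High"`/`"Low"`), `n_units` (seed units contributing),
#'   sorted by `start`.
#' @keywords internal
segment_exceedance <- function(status, unit_start, unit_end,
                               merge_gap, min_len_high, min_len_low) {
  stopifnot(length(status) == length(unit_start),
            length(status) == length(unit_end))
  empty <- tibble(start = numeric(), end = numeric(),
                  direction = character(), n_units = integer())
  if (length(status) == 0) return(empty)

  r <- rle(as.integer(status))
  run_end_idx <- cumsum(r$lengths)
  run_start_idx <- run_end_idx - r$lengths + 1
  seed <- r$values != 0
  if (!any(seed)) return(empty)

  runs <- tibble(
    start = as.numeric(unit_start[run_start_idx[seed]]),
    end = as.numeric(unit_end[run_end_idx[seed]]),
    direction = ifelse(r$values[seed] > 0, "High", "Low"),
    n_units = r$lengths[seed]
  )

  merged <- runs %>%
    group_by(.data$direction) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(
      gap = .data$start - lag(.data$end, default = -Inf),
      grp = cumsum(.data$gap > .env$merge_gap)
    ) %>%
    group_by(.data$direction, .data$grp) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_units = sum(.data$n_units), .groups = "drop"
    )

  min_len <- ifelse(merged$direction == "High", min_len_high, min_len_low)
  merged %>%
    filter(.data$end - .data$start >= min_len) %>%
    arrange(.data$start) %>%
    select(all_of(c("start", "end", "direction", "n_units")))
}

# Exceedance status of a numeric signal against mean/sd with strict
# inequalities (> mu + k*sd seeds High, < mu - k*sd seeds Low); masked
# units get status 0.
exceedance_status <- function(x, mu, sd, k, masked = NULL) {
  status <- integer(length(x))
  status[x > mu + k * sd] <- 1L
  status[x < mu - k * sd] <- -1L
  if (!is.null(masked)) status[masked] <- 0L
  status[is.na(x)] <- 0L
  status
}
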