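#' Jointly classify regions from coverage and density evidence
#'
#' Operationalises the interpretive logic used when reading coverage and
#' variant-density tracks side by side: a region with read depth near the
#' accession mean and unremarkable variant density looks like the
#' reference (`CS_LIKE`); near-mean depth with strongly elevated density
#' marks sequence divergent from the reference (`DIVERGENT`); depth
#' collapsing toward zero marks a deletion or an alien introgression
#' whose sequence no longer aligns (`DELETED_OR_INTROGRESSED`); and a
#' roughly two-fold depth gain that also clears the 2-SD band marks a
#' copy-number gain (`CNV_GAIN`).
#'
#' Decision rule, evaluated in order on each interval's evidence
#' (`ratio` = mean depth / accession mean depth; `dens` = mean window
#' count; `mu_d`, `sd_d` = density stats):
#'
#' 1. `ratio < low_cut`  ->  `DELETED_OR_INTROGRESSED`
#' 2. `|ratio - 1| <= band` (with `band = k*sd/mean` of depth) and
#'    `dens <= mu_d + k*sd_d`  ->  `CS_LIKE`;
#'    same depth band with `dens > mu_d + k*sd_d`  ->  `DIVERGENT`
#' 3. `gain_lo <= ratio <= gain_hi` and mean depth `> mean + k*sd`  ->
#'    `CNV_GAIN`
#' 4. otherwise the nearest rule by normalised distance, flagged
#'    `ambiguous`.
#'
#' None of these cut-offs is canonical ("good coverage" and "low
#' density" are qualitative notions); all are explicit arguments.
#'
#' @param intervals A data frame of intervals: `part`, `start`, `end`
#'   (0-based half-open bp).
#' @param profile A [coverage_profile()] covering the intervals' part.
#' @param cov_stats Accession depth statistics ([depth_stats()]).
#' @param track Variant-density track for the part ([variant_density()]).
#' @param dens_stats Accession density statistics ([density_stats()]);
#'   defaults to `density_stats(track)`.
#' @param low_cut Depth ratio below which a region counts as
#'   deleted/introgressed (default 0.25).
#' @param gain Two-element depth-ratio range for a copy-number gain
#'   (default `c(1.75, 2.5)`, bracketing the ~2-fold signal of a
#'   single-copy gain).
#' @param k SD multiplier shared with the anomaly callers (default 2).
#' @param genes Optional data frame of gene features on the part
#'   (`start`, `end`, 0-based half-open bp).  When supplied, each region
#'   gains `gene_cov_frac`: the fraction of gene-overlapping bases with
#'   depth above half the accession mean.  Alien introgressions tend to
#'   retain genic coverage spikes that true deletions lack, so a low
#'   ratio with appreciable `gene_cov_frac` hints at introgression
#'   rather than deletion.
#' @return A tibble: the intervals plus `label`, `depth_ratio`,
#'   `mean_depth`, `mean_density`, `density_z`, `ambiguous`
#'   (and `gene_cov_frac` when `genes` is given).
#' @export
classify_regions <- function(intervals, profile, cov_stats, track,
                             dens_stats = NULL, low_cut = 0.25,
                             gain = c(1.75, 2.5), k = 2, genes = NULL) {
  check_columns(intervals, c("part", "start", "end"), "intervals")
  stopifnot(inherits(profile, "coverage_profile"))
  check_columns(cov_stats, c("mean", "sd"), "cov_stats")
  check_columns(track, c("start", "end", "count"), "track")
  dens_stats <- dens_stats %||% density_stats(track)

  mu <- cov_stats$mean[1]; sigma <- cov_stats$sd[1]
  mu_d <- dens_stats$mean[1]; sd_d <- dens_stats$sd[1]
  band <- if (mu > 0) k * sigma / mu else Inf
  L <- length(profile$depth)

  res <- map(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (intervals$part[i] != profile$part || s < 0 || e > L || e <= s) {
      abort(sprintf("interval %s:%g-%g has no track data",
                    intervals$part[i], s, e))
    }
    span <- (s + 1):e
    d <- profile$depth[span]
    if (!is.null(profile$mask)) d <- d[!profile$mask[span]]
    if (length(d) == 0) abort("interval entirely masked")
    mean_depth <- mean(d)
    ratio <- if (mu > 0) mean_depth / mu else Inf

    w <- track$start < e & track$end > s
    if (!any(w)) {
      abort(sprintf("interval %s:%g-%g overlaps no density window",
                    intervals$part[i], s, e))
    }
    dens <- mean(track$count[w])
    dens_z <- if (sd_d > 0) (dens - mu_d) / sd_d else
      ifelse(dens == mu_d, 0, sign(dens - mu_d) * Inf)

    label <- NA_character_; ambiguous <- FALSE
    if (ratio < low_cut) {
      label <- "DELETED_OR_INTROGRESSED"
    } else if (abs(ratio - 1) <= band) {
      label <- if (dens <= mu_d + k * sd_d) "CS_LIKE" else "DIVERGENT"
    } else if (ratio >= gain[1] && ratio <= gain[2] &&
               mean_depth > mu + k * sigma) {
      label <- "CNV_GAIN"
    } else {
      # nearest rule by normalised distance in (ratio, density-z) space
      dist <- c(
        DELETED_OR_INTROGRESSED = max(0, ratio - low_cut) / low_cut,
        CS_LIKE = max(0, abs(ratio - 1) - band) + max(0, dens_z - k),
        DIVERGENT = max(0, abs(ratio - 1) - band) + max(0, k - dens_z),
        CNV_GAIN = max(0, gain[1] - ratio, ratio - gain[2])
      )
      label <- names(dist)[which.min(dist)]
      ambiguous <- TRUE
    }

    out <- tibble(
      part = intervals$part[i], start = s, end = e,
      label = label, depth_ratio = ratio, mean_depth = mean_depth,
      mean_density = dens, density_z = dens_z, ambiguous = ambiguous
    )
    if (!is.null(genes)) {
      out$gene_cov_frac <- gene_coverage_fraction(genes, profile, s, e, mu)
    }
    out
  })
  list_rbind(res)
}

# Fraction of gene-overlapping bases within [s, e) with depth > 0.5 * mu.
gene_coverage_fraction <- function(genes, profile, s, e, mu) {
  check_columns(genes, c("start", "end"), "genes")
  gs <- pmax(genes$start, s); ge <- pmin(genes$end, e)
  keep <- ge > gs
  if (!any(keep)) return(NA_real_)
  pos <- unique(unlist(map2(gs[keep], ge[keep], function(a, b) (a + 1):b)))
  mean(profile$depth[pos] > 0.5 * mu)
}
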