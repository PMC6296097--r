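#' Synthetic resequencing panels with planted features
#'
#' The generator emulates the signal structure the track pipeline is built
#' to expose: per-base read depth as Poisson counts around a baseline
#' lambda, and variant calls as a spatial Poisson process, with planted
#' intervals that modulate both.  Feature types and their default effects:
#'
#' * `deletion` — depth multiplier 0, no variants (nothing aligns);
#' * `introgression` — depth multiplier 0.25 and 5x variant rate (alien
#'   sequence aligns poorly and mismatches heavily where it does);
#' * `cnv_gain` — depth multiplier 2, baseline variant rate;
#' * `haplotype_block` — baseline depth, 5x variant rate (a divergent but
#'   syntenic segment).
#'
#' @param seed Integer seed; all stochastic draws flow from it.
#' @param parts Tibble of `part`, `length` (bp).
#' @param lambda Baseline mean depth (default 10, shallow whole-genome
#'   resequencing scale).
#' @param variant_rate_kbp Baseline variant rate per kbp, all classes
#'   (default 1.7, the order observed for wheat accessions against a
#'   distant reference).
#' @param hom_fraction Fraction of simulated variants that are
#'   homozygous (default 0.85).
#' @param high_qual_fraction Fraction with QUAL at or above 20
#'   (default 0.8).
#' @param features Tibble of planted features: `type`, `part`, `start`,
#'   `end` (1-based closed bp) and optional `multiplier`,
#'   `rate_kbp` overriding the type defaults.  Features of conflicting
#'   type must not overlap.
#' @param accession Accession name for the simulated sample.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       parts = tibble(part = "synth1_part1",
                                      length = 1e6),
                       lambda = 10,
                       variant_rate_kbp = 1.7,
                       hom_fraction = 0.85,
                       high_qual_fraction = 0.8,
                       features = NULL,
                       accession = "synthA") {
  check_columns(parts, c("part", "length"), "parts")
  if (lambda < 0 || variant_rate_kbp < 0) {
    abort("lambda and variant_rate_kbp must be non-negative")
  }
  defaults <- tibble(
    type = c("deletion", "introgression", "cnv_gain", "haplotype_block"),
    .mult = c(0, 0.25, 2, 1),
    .rate_factor = c(0, 5, 1, 5)
  )
  if (is.null(features)) {
    features <- tibble(type = character(), part = character(),
                       start = numeric(), end = numeric(),
                       multiplier = numeric(), rate_kbp = numeric())
  } else {
    check_columns(features, c("type", "part", "start", "end"), "features")
    features <- as_tibble(features)
    bad_type <- setdiff(features$type, defaults$type)
    if (length(bad_type) > 0) {
      abort(sprintf("unknown feature type(s): %s",
                    paste(bad_type, collapse = ", ")))
    }
    features <- left_join(features, defaults, by = "type")
    if (!"multiplier" %in% names(features)) features$multiplier <- NA
    if (!"rate_kbp" %in% names(features)) features$rate_kbp <- NA
    features$multiplier <- dplyr::coalesce(features$multiplier,
                                           features$.mult)
    features$rate_kbp <- dplyr::coalesce(features$rate_kbp,
                                         features$.rate_factor *
                                           variant_rate_kbp)
    features$.mult <- NULL; features$.rate_factor <- NULL

    plen <- setNames(parts$length, parts$part)
    if (any(!features$part %in% parts$part) ||
        any(features$start < 1) ||
        any(features$end > plen[features$part]) ||
        any(features$start > features$end)) {
      abort("planted features must lie within their parts")
    }
    if (any(features$multiplier < 0) || any(features$rate_kbp < 0)) {
      abort("feature effect parameters must be non-negative")
    }
    # conflicting-type overlap check per part
    for (p in unique(features$part)) {
      f <- features[features$part == p, ] %>% arrange(.data$start)
      if (nrow(f) > 1) {
        overlap <- f$start[-1] <= f$end[-nrow(f)]
        conflict <- overlap & (f$type[-1] != f$type[-nrow(f)])
        if (any(conflict)) {
          abort(sprintf("overlapping planted features of conflicting type on %s", p))
        }
      }
    }
  }
  structure(
    list(seed = as.integer(seed), parts = as_tibble(parts),
         lambda = lambda, variant_rate_kbp = variant_rate_kbp,
         hom_fraction = hom_fraction,
         high_qual_fraction = high_qual_fraction,
         features = features, accession = accession),
    class = "sim_config"
  )
}

#' The shipped benchmark configuration for planted-feature recovery
#'
#' One 10-Mbp part at baseline depth 10 with three planted features, all
#' aligned to the window grids so boundary recovery is measurable: a
#' 60-kbp deletion, a 600-kbp high-variant-density haplotype block, and a
#' 200-kbp two-fold copy-number gain.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
recovery_sim_config <- function(seed = 1) {
  sim_config(
    seed = seed,
    parts = tibble(part = "synth1_part1", length = 1e7),
    lambda = 10,
    features = tibble(
      type = c("deletion", "haplotype_block", "cnv_gain"),
      part = "synth1_part1",
      start = c(2000001, 7000001, 5000001),
      end = c(2060000, 7600000, 5200000)
    )
  )
}

# Piecewise-constant per-base segments of (multiplier, rate) for one part.
feature_segments <- function(config, part) {
  plen <- config$parts$length[config$parts$part == part]
  f <- config$features[config$features$part == part, ]
  cuts <- sort(unique(c(1, plen + 1, f$start, f$end + 1)))
  cuts <- cuts[cuts >= 1 & cuts <= plen + 1]
  seg <- tibble(
    start = cuts[-length(cuts)],
    end = cuts[-1] - 1,
    multiplier = 1,
    rate_kbp = config$variant_rate_kbp
  )
  for (i in seq_len(nrow(f))) {
    hit <- seg$start >= f$start[i] & seg$end <= f$end[i]
    seg$multiplier[hit] <- seg$multiplier[hit] * f$multiplier[i]
    seg$rate_kbp[hit] <- f$rate_kbp[i]
  }
  seg
}

#' Simulate a panel from a configuration
#'
#' Draws per-base depths (Poisson with the planted piecewise rates) and
#' variant records (spatial Poisson process with per-feature rates,
#' random ref/alt bases, QUAL and genotype per the configured fractions)
#' for each part, and records every planted interval in a truth table.
#' The same seed yields identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `profiles` (named list of
#'   [coverage_profile()] per part), `variants` (classified records,
#'   [classify_variants()] columns), `truth` (tibble `accession`, `part`,
#'   `start`, `end` 0-based half-open, `type`), `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    profiles <- list()
    variants <- list()
    for (p in config$parts$part) {
      seg <- feature_segments(config, p)
      depth <- unlist(map(seq_len(nrow(seg)), function(i) {
        n <- seg$end[i] - seg$start[i] + 1
        rpois(n, config$lambda * seg$multiplier[i])
      }))
      profiles[[p]] <- coverage_profile(p, depth)

      pos <- unlist(map(seq_len(nrow(seg)), function(i) {
        n <- seg$end[i] - seg$start[i] + 1
        k <- rpois(1, n * seg$rate_kbp[i] / 1000)
        if (k == 0) return(numeric(0))
        seg$start[i] - 1 + sample.int(n, min(k, n))
      }))
      pos <- sort(unique(pos))
      nv <- length(pos)
      if (nv > 0) {
        bases <- c("A", "C", "G", "T")
        ref_i <- sample.int(4, nv, replace = TRUE)
        alt <- bases[(ref_i - 1 + sample.int(3, nv, replace = TRUE)) %% 4 + 1]
        ref <- bases[ref_i]
        hom <- runif(nv) < config$hom_fraction
        high <- runif(nv) < config$high_qual_fraction
        variants[[p]] <- tibble(
          part = p, pos = pos, ref = ref, alt = alt,
          qual = ifelse(high, runif(nv, 20, 200), runif(nv, 0, 19.99)),
          gt = ifelse(hom, "1/1", "0/1")
        )
      }
    }
    vr <- list_rbind(variants)
    if (is.null(vr) || nrow(vr) == 0) {
      vr <- tibble(part = character(), pos = numeric(), ref = character(),
                   alt = character(), qual = numeric(), gt = character())
    }
    list(
      profiles = profiles,
      variants = classify_variants(vr),
      truth = tibble(
        accession = config$accession,
        part = config$features$part,
        start = config$features$start - 1,
        end = config$features$end,
        type = config$features$type
      ),
      config = config
    )
  })
}

#' Run the anomaly callers on a simulated panel and label the calls
#'
#' Convenience pipeline for recovery benchmarking: computes accession
#' depth statistics, calls coverage anomalies (on mean-depth windows of
#' `cov_window` bp; see the package vignette for why per-base exceedance
#' is not advisable at shallow depth) and density anomalies, and maps
#' call directions onto planted-feature types (`Low` coverage ->
#' `deletion`, `High` coverage -> `cnv_gain`, `High` density ->
#' `haplotype_block`).
#'
#' @param panel Output of [simulate_panel()].
#' @param cov_window Window width for coverage exceedance (default
#'   1000 bp).
#' @param k,merge_gap,min_len_high,min_len_low Coverage rule parameters,
#'   see [call_coverage_anomalies()].
#' @param density_window,density_merge_gap,density_min_len Density rule
#'   parameters, see [call_density_anomalies()].
#' @return A tibble of labelled calls: `accession`, `part`, `start`,
#'   `end`, `type`, `direction`, `source`.
#' @export
recover_planted_features <- function(panel, cov_window = 1000, k = 2,
                                     merge_gap = 500,
                                     min_len_high = 5000,
                                     min_len_low = 50000,
                                     density_window = 10000,
                                     density_merge_gap = 40000,
                                     density_min_len = 500000) {
  cov_stats <- depth_stats(panel$profiles)
  part_lengths <- setNames(panel$config$parts$length,
                           panel$config$parts$part)
  track <- variant_density(panel$variants, window = density_window,
                           part_lengths = part_lengths)
  dens_stats <- density_stats(track)

  calls <- list()
  for (p in names(panel$profiles)) {
    cov <- call_coverage_anomalies(panel$profiles[[p]], cov_stats,
                                   k = k, merge_gap = merge_gap,
                                   min_len_high = min_len_high,
                                   min_len_low = min_len_low,
                                   window = cov_window)
    if (nrow(cov) > 0) {
      cov$type <- ifelse(cov$direction == "High", "cnv_gain", "deletion")
      cov$source <- "coverage"
      calls[[paste0(p, ".cov")]] <-
        cov[, c("part", "start", "end", "type", "direction", "source")]
    }
    den <- call_density_anomalies(track[track$part == p, ], k = k,
                                  merge_gap = density_merge_gap,
                                  min_len = density_min_len,
                                  stats = dens_stats)
    den <- den[den$direction == "High", ]
    if (nrow(den) > 0) {
      den$type <- "haplotype_block"
      den$source <- "density"
      calls[[paste0(p, ".den")]] <-
        den[, c("part", "start", "end", "type", "direction", "source")]
    }
  }
  out <- list_rbind(calls)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(accession = character(), part = character(),
                  start = numeric(), end = numeric(), type = character(),
                  direction = character(), source = character()))
  }
  out$accession <- panel$config$accession
  out[, c("accession", "part", "start", "end", "type", "direction",
          "source")]
}

#' Score recovery of planted features
#'
#' A truth feature is recovered when a call of matching `type` on the
#' same part overlaps it with reciprocal overlap of at least
#' `min_reciprocal` (overlap / truth length and overlap / call length
#' both at or above the cut).  Matching is greedy by overlap size; each
#' call matches at most one truth feature.
#'
#' @param calls Tibble of calls: `part`, `start`, `end`, `type` (0-based
#'   half-open).
#' @param truth Tibble of truth features, same columns.
#' @param min_reciprocal Reciprocal-overlap cut (default 0.5).
#' @return A one-row tibble: `recall`, `precision`,
#'   `mean_boundary_error` (bp, mean of `(|d start| + |d end|)/2` over
#'   matched pairs), `n_truth`, `n_calls`, `n_matched`.
#' @export
score_recovery <- function(calls, truth, min_reciprocal = 0.5) {
  check_columns(truth, c("part", "start", "end", "type"), "truth")
  check_columns(calls, c("part", "start", "end", "type"), "calls")
  n_truth <- nrow(truth); n_calls <- nrow(calls)
  matched_truth <- logical(n_truth)
  matched_call <- logical(n_calls)
  berr <- numeric(0)

  if (n_truth > 0 && n_calls > 0) {
    # all candidate pairs, best overlap first
    pairs <- list()
    for (i in seq_len(n_truth)) {
      for (j in seq_len(n_calls)) {
        if (truth$part[i] != calls$part[j] ||
            truth$type[i] != calls$type[j]) next
        ov <- min(truth$end[i], calls$end[j]) -
          max(truth$start[i], calls$start[j])
        if (ov <= 0) next
        if (ov / (truth$end[i] - truth$start[i]) >= min_reciprocal &&
            ov / (calls$end[j] - calls$start[j]) >= min_reciprocal) {
          pairs[[length(pairs) + 1]] <- c(i, j, ov)
        }
      }
    }
    if (length(pairs) > 0) {
      pm <- do.call(rbind, pairs)
      pm <- pm[order(-pm[, 3]), , drop = FALSE]
      for (r in seq_len(nrow(pm))) {
        i <- pm[r, 1]; j <- pm[r, 2]
        if (matched_truth[i] || matched_call[j]) next
        matched_truth[i] <- TRUE; matched_call[j] <- TRUE
        berr <- c(berr, (abs(truth$start[i] - calls$start[j]) +
                           abs(truth$end[i] - calls$end[j])) / 2)
      }
    }
  }
  tibble(
    recall = if (n_truth == 0) NA_real_ else mean(matched_truth),
    precision = if (n_calls == 0) NA_real_ else mean(matched_call),
    mean_boundary_error = if (length(berr) == 0) NA_real_ else mean(berr),
    n_truth = n_truth, n_calls = n_calls, n_matched = sum(matched_truth)
  )
}

#' Simulate aligned reads over a reference sequence
#'
#' Read-level companion to the direct Poisson depth draw: emits perfectly
#' mapped fixed-length reads at Poisson density over one part, optionally
#' carrying alternative bases at chosen sites, for exercising the SAM/BAM
#' code path end to end.
#'
#' @param reference Reference sequence of the part (character string).
#' @param part Part name.
#' @param lambda Target mean depth.
#' @param read_length Read length in bp (default 100).
#' @param alt_sites Optional tibble `pos`, `base`, `fraction`: each read
#'   covering `pos` carries `base` there with probability `fraction`.
#' @param mapq MAPQ assigned to every read (default 60).
#' @return A coordinate-sorted alignments tibble (same columns as
#'   [read_alignments()]).
#' @export
simulate_reads <- function(reference, part, lambda, read_length = 100,
                           alt_sites = NULL, mapq = 60) {
  L <- nchar(reference)
  if (L < read_length) abort("reference shorter than read length")
  n_reads <- rpois(1, lambda * L / read_length)
  starts <- sort(sample.int(L - read_length + 1, n_reads, replace = TRUE))
  seqs <- substring(reference, starts, starts + read_length - 1)
  if (!is.null(alt_sites)) {
    check_columns(alt_sites, c("pos", "base", "fraction"), "alt_sites")
    for (i in seq_len(nrow(alt_sites))) {
      covers <- which(starts <= alt_sites$pos[i] &
                        starts + read_length - 1 >= alt_sites$pos[i])
      flip <- covers[runif(length(covers)) < alt_sites$fraction[i]]
      off <- alt_sites$pos[i] - starts[flip] + 1
      substring(seqs[flip], off, off) <- alt_sites$base[i]
    }
  }
  tibble(
    qname = sprintf("read%06d", seq_len(n_reads)),
    flag = 0L,
    part = part,
    pos = as.numeric(starts),
    mapq = as.integer(mapq),
    cigar = paste0(read_length, "M"),
    seq = seqs
  )
}

#' Write an alignments tibble as a SAM file
#'
#' Serialises the in-memory alignment representation to plain-text SAM
#' (with `@SQ` headers from `part_lengths`) so fixtures can flow through
#' the same Rsamtools reading path as real data.
#'
#' @param alignments Alignments tibble (columns as [read_alignments()];
#'   `seq` optional).
#' @param path Output path ending in `.sam`.
#' @param part_lengths Named vector of reference part lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, part_lengths) {
  check_columns(alignments, c("qname", "flag", "part", "pos", "mapq",
                              "cigar"), "alignments")
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(part_lengths),
            as.integer(part_lengths))
  )
  aln <- alignments %>% arrange(.data$part, .data$pos)
  seqs <- if ("seq" %in% names(aln)) aln$seq else
    strrep("N", cigar_query_length(aln$cigar))
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  aln$qname, aln$flag, aln$part, as.integer(aln$pos),
                  aln$mapq, aln$cigar, seqs)
  writeLines(c(header, recs), path)
  invisible(path)
}

# Query (read) length implied by a CIGAR string.
cigar_query_length <- function(cigar) {
  ops <- cigar_ops(cigar)
  consumes <- ops$op %in% c("M", "=", "X", "I", "S")
  vapply(split(ops$len * consumes, ops$rec), sum, numeric(1))[
    as.character(seq_along(cigar))]
}

#' Generate a random reference sequence
#'
#' @param length Sequence length in bp.
#' @param gc GC content (default 0.46, wheat-like).
#' @return A character string of A/C/G/T.
#' @export
random_reference <- function(length, gc = 0.46) {
  paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
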