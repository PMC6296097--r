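# Independent oracles and fixture builders shared across tests.
# Oracles deliberately avoid the package's own code paths.

# O(n^2) brute-force segmentation: scan for seed runs, repeatedly merge
# the closest same-direction pair until fixpoint, then length-filter.
brute_force_segment <- function(status, unit_start, unit_end,
                                merge_gap, min_high, min_low) {
  runs <- list()
  i <- 1
  n <- length(status)
  while (i <= n) {
    if (status[i] != 0) {
      j <- i
      while (j < n && status[j + 1] == status[i]) j <- j + 1
      runs[[length(runs) + 1]] <- list(start = unit_start[i],
                                       end = unit_end[j],
                                       dir = status[i])
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  repeat {
    merged <- FALSE
    if (length(runs) >= 2) {
      for (a in seq_len(length(runs) - 1)) {
        for (b in (a + 1):length(runs)) {
          ra <- runs[[a]]; rb <- runs[[b]]
          if (ra$dir != rb$dir) next
          gap <- max(ra$start, rb$start) - min(ra$end, rb$end)
          if (gap <= merge_gap) {
            runs[[a]] <- list(start = min(ra$start, rb$start),
                              end = max(ra$end, rb$end), dir = ra$dir)
            runs[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  keep <- Filter(function(r) {
    len <- r$end - r$start
    if (r$dir > 0) len >= min_high else len >= min_low
  }, runs)
  if (length(keep) == 0) {
    return(data.frame(start = numeric(), end = numeric(),
                      direction = character()))
  }
  out <- data.frame(
    start = vapply(keep, `[[`, numeric(1), "start"),
    end = vapply(keep, `[[`, numeric(1), "end"),
    direction = ifelse(vapply(keep, `[[`, numeric(1), "dir") > 0,
                       "High", "Low")
  )
  out[order(out$start), , drop = FALSE]
}

# Depth vector encoding an exceedance string for stats mean 10, sd 1, k=2:
# +1 -> 20, -1 -> 0, 0 -> 10.
depth_from_status <- function(status) {
  c(20L, 10L, 0L)[match(status, c(1L, 0L, -1L))]
}
fixed_stats <- function() data.frame(mean = 10, sd = 1)

# Random valid partition scheme.
random_scheme <- function(n_chrom = 3, max_parts = 4, max_len = 5000) {
  rows <- lapply(seq_len(n_chrom), function(i) {
    L <- sample(50:max_len, 1)
    k <- sample(seq_len(min(max_parts, L)), 1)
    cuts <- sort(sample(seq_len(L - 1), k - 1))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, L)
    data.frame(chrom = sprintf("chr%d", i), start = starts, end = ends)
  })
  partition_scheme(do.call(rbind, rows))
}

# Naive per-base liftover: scan the scheme rows one by one.
naive_to_part <- function(scheme, chrom, position) {
  for (r in seq_len(nrow(scheme))) {
    if (scheme$chrom[r] == chrom && scheme$start[r] <= position &&
        scheme$end[r] >= position) {
      return(list(part = scheme$part[r],
                  part_position = position - scheme$start[r] + 1))
    }
  }
  stop("not found")
}

# Micro-SAM fixture on a small reference; returns list(sam, fasta, ref).
make_micro_sam <- function(dir, part = "toy_part1", ref_len = 300,
                           lambda = 4, read_length = 20,
                           alt_sites = NULL, seed = 1) {
  withr::with_seed(seed, {
    ref <- random_reference(ref_len)
    aln <- simulate_reads(ref, part, lambda, read_length,
                          alt_sites = alt_sites)
  })
  sam <- file.path(dir, "micro.sam")
  fa <- file.path(dir, "micro.fa")
  write_sam(aln, sam, setNames(ref_len, part))
  write_fasta(setNames(ref, part), fa)
  list(sam = sam, fasta = fa, ref = ref, alignments = aln)
}

# Random VCF-like record tibble.
random_records <- function(n, part = "p1", max_pos = 1e6, seed = NULL) {
  gen <- function() {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    # a few indels and multiallelics
    kind <- runif(n)
    alt[kind < 0.05] <- paste0(alt[kind < 0.05], "A")
    alt[kind > 0.95] <- paste0(alt[kind > 0.95], ",G")
    tibble::tibble(
      part = part,
      pos = sort(sample.int(max_pos, n, replace = TRUE)),
      ref = ref, alt = alt,
      qual = runif(n, 0, 60),
      gt = sample(c("0/0", "0/1", "1/1", "1/2", "1|1"), n, replace = TRUE)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
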