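test_that("MAPQ filtering keeps records at the threshold and drops below", {
  aln <- tibble::tibble(
    qname = paste0("r", 1:5),
    flag = c(0L, 0L, 4L, 0L, 0L),
    part = "p", pos = c(1, 2, NA, 3, 4),
    mapq = c(4L, 5L, 60L, 30L, 0L),
    cigar = "10M"
  )
  out <- filter_alignments(aln, min_mapq = 5)
  expect_equal(out$qname, c("r2", "r4"))   # MAPQ 4 removed, 5 kept
  expect_equal(nrow(filter_alignments(aln[0, ])), 0)
})

test_that("filtered count equals a naive count on random MAPQ vectors", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      n <- sample.int(200, 1)
      aln <- tibble::tibble(
        qname = paste0("r", seq_len(n)), flag = 0L, part = "p",
        pos = seq_len(n),
        mapq = sample(0:60, n, replace = TRUE), cigar = "5M"
      )
      thr <- sample(0:60, 1)
      expect_equal(nrow(filter_alignments(aln, thr)),
                   sum(aln$mapq >= thr))
    }
  })
})

test_that("malformed mapped records are skipped with a warning", {
  aln <- tibble::tibble(qname = c("a", "b"), flag = 0L, part = "p",
                        pos = c(1, 2), mapq = 60L,
                        cigar = c("10M", "*"))
  expect_warning(out <- filter_alignments(aln), "1 malformed")
  expect_equal(out$qname, "a")
})

test_that("mapq_table cumulates counts from high MAPQ down", {
  aln <- tibble::tibble(mapq = c(0L, 5L, 5L, 30L))
  tab <- mapq_table(aln)
  expect_equal(tab$mapq, c(30L, 5L, 0L))
  expect_equal(tab$cum_n, c(1L, 3L, 4L))
  expect_equal(tab$cum_n[tab$mapq == 5], 3L)
  expect_equal(tab$pct_aligned, c(25, 75, 100))

  one <- mapq_table(tibble::tibble(mapq = rep(17L, 8)))
  expect_equal(nrow(one), 1)
  expect_equal(one$pct_aligned, 100)

  # raw-read denominator
  tab2 <- mapq_table(aln, raw_total = 8)
  expect_equal(tab2$pct_raw, c(12.5, 37.5, 50))
})

test_that("cumulative column equals a suffix-sum oracle", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      mapq <- sample(0:60, sample.int(300, 1), replace = TRUE)
      tab <- mapq_table(tibble::tibble(mapq = mapq))
      oracle <- vapply(tab$mapq, function(q) sum(mapq >= q), 1L)
      expect_equal(tab$cum_n, oracle)
    }
  })
})

test_that("depth counts aligned reference spans only", {
  aln <- tibble::tibble(
    qname = c("a", "b"), flag = 0L, part = "p",
    pos = c(10, 15), mapq = 60L, cigar = c("10M", "10M")
  )
  prof <- depth_profile(aln, "p", 40)
  expect_equal(prof$depth[10:19], c(rep(1L, 5), rep(2L, 5)))
  expect_equal(prof$depth[20:24], rep(1L, 5))
  expect_equal(sum(prof$depth), 20)

  # deletion and soft clip do not cover
  aln2 <- tibble::tibble(qname = "c", flag = 0L, part = "p", pos = 5,
                         mapq = 60L, cigar = "3S4M2D3M")
  prof2 <- depth_profile(aln2, "p", 20)
  expect_equal(which(prof2$depth == 1L), c(5:8, 11:13))

  expect_error(
    depth_profile(tibble::tibble(qname = c("a", "b"), flag = 0L,
                                 part = "p", pos = c(9, 2), mapq = 60L,
                                 cigar = "4M"), "p", 20),
    "sorted"
  )
})

test_that("depth matches the Rsamtools pileup on a simulated micro-SAM", {
  dir <- withr::local_tempdir()
  fx <- make_micro_sam(dir, ref_len = 400, lambda = 6, seed = 31)
  aln <- filter_alignments(read_alignments(fx$sam), min_mapq = 5)
  prof <- depth_profile(aln, "toy_part1", 400)

  bam <- Rsamtools::asBam(fx$sam, destination = tempfile(),
                          overwrite = TRUE)
  pu <- Rsamtools::pileup(
    bam,
    pileupParam = Rsamtools::PileupParam(
      distinguish_nucleotides = FALSE, distinguish_strands = FALSE,
      min_mapq = 5, min_base_quality = 0, min_nucleotide_depth = 0,
      max_depth = 10000
    )
  )
  oracle <- integer(400)
  oracle[pu$pos] <- pu$count
  expect_equal(prof$depth, oracle)
})

test_that("depth statistics are mean and population SD of unmasked bases", {
  expect_equal(depth_stats(coverage_profile("p", rep(7, 100)))$sd, 0)
  expect_equal(depth_stats(coverage_profile("p", rep(7, 100)))$mean, 7)
  s <- depth_stats(coverage_profile("p", rep(c(0L, 10L), 50)))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 5)   # population, not sample, SD

  masked <- coverage_profile("p", c(0L, 0L, 8L, 8L),
                             mask = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(depth_stats(masked)$mean, 8)
  expect_equal(depth_stats(masked)$n, 2)
  all_masked <- coverage_profile("p", 1:3, mask = rep(TRUE, 3))
  expect_error(depth_stats(all_masked), "masked")

  withr::with_seed(19, {
    for (rep in 1:10) {
      d <- rpois(sample.int(1000, 1), 8)
      s <- depth_stats(coverage_profile("p", d))
      mu <- sum(d) / length(d)                     # two-pass oracle
      expect_equal(s$mean, mu, tolerance = 1e-9)
      expect_equal(s$sd, sqrt(sum((d - mu)^2) / length(d)),
                   tolerance = 1e-9)
    }
  })
})

test_that("coverage anomaly segmentation merges, filters and sorts per the rule", {
  st <- fixed_stats()  # mean 10, sd 1, k = 2 thresholds at 12 / 8

  # two 3 kbp High runs 400 bp apart merge into one 6.4 kbp region
  status <- c(rep(1L, 3000), rep(0L, 400), rep(1L, 3000))
  prof <- coverage_profile("p", depth_from_status(status))
  out <- call_coverage_anomalies(prof, st)
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, "High")
  expect_equal(out$length, 6400)
  expect_equal(c(out$start, out$end), c(0, 6400))

  # constant profile -> nothing
  expect_equal(
    nrow(call_coverage_anomalies(coverage_profile("p", rep(10L, 5000)),
                                 st)),
    0
  )
})

test_that("High and Low calls are disjoint and regions never overlap", {
  withr::with_seed(23, {
    st <- fixed_stats()
    for (rep in 1:10) {
      status <- sample(c(-1L, 0L, 1L), 5000, replace = TRUE,
                       prob = c(0.2, 0.6, 0.2))
      out <- call_coverage_anomalies(
        coverage_profile("p", depth_from_status(status)), st,
        merge_gap = 20, min_len_high = 30, min_len_low = 30
      )
      for (dir in c("High", "Low")) {
        r <- out[out$direction == dir, ]
        if (nrow(r) > 1) expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
      }
    }
  })
})

test_that("anomaly calls agree with the brute-force oracle on random vectors", {
  withr::with_seed(29, {
    st <- fixed_stats()
    for (rep in 1:60) {
      n <- sample.int(2000, 1)
      status <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                       prob = c(0.15, 0.7, 0.15))
      mg <- sample.int(30, 1)
      mh <- sample.int(60, 1); ml <- sample.int(120, 1)
      out <- call_coverage_anomalies(
        coverage_profile("p", depth_from_status(status)), st,
        merge_gap = mg, min_len_high = mh, min_len_low = ml
      )
      oracle <- brute_force_segment(status, 0:(n - 1), 1:n, mg, mh, ml)
      expect_equal(nrow(out), nrow(oracle))
      if (nrow(out) > 0) {
        expect_equal(out$start, oracle$start)
        expect_equal(out$end, oracle$end)
        expect_equal(out$direction, oracle$direction)
      }
    }
  })
})

test_that("merging is idempotent and thresholds act monotonically", {
  withr::with_seed(37, {
    st <- fixed_stats()
    status <- sample(c(-1L, 0L, 1L), 3000, replace = TRUE,
                     prob = c(0.1, 0.8, 0.1))
    prof <- coverage_profile("p", depth_from_status(status))
    base <- call_coverage_anomalies(prof, st, merge_gap = 10,
                                    min_len_high = 20, min_len_low = 20)
    # growing the merge gap never shrinks total reported bases
    prev <- sum(base$end - base$start)
    for (mg in c(20, 40, 80)) {
      cur <- call_coverage_anomalies(prof, st, merge_gap = mg,
                                     min_len_high = 20, min_len_low = 20)
      tot <- sum(cur$end - cur$start)
      expect_gte(tot, prev)
      prev <- tot
    }
    # raising min length never adds regions
    prev_n <- nrow(base)
    for (ml in c(40, 80, 160)) {
      cur <- call_coverage_anomalies(prof, st, merge_gap = 10,
                                     min_len_high = ml, min_len_low = ml)
      expect_lte(nrow(cur), prev_n)
      prev_n <- nrow(cur)
    }
  })
})

test_that("masked positions break seed runs but count toward the merge gap", {
  st <- fixed_stats()
  depth <- rep(20L, 100)
  mask <- rep(FALSE, 100); mask[41:45] <- TRUE
  out <- call_coverage_anomalies(coverage_profile("p", depth, mask), st,
                                 merge_gap = 10, min_len_high = 50,
                                 min_len_low = 50)
  expect_equal(nrow(out), 1)           # re-merged across the masked gap
  expect_equal(c(out$start, out$end), c(0, 100))
  out2 <- call_coverage_anomalies(coverage_profile("p", depth, mask), st,
                                  merge_gap = 3, min_len_high = 60,
                                  min_len_low = 60)
  expect_equal(nrow(out2), 0)          # unmerged runs of 40/55 bp < 60
})

test_that("windowed exceedance mode window-aligns region bounds", {
  st <- fixed_stats()
  depth <- c(rep(10L, 1000), rep(20L, 2000), rep(10L, 1000))
  out <- call_coverage_anomalies(coverage_profile("p", depth), st,
                                 window = 100, min_len_high = 500,
                                 min_len_low = 500)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(1000, 3000))
  expect_equal(out$start %% 100, 0)
})

test_that("zero-SD statistics seed every off-mean position", {
  st <- data.frame(mean = 10, sd = 0)
  depth <- c(rep(10L, 50), rep(11L, 60), rep(10L, 50))
  out <- call_coverage_anomalies(coverage_profile("p", depth), st,
                                 merge_gap = 5, min_len_high = 10,
                                 min_len_low = 10)
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, "High")
  expect_equal(out$length, 60)
})
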