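rec <- function(pos = 1, ref = "A", alt = "T", qual = 30, gt = "1/1") {
  tibble::tibble(part = "p", pos = pos, ref = ref, alt = alt,
                 qual = qual, gt = gt)
}

test_that("quality and zygosity map onto the four track classes", {
  r <- dplyr::bind_rows(
    rec(qual = 30, gt = "1/1"),   # PASS
    rec(qual = 30, gt = "0/1"),   # Het
    rec(qual = 10, gt = "1/1"),   # LowQualHom
    rec(qual = 10, gt = "0/1"),   # LowQualHet
    rec(qual = 20, gt = "1|1"),   # threshold inclusive, phased GT
    rec(qual = 30, gt = "1/2")    # het with two alt alleles
  )
  out <- classify_variants(r, qual_threshold = 20)
  expect_equal(out$class, c("PASS", "Het", "LowQualHom", "LowQualHet",
                            "PASS", "Het"))
})

test_that("kind and display colour follow allele structure", {
  r <- dplyr::bind_rows(
    rec(alt = "T"),              # SNV, red
    rec(alt = "G"),              # SNV, yellow
    rec(ref = "AT", alt = "A"),  # indel, black
    rec(alt = "T,G")             # multiallelic, black
  )
  out <- classify_variants(r)
  expect_equal(out$kind, c("SNV", "SNV", "indel", "multiallelic"))
  expect_equal(out$colour, c("red", "yellow", "black", "black"))
})

test_that("records without genotype are skipped with a warning", {
  r <- dplyr::bind_rows(rec(), rec(gt = "./."), rec(gt = NA))
  expect_warning(out <- classify_variants(r), "skipped 2")
  expect_equal(nrow(out), 1)
})

test_that("the four classes partition any record set", {
  withr::with_seed(59, {
    r <- random_records(5000)
    out <- classify_variants(r)
    expect_true(all(out$class %in%
                      c("PASS", "Het", "LowQualHom", "LowQualHet")))
    expect_equal(sum(table(out$class)), nrow(out))
    expect_equal(nrow(out), nrow(r))   # all GTs here are called
    # deterministic: same input, same classes
    expect_identical(classify_variants(r)$class, out$class)
  })
})

test_that("density windows are anchored at 1 and counts are conserved", {
  r <- classify_variants(dplyr::bind_rows(
    rec(pos = 1), rec(pos = 500), rec(pos = 9999), rec(pos = 10000),
    rec(pos = 10001),
    rec(pos = 3, qual = 30, gt = "0/1")     # Het: not counted by default
  ))
  track <- variant_density(r, window = 10000)
  expect_equal(track$count, c(4L, 1L))       # 10000 -> window 1; 10001 -> 2
  expect_equal(track$start, c(0, 10000))

  withr::with_seed(61, {
    r2 <- classify_variants(random_records(3000, max_pos = 250000))
    t2 <- variant_density(r2, window = 10000,
                          part_lengths = c(p1 = 250000))
    expect_equal(sum(t2$count),
                 sum(r2$class %in% c("PASS", "LowQualHom")))
    expect_equal(nrow(t2), 25)
    # shifting every position by one window shifts counts by one window
    r3 <- dplyr::mutate(r2, pos = pos + 10000)
    t3 <- variant_density(r3, window = 10000,
                          part_lengths = c(p1 = 260000))
    expect_equal(t3$count[-1], t2$count)
  })
})

test_that("terminal partial windows are flagged and excluded from stats", {
  r <- classify_variants(rec(pos = 25000))
  track <- variant_density(r, window = 10000, part_lengths = c(p = 25000))
  expect_equal(track$partial, c(FALSE, FALSE, TRUE))
  expect_equal(track$end[3], 25000)
  expect_equal(density_stats(track)$n, 2)
})

test_that("density anomaly thresholds follow the windowed rule exactly", {
  base <- rep(10L, 300)
  mk <- function(counts) {
    n <- length(counts)
    tibble::tibble(part = "p", win = seq_len(n),
                   start = (seq_len(n) - 1) * 10000,
                   end = seq_len(n) * 10000,
                   count = counts, partial = FALSE)
  }
  st <- data.frame(mean = 10, sd = 1)

  # 60 consecutive High windows (600 kbp) -> one region
  x <- base; x[101:160] <- 100L
  out <- call_density_anomalies(mk(x), stats = st)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(1000000, 1600000))

  # two 30-window blocks 4 windows (40 kbp) apart merge
  x <- base; x[c(101:130, 135:164)] <- 100L
  out <- call_density_anomalies(mk(x), stats = st)
  expect_equal(nrow(out), 1)
  expect_equal(out$length, 640000)

  # 49 isolated High windows (490 kbp) dropped
  x <- base; x[101:149] <- 100L
  expect_equal(nrow(call_density_anomalies(mk(x), stats = st)), 0)

  # uniform counts -> empty (and stats from the track itself)
  expect_equal(nrow(call_density_anomalies(mk(base))), 0)

  expect_error(call_density_anomalies(mk(base)[1, ]), "2 windows")
})

test_that("density anomalies agree with the brute-force oracle", {
  withr::with_seed(67, {
    st <- data.frame(mean = 10, sd = 1)
    for (rep in 1:40) {
      n <- sample(10:400, 1)
      status <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                       prob = c(0.2, 0.6, 0.2))
      counts <- c(100L, 10L, 0L)[match(status, c(1L, 0L, -1L))]
      track <- tibble::tibble(part = "p", win = seq_len(n),
                              start = (seq_len(n) - 1) * 10000,
                              end = seq_len(n) * 10000,
                              count = counts, partial = FALSE)
      mg <- sample.int(6, 1) * 10000
      ml <- sample.int(20, 1) * 10000
      out <- call_density_anomalies(track, merge_gap = mg, min_len = ml,
                                    stats = st)
      oracle <- brute_force_segment(status, track$start, track$end,
                                    mg, ml, ml)
      expect_equal(nrow(out), nrow(oracle))
      if (nrow(out) > 0) {
        expect_equal(out$start, oracle$start)
        expect_equal(out$end, oracle$end)
        expect_equal(out$direction, oracle$direction)
      }
    }
  })
})

test_that("density anomaly calls ignore non-counted variant classes", {
  withr::with_seed(71, {
    r <- random_records(2000, max_pos = 3e6)
    cl <- classify_variants(r)
    t1 <- variant_density(cl, part_lengths = c(p1 = 3e6))
    # add heterozygous low-quality records: counted classes unchanged
    extra <- random_records(1000, max_pos = 3e6)
    extra$gt <- "0/1"
    cl2 <- classify_variants(dplyr::bind_rows(r, extra))
    t2 <- variant_density(cl2, part_lengths = c(p1 = 3e6))
    expect_equal(t2$count, t1$count)
    expect_equal(
      call_density_anomalies(t2, min_len = 50000),
      call_density_anomalies(t1, min_len = 50000)
    )
  })
})

test_that("classified VCF output round-trips through a VCF parser", {
  withr::with_seed(73, {
    r <- classify_variants(random_records(50, max_pos = 1000))
    r$pos <- sort(sample.int(5000, 50))
    path <- withr::local_tempfile(fileext = ".vcf")
    write_classified_vcf(r, path)
    back <- read_vcf_records(path)
    expect_equal(back$pos, r$pos)
    expect_equal(back$ref, r$ref)
    expect_equal(back$gt, r$gt)
    expect_equal(classify_variants(back)$class, r$class)
  })
})
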