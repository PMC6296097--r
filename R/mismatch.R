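#' Pileup columns from filtered alignments
#'
#' Tallies, for every covered reference position of one part, the aligned
#' read bases (A/C/G/T), reads whose alignment deletes the position, and
#' insertions anchored immediately to its left.  This is the input to the
#' mismatch-site ("SNP coverage") screen, which works from raw alignment
#' mismatches rather than a variant-calling model.
#'
#' Column depth counts aligned bases plus deletion-spanning reads;
#' insertions occupy no reference base and are tallied separately at
#' their anchor (the last reference position consumed before the
#' insertion).  Read `N` bases are ignored.
#'
#' @param alignments MAPQ-filtered, coordinate-sorted alignments with
#'   `part`, `pos`, `cigar`, `seq` columns ([read_alignments()] +
#'   [filter_alignments()]).
#' @param reference Reference sequence of the part: a character string or
#'   anything coercible via `as.character` (e.g. one element of a
#'   `Biostrings::DNAStringSet`).
#' @param part Part name; records on other parts are ignored.
#' @return A tibble with one row per covered position: `part`, `pos`,
#'   `ref`, `A`, `C`, `G`, `T`, `ins`, `del`, `depth`
#'   (`= A + C + G + T + del`).
#' @export
pileup_columns <- function(alignments, reference, part) {
  check_columns(alignments, c("part", "pos", "cigar", "seq"), "alignments")
  aln <- alignments[alignments$part == part, ]
  if (nrow(aln) > 0 && is.unsorted(aln$pos)) {
    abort("alignments must be coordinate-sorted")
  }
  ref <- toupper(as.character(reference))
  ref_len <- nchar(ref)

  base_pos <- vector("list", nrow(aln))
  base_chr <- vector("list", nrow(aln))
  del_pos <- vector("list", nrow(aln))
  ins_pos <- vector("list", nrow(aln))

  for (i in seq_len(nrow(aln))) {
    ops <- cigar_ops(aln$cigar[i])
    rpos <- aln$pos[i]
    qpos <- 1L
    read <- strsplit(toupper(aln$seq[i]), "")[[1]]
    bp <- integer(0); bc <- character(0); dp <- integer(0); ip <- integer(0)
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        if (qpos + len - 1 > length(read)) {
          abort(sprintf("CIGAR %s inconsistent with read length for %s",
                        aln$cigar[i], aln$qname[i] %||% "<record>"))
        }
        bp <- c(bp, rpos:(rpos + len - 1))
        bc <- c(bc, read[qpos:(qpos + len - 1)])
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        ip <- c(ip, rpos - 1L)
        qpos <- qpos + len
      } else if (op == "D") {
        dp <- c(dp, rpos:(rpos + len - 1))
        rpos <- rpos + len
      } else if (op == "N") {
        rpos <- rpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      } # H, P: no cursor movement
    }
    base_pos[[i]] <- bp; base_chr[[i]] <- bc
    del_pos[[i]] <- dp; ins_pos[[i]] <- ip
  }

  bp <- unlist(base_pos); bc <- unlist(base_chr)
  dp <- unlist(del_pos); ip <- unlist(ins_pos)
  if (max(c(bp, dp, ip, 1L)) > ref_len) {
    abort("alignments extend beyond the reference sequence length")
  }

  if (length(bp) > 0) {
    keep <- bc %in% c("A", "C", "G", "T")
    bp <- bp[keep]; bc <- bc[keep]
  }
  all_pos <- sort(unique(c(bp, dp)))
  if (length(all_pos) == 0) {
    return(tibble(part = character(), pos = integer(), ref = character(),
                  A = integer(), C = integer(), G = integer(),
                  T = integer(), ins = integer(), del = integer(),
                  depth = integer()))
  }

  pos_f <- factor(bp, levels = all_pos)
  counts <- table(pos_f, factor(bc, levels = c("A", "C", "G", "T")))
  del_n <- table(factor(dp, levels = all_pos))
  ins_n <- table(factor(ip, levels = all_pos))

  out <- tibble(
    part = part,
    pos = as.integer(all_pos),
    ref = substring(ref, all_pos, all_pos),
    A = as.integer(counts[, "A"]),
    C = as.integer(counts[, "C"]),
    G = as.integer(counts[, "G"]),
    T = as.integer(counts[, "T"]),
    ins = as.integer(ins_n),
    del = as.integer(del_n)
  )
  out$depth <- out$A + out$C + out$G + out$T + out$del
  out[out$depth > 0, ]
}

mismatch_colours <- c(A = "green", T = "red", C = "blue",
                      G = "yellow", indel = "grey")

#' Call mismatch ("SNP coverage") sites from pileup columns
#'
#' A position is called when its depth is at least `min_depth` and the
#' fraction of non-reference evidence (non-reference bases plus
#' deletion-spanning reads, over column depth) strictly exceeds
#' `min_alt_frac`.  With the defaults this is the "more than 90%
#' alternative bases at >= 3 reads" screening rule.  Positions whose
#' reference base is `N` are never called.
#'
#' @param columns Pileup columns from [pileup_columns()].
#' @param min_depth Minimum column depth (default 3).
#' @param min_alt_frac Alternative-evidence fraction that must be
#'   strictly exceeded (default 0.9; a column at exactly 90% is not
#'   called).
#' @return A tibble of called sites: `part`, `pos`, `symbol` (dominant
#'   alternative: `A`/`C`/`G`/`T` or `indel`, ties broken
#'   `A < C < G < T < indel`), `alt_frac`, `depth`, `colour` (the track
#'   display class: A green, T red, C blue, G yellow, indel grey).
#' @export
call_mismatch_sites <- function(columns, min_depth = 3,
                                min_alt_frac = 0.90) {
  check_columns(columns, c("part", "pos", "ref", "A", "C", "G", "T",
                           "ins", "del", "depth"), "columns")
  columns <- as_tibble(columns)
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(columns[, bases])
  ref_idx <- match(columns$ref, bases)          # NA for ref N
  ref_count <- ifelse(is.na(ref_idx), 0L,
                      cnt[cbind(seq_len(nrow(columns)),
                                pmax(ref_idx, 1L))])
  alt_count <- columns$depth - ref_count
  alt_frac <- ifelse(columns$depth > 0, alt_count / columns$depth, 0)

  called <- columns$depth >= min_depth &
    alt_frac > min_alt_frac &
    !is.na(ref_idx)
  if (!any(called)) {
    return(tibble(part = character(), pos = integer(), symbol = character(),
                  alt_frac = numeric(), depth = integer(),
                  colour = character()))
  }

  idx <- which(called)
  # candidate tallies: non-reference bases and the indel class
  # (deletions + anchored insertions); fixed tie order A<C<G<T<indel
  tal <- cbind(cnt[idx, , drop = FALSE],
               indel = columns$del[idx] + columns$ins[idx])
  for (b in bases) {
    tal[columns$ref[idx] == b, b] <- -1L
  }
  symbol <- c(bases, "indel")[max.col(tal, ties.method = "first")]

  tibble(
    part = columns$part[idx],
    pos = columns$pos[idx],
    symbol = symbol,
    alt_frac = alt_frac[idx],
    depth = columns$depth[idx],
    colour = unname(mismatch_colours[symbol])
  )
}
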