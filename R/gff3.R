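#' GFF3 handling for the liftover pipeline
#'
#' Annotation files delivered with a partitioned assembly are addressed on
#' the full pseudomolecules and must be re-addressed to the parts before a
#' genome browser indexed per part can use them.  The functions here treat
#' the GFF3 attribute column as opaque text so that re-addressing preserves
#' it byte-for-byte (a re-encoding round trip through a structured parser
#' would not).
#'
#' @name gff3
NULL

gff3_cols <- c("seqid", "source", "type", "start", "end",
               "score", "strand", "phase", "attributes")

#' Read a GFF3 file into a tibble
#'
#' Feature rows become one tibble row each; `##`/`#` directive and comment
#' lines are kept in the `"directives"` attribute of the result so that
#' [write_gff3()] can restore them at the top of the file.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with the nine GFF3 columns (`start`, `end` numeric,
#'   everything else character).
#' @export
read_gff3 <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  is_meta <- startsWith(lines, "#") | lines == ""
  feats <- lines[!is_meta]
  if (length(feats) == 0) {
    df <- tibble(seqid = character(), source = character(),
                 type = character(), start = numeric(), end = numeric(),
                 score = character(), strand = character(),
                 phase = character(), attributes = character())
  } else {
    fields <- strsplit(feats, "\t", fixed = TRUE)
    bad <- lengths(fields) != 9
    if (any(bad)) {
      abort(sprintf("malformed GFF3: %d line(s) without 9 columns",
                    sum(bad)))
    }
    m <- do.call(rbind, fields)
    df <- tibble(
      seqid = m[, 1], source = m[, 2], type = m[, 3],
      start = as.numeric(m[, 4]), end = as.numeric(m[, 5]),
      score = m[, 6], strand = m[, 7], phase = m[, 8],
      attributes = m[, 9]
    )
  }
  attr(df, "directives") <- lines[is_meta & lines != ""]
  df
}

#' Write a tibble of GFF3 features back to disk
#'
#' @param features A tibble as returned by [read_gff3()].
#' @param path Output path.
#' @param directives Header lines to emit before the features; defaults to
#'   the `"directives"` attribute of `features` (or `"##gff-version 3"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, directives = NULL) {
  check_columns(features, gff3_cols, "features")
  directives <- directives %||% attr(features, "directives") %||%
    "##gff-version 3"
  body <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                  features$seqid, features$source, features$type,
                  as.integer(features$start), as.integer(features$end),
                  features$score, features$strand, features$phase,
                  features$attributes)
  writeLines(c(directives, body), path)
  invisible(path)
}

#' Re-address GFF3 features from pseudomolecule to part coordinates
#'
#' Every feature is assigned to the scheme part containing it and its
#' coordinates shifted to 1-based positions within that part.  The strand,
#' score, phase and attribute columns (hence `ID=`/`Parent=` relations) are
#' carried through untouched.
#'
#' A feature spanning a part boundary cannot be represented in part
#' coordinates.  By default this is a hard error naming the feature
#' (silent truncation would corrupt gene models); `mode = "clip"` instead
#' splits it into one feature per part, suffixing any `ID=` attribute with
#' `.p1`, `.p2`, ... in part order.
#'
#' @param features GFF3 features as a tibble ([read_gff3()]).
#' @param scheme A [partition_scheme()]; feature `seqid`s must be scheme
#'   chromosomes.
#' @param mode `"error"` (default) or `"clip"` for boundary-crossing
#'   features.
#' @return A tibble of features addressed in part coordinates (`seqid` is
#'   now the part name), same column set, original order (clip mode emits
#'   the pieces of a split feature consecutively).
#' @export
split_gff3 <- function(features, scheme, mode = c("error", "clip")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "partition_scheme"))
  check_columns(features, gff3_cols, "features")
  features <- as_tibble(features)
  dirs <- attr(features, "directives")

  unknown <- setdiff(unique(features$seqid), scheme$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("feature seqid(s) not in scheme: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (nrow(features) == 0) {
    attr(features, "directives") <- dirs
    return(features)
  }

  pieces <- map(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    ps <- scheme[scheme$chrom == f$seqid &
                   scheme$start <= f$end & scheme$end >= f$start, ]
    if (nrow(ps) == 0) {
      abort(sprintf("feature at %s:%d-%d outside chromosome bounds",
                    f$seqid, as.integer(f$start), as.integer(f$end)))
    }
    if (nrow(ps) > 1 && mode == "error") {
      abort(sprintf(
        "boundary-crossing feature %s at %s:%d-%d spans parts %s (use mode = \"clip\" to split)",
        gff3_attr(f$attributes, "ID") %||% "<no ID>",
        f$seqid, as.integer(f$start), as.integer(f$end),
        paste(ps$part, collapse = ", ")
      ))
    }
    out <- f[rep(1, nrow(ps)), ]
    out$seqid <- ps$part
    out$start <- pmax(f$start, ps$start) - ps$start + 1
    out$end <- pmin(f$end, ps$end) - ps$start + 1
    if (nrow(ps) > 1) {
      out$attributes <- vapply(seq_len(nrow(ps)), function(k) {
        gff3_suffix_id(f$attributes, paste0(".p", k))
      }, character(1))
    }
    out
  })
  out <- list_rbind(pieces)
  attr(out, "directives") <- dirs
  out
}

# Extract one attribute value from a raw GFF3 column-9 string (undecoded).
gff3_attr <- function(attributes, key) {
  m <- regmatches(
    attributes,
    regexpr(paste0("(^|;)", key, "=[^;]*"), attributes)
  )
  if (length(m) == 0 || m == "") return(NULL)
  sub(paste0("^;?", key, "="), "", m)
}

# Append a suffix to the ID= attribute value, leaving other attributes
# (including Parent=) byte-identical.
gff3_suffix_id <- function(attributes, suffix) {
  if (is.null(gff3_attr(attributes, "ID"))) return(attributes)
  sub("(^|;)(ID=[^;]*)", paste0("\\1\\2", suffix), attributes)
}

#' Percent-encode a string for use in a GFF3 attribute value
#'
#' GFF3 reserves `; = & ,` (and literal `%`, tabs and newlines) inside
#' attribute values; they must be percent-encoded.  [gff3_unescape()]
#' inverts the encoding.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x <- gsub("\n", "%0A", x, fixed = TRUE)
  x
}

#' @rdname gff3_escape
#' @export
gff3_unescape <- function(x) {
  utils::URLdecode(x)
}

#' Merge a functional-annotation table into gene models
#'
#' Gene models in GFF3 typically carry only structural attributes; the
#' functional annotation (descriptions, domain hits, GO terms, ...) is
#' delivered as a separate table keyed by gene ID.  This appends each
#' matched gene's table fields as properly percent-encoded GFF3
#' attributes; unmatched features pass through unchanged.
#'
#' @param features GFF3 features as a tibble ([read_gff3()]).
#' @param annotation A data frame whose first column is the gene ID key;
#'   every other column becomes one attribute (`<column name>=<encoded
#'   value>`).  Keys must be unique.
#' @return The features tibble with augmented `attributes`.
#' @export
merge_functional_annotations <- function(features, annotation) {
  check_columns(features, gff3_cols, "features")
  if (!is.data.frame(annotation) || ncol(annotation) < 1) {
    abort("annotation must be a data frame with a key column")
  }
  features <- as_tibble(features)
  if (nrow(annotation) == 0 || ncol(annotation) == 1) return(features)

  keys <- as.character(annotation[[1]])
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate annotation key(s): %s",
                  paste(dup, collapse = ", ")))
  }

  ids <- vapply(features$attributes,
                function(a) gff3_attr(a, "ID") %||% NA_character_,
                character(1), USE.NAMES = FALSE)
  hit <- match(ids, keys)
  todo <- which(!is.na(hit))
  if (length(todo) == 0) return(features)

  extra_cols <- names(annotation)[-1]
  for (i in todo) {
    row <- annotation[hit[i], ]
    vals <- vapply(extra_cols, function(cl) as.character(row[[cl]]),
                   character(1))
    keep <- !is.na(vals) & vals != ""
    if (!any(keep)) next
    extra <- paste0(gff3_escape(extra_cols[keep]), "=",
                    gff3_escape(vals[keep]), collapse = ";")
    features$attributes[i] <- paste0(features$attributes[i], ";", extra)
  }
  features
}
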