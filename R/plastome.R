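## Core plastome container and strand-/circularity-aware sequence access.
## Coordinates are 0-based half-open everywhere inside the package; GenBank's
## 1-based inclusive convention exists only at the I/O boundary. An interval
## with end <= start wraps the origin and has unwrapped length (L - start) + end.

#' Construct a plastome object
#'
#' A plastome is a circular (usually) annotated DNA sequence restricted to the
#' alphabet A, C, G, T, N, with an ordered feature table.
#'
#' @param id accession or name.
#' @param sequence DNA string; lowercase input is uppercased.
#' @param circular logical; plastomes default to circular.
#' @param features feature table as built by [feature_table()].
#' @param genus,species,subfamily taxonomy labels used by the cohort analyses.
#' @return an object of class `plastome` with fields `id`, `sequence`,
#'   `length`, `circular`, `features`, `genus`, `species`, `subfamily`.
#' @export
plastome <- function(id, sequence, circular = TRUE, features = feature_table(),
                     genus = "", species = "", subfamily = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("plastome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("plastome sequence restricted to A, C, G, T, N")
  L <- nchar(sequence)
  features <- validate_features(features, L, id)
  structure(list(id = id, sequence = sequence, length = L,
                 circular = circular, features = features,
                 genus = genus, species = species, subfamily = subfamily),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %d bp, %s, %d features (%s %s)\n",
              x$id, x$length, if (x$circular) "circular" else "linear",
              nrow(x$features), x$genus, x$species))
  invisible(x)
}

#' Build a feature table
#'
#' @param key character; one of gene, CDS, tRNA, rRNA, intron, misc.
#' @param label gene name (e.g. "ycf1", "ndhB").
#' @param strand +1 or -1.
#' @param intervals list of 2-column matrices of 0-based half-open intervals;
#'   an interval with `end <= start` wraps the origin.
#' @return data.frame with a list-column `intervals`, sorted by start, end,
#'   key, label.
#' @export
feature_table <- function(key = character(), label = character(),
                          strand = integer(), intervals = list()) {
  df <- data.frame(key = as.character(key), label = as.character(label),
                   strand = as.integer(strand), stringsAsFactors = FALSE)
  df$intervals <- lapply(intervals, function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    colnames(m) <- c("start", "end")
    m
  })
  df
}

validate_features <- function(features, L, id = "?") {
  if (nrow(features) == 0L) return(features)
  ok_keys <- c("gene", "CDS", "tRNA", "rRNA", "intron", "misc")
  bad <- setdiff(unique(features$key), ok_keys)
  if (length(bad)) stop("unknown feature key(s): ", paste(bad, collapse = ", "))
  for (i in seq_len(nrow(features))) {
    m <- features$intervals[[i]]
    if (any(m[, 1] < 0L | m[, 1] >= L | m[, 2] < 0L | m[, 2] > L))
      stop(sprintf("feature '%s' outside sequence bounds of %s",
                   features$label[i], id))
    if (any(m[, 2] == m[, 1] & m[, 2] != 0L) || any(m[, 1] == 0L & m[, 2] == 0L))
      stop(sprintf("feature '%s' has an empty interval", features$label[i]))
  }
  o <- order(vapply(features$intervals, function(m) m[1, 1], integer(1)),
             vapply(features$intervals, function(m) m[1, 2], integer(1)),
             features$key, features$label)
  features <- features[o, , drop = FALSE]
  rownames(features) <- NULL
  features
}

#' Unwrapped length of a 0-based half-open (possibly wrapping) interval
#' @param start,end interval bounds; `end <= start` wraps the origin.
#' @param L sequence length.
#' @export
interval_length <- function(start, end, L) {
  ifelse(end > start, end - start, (L - start) + end)
}

#' Reverse complement of a DNA string
#' @param seq DNA string over A, C, G, T, N.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract the sequence of a region, wrapping the origin when needed
#' @param p plastome.
#' @param start,end 0-based half-open bounds; `end <= start` wraps (requires a
#'   circular plastome).
#' @export
region_sequence <- function(p, start, end) {
  L <- p$length
  if (end > start) return(substr(p$sequence, start + 1L, end))
  if (!p$circular) stop("wrapping interval on a linear plastome")
  paste0(substr(p$sequence, start + 1L, L), substr(p$sequence, 1L, end))
}

#' Sequence of a feature, strand- and origin-aware
#'
#' Concatenates the feature's intervals in stored order (wrapping intervals
#' resolved through the origin) and reverse-complements the result for
#' minus-strand features.
#'
#' @param p plastome containing the feature.
#' @param f one-row slice of `p$features`, or an integer row index.
#' @export
feature_sequence <- function(p, f) {
  if (is.numeric(f)) f <- p$features[f, , drop = FALSE]
  if (nrow(f) != 1L) stop("feature_sequence expects a single feature")
  member <- any(vapply(seq_len(nrow(p$features)), function(i)
    identical(p$features$intervals[[i]], f$intervals[[1]]) &&
      p$features$label[i] == f$label && p$features$key[i] == f$key,
    logical(1)))
  if (!member) stop("feature does not belong to this plastome")
  m <- f$intervals[[1]]
  s <- paste0(vapply(seq_len(nrow(m)), function(i)
    region_sequence(p, m[i, 1], m[i, 2]), character(1)), collapse = "")
  if (f$strand == -1L) s <- revcomp(s)
  s
}

#' GC content in percent
#'
#' N bases are excluded from both numerator and denominator. The unrounded
#' value is returned; reports round to 2 decimals.
#'
#' @param seq DNA string.
#' @export
gc_content <- function(seq) {
  gc <- nchar(gsub("[^GCgc]", "", seq))
  acgt <- nchar(gsub("[^ACGTacgt]", "", seq))
  if (acgt == 0L) stop("gc_content undefined: no A/C/G/T bases")
  100 * gc / acgt
}

## case-insensitive gene-label matching with a small synonym table
label_synonyms <- c("ycf1a" = "ycf1", "ycf1b" = "ycf1")

norm_label <- function(x) {
  y <- tolower(trimws(x))
  hit <- match(y, names(label_synonyms))
  y[!is.na(hit)] <- unname(label_synonyms[hit[!is.na(hit)]])
  y
}

#' Test gene-label identity (case-insensitive, synonym-aware)
#' @param a,b gene labels.
#' @export
same_gene <- function(a, b) norm_label(a) == norm_label(b)
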