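## GenBank flat-file reader/writer. Only the pieces a plastome pipeline needs:
## LOCUS (name, length, circular), the feature table with join()/complement()
## locations, /gene qualifiers, and the ORIGIN sequence. 1-based inclusive
## coordinates are converted to 0-based half-open at this boundary, and join
## pieces that abut across the origin of a circular record are normalized into
## a single wrapping interval.

CAPTURED_KEYS <- c("gene", "CDS", "tRNA", "rRNA", "intron")

#' Read an annotated plastome from a GenBank flat file
#'
#' @param path file path.
#' @param genus,species,subfamily optional taxonomy overrides; when missing,
#'   genus/species are taken from the ORGANISM line if present.
#' @return a [plastome()] object.
#' @export
read_genbank <- function(path, genus = NULL, species = NULL, subfamily = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("format error: no LOCUS line in ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(tolower(locus) == "circular") ||
    !any(tolower(locus) == "linear")  # plastomes default to circular
  org_i <- grep("^\\s+ORGANISM", lines)
  if (length(org_i) && (is.null(genus) || is.null(species))) {
    org <- strsplit(trimws(sub("^\\s+ORGANISM\\s+", "", lines[org_i[1]])), "\\s+")[[1]]
    if (is.null(genus)) genus <- if (length(org) >= 1) org[1] else ""
    if (is.null(species)) species <- if (length(org) >= 2) org[2] else ""
  }
  if (is.null(genus)) genus <- ""
  if (is.null(species)) species <- ""

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("format error: no ORIGIN sequence in ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("format error: empty ORIGIN sequence in ", path)
  L <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  features <- feature_table()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    features <- parse_feature_block(block, L, circular)
  }
  plastome(id = id, sequence = sequence, circular = circular,
           features = features, genus = genus, species = species,
           subfamily = subfamily)
}

parse_feature_block <- function(block, L, circular) {
  keys <- character(); labels <- character(); strands <- integer()
  ivs <- list()
  i <- 1L; n <- length(block)
  while (i <= n) {
    line <- block[i]
    key <- trimws(substr(line, 1, 20))
    if (key == "" || substr(trimws(line), 1, 1) == "/") { i <- i + 1L; next }
    loc <- trimws(substr(line, 21, nchar(line)))
    i <- i + 1L
    # location may continue over lines until a qualifier or a new key
    while (i <= n && trimws(substr(block[i], 1, 20)) == "" &&
           substr(trimws(block[i]), 1, 1) != "/") {
      loc <- paste0(loc, trimws(block[i])); i <- i + 1L
    }
    gene <- NA_character_
    while (i <= n && trimws(substr(block[i], 1, 20)) == "") {
      q <- trimws(block[i])
      if (grepl('^/gene="', q) && is.na(gene))
        gene <- sub('^/gene="([^"]*)".*$', "\\1", q)
      if (grepl('^/standard_name="', q) && is.na(gene))
        gene <- sub('^/standard_name="([^"]*)".*$', "\\1", q)
      i <- i + 1L
    }
    if (key == "source") next
    mapped <- if (key %in% CAPTURED_KEYS) key else "misc"
    parsed <- parse_location(loc, L, circular)
    if (is.null(parsed)) next
    if (is.na(gene)) gene <- paste0(mapped, "_", length(keys) + 1L)
    keys <- c(keys, mapped); labels <- c(labels, gene)
    strands <- c(strands, parsed$strand); ivs <- c(ivs, list(parsed$intervals))
  }
  feature_table(keys, labels, strands, ivs)
}

## parse a GenBank location string into 0-based half-open intervals + strand
parse_location <- function(loc, L, circular) {
  strand <- 1L
  loc <- gsub("\\s", "", loc)
  while (grepl("^complement\\(", loc)) {
    strand <- -strand
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",")[[1]]
  iv <- matrix(NA_integer_, nrow = 0, ncol = 2)
  for (pt in parts) {
    pt <- gsub("[<>]", "", pt)
    if (grepl("^[0-9]+\\.\\.[0-9]+$", pt)) {
      ab <- as.integer(strsplit(pt, "\\.\\.")[[1]])
    } else if (grepl("^[0-9]+$", pt)) {
      ab <- c(as.integer(pt), as.integer(pt))
    } else return(NULL)
    if (ab[1] < 1 || ab[2] > L)
      stop(sprintf("coordinate error: location '%s' outside [1, %d]", pt, L))
    iv <- rbind(iv, c(ab[1] - 1L, ab[2]))
  }
  # merge pieces that abut across the origin into one wrapping interval
  if (circular && nrow(iv) >= 2) {
    keep <- rep(TRUE, nrow(iv))
    for (r in seq_len(nrow(iv) - 1L)) {
      if (iv[r, 2] == L && iv[r + 1L, 1] == 0L) {
        iv[r + 1L, ] <- c(iv[r, 1], iv[r + 1L, 2])
        keep[r] <- FALSE
      }
    }
    iv <- iv[keep, , drop = FALSE]
  }
  list(strand = strand, intervals = iv)
}

#' Write a plastome to a GenBank flat file
#'
#' Inverse of [read_genbank()]: `read_genbank(write_genbank(p))` reproduces
#' the sequence, features and strands.
#'
#' @param p plastome.
#' @param path output file path.
#' @export
write_genbank <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (p$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     p$id, p$length, topo, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s %s plastid genome.", p$genus, p$species), con)
  if (nzchar(p$genus) || nzchar(p$species)) {
    writeLines("SOURCE      plastid", con)
    writeLines(sprintf("  ORGANISM  %s %s", p$genus, p$species), con)
  }
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", p$length), con)
  for (i in seq_len(nrow(p$features))) {
    f <- p$features[i, ]
    loc <- format_location(f$intervals[[1]], f$strand, p$length)
    writeLines(sprintf("     %-16s%s", f$key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$label), con)
  }
  writeLines("ORIGIN", con)
  s <- p$sequence
  pos <- seq(1, nchar(s), by = 60)
  for (st in pos) {
    chunk <- substr(s, st, min(st + 59, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

format_location <- function(iv, strand, L) {
  pieces <- character()
  for (r in seq_len(nrow(iv))) {
    s <- iv[r, 1]; e <- iv[r, 2]
    if (e > s) {
      pieces <- c(pieces, sprintf("%d..%d", s + 1L, e))
    } else {  # wrapping interval -> two GenBank pieces
      pieces <- c(pieces, sprintf("%d..%d", s + 1L, L), sprintf("1..%d", e))
    }
  }
  loc <- if (length(pieces) > 1L)
    sprintf("join(%s)", paste(pieces, collapse = ",")) else pieces
  if (strand == -1L) loc <- sprintf("complement(%s)", loc)
  loc
}

#' Export features or regions as FASTA
#'
#' @param p plastome.
#' @param path output path.
#' @param which optional integer vector of feature rows (default: all).
#' @export
write_feature_fasta <- function(p, path, which = seq_len(nrow(p$features))) {
  seqs <- vapply(which, function(i) feature_sequence(p, i), character(1))
  names(seqs) <- paste0(p$id, "|", p$features$label[which])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
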