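## Concatenated protein-coding supermatrix: shared-gene selection (excluding
## the ndh set by default), gap/ambiguity column stripping, concatenation,
## and partition-file export for downstream tree software.

is_functional_cds <- function(seq) {
  nchar(seq) %% 3L == 0L && identical(has_internal_stop(seq), FALSE)
}

#' Protein-coding genes shared by all plastomes
#'
#' CDS labels annotated as present and functional (length a multiple of 3,
#' no internal stop codon) in every input plastome, minus the exclusion set,
#' in alphabetical order.
#'
#' @param plastomes list of >= 2 plastome objects.
#' @param exclude labels to drop (default the 11 ndh genes).
#' @return character vector (empty, with a warning, when nothing is shared).
#' @export
shared_genes <- function(plastomes, exclude = ndh_gene_names()) {
  if (length(plastomes) < 2L) stop("need at least 2 plastomes")
  per <- lapply(plastomes, function(p) {
    cds <- p$features[p$features$key == "CDS", , drop = FALSE]
    ok <- vapply(seq_len(nrow(cds)), function(i)
      is_functional_cds(feature_sequence(p, cds[i, , drop = FALSE])),
      logical(1))
    unique(norm_label(cds$label[ok]))
  })
  shared <- Reduce(intersect, per)
  shared <- setdiff(shared, norm_label(exclude))
  if (!length(shared)) {
    warning("no shared protein-coding genes")
    return(character())
  }
  # report with the casing used in the first plastome
  cds1 <- plastomes[[1]]$features
  lab1 <- cds1$label[cds1$key == "CDS"]
  out <- lab1[match(shared, norm_label(lab1))]
  sort(out, method = "radix")
}

#' Extract per-gene CDS sequences across plastomes
#' @param plastomes list of plastome objects.
#' @param genes gene labels (e.g. from [shared_genes()]).
#' @return named list gene -> named character vector (taxon -> sequence).
#' @export
extract_gene_sequences <- function(plastomes, genes) {
  out <- lapply(genes, function(g) {
    v <- vapply(plastomes, function(p) {
      cds <- p$features[p$features$key == "CDS", , drop = FALSE]
      hit <- which(same_gene(cds$label, g))
      if (!length(hit)) stop(sprintf("gene %s missing from %s", g, p$id))
      feature_sequence(p, cds[hit[1], , drop = FALSE])
    }, character(1))
    names(v) <- vapply(plastomes, `[[`, character(1), "id")
    v
  })
  names(out) <- genes
  out
}

#' Align a set of homologous sequences (helper, center-star progressive)
#'
#' Desk-scale multiple alignment built on [align_pair()]: every sequence is
#' aligned to the first (the center), and the pairwise gap patterns are
#' merged. Intended for fixtures and small gene sets, not production MSA.
#'
#' @param seqs named character vector.
#' @param ... scoring parameters passed to [align_pair()].
#' @return named character vector of equal-length aligned sequences.
#' @export
align_genes <- function(seqs, ...) {
  if (length(seqs) < 2L) return(seqs)
  center <- seqs[[1]]
  pws <- lapply(seqs[-1], function(s) align_pair(center, s, ...))
  # insertion run length before each center position (and at the end)
  cpos <- nchar(center) + 1L
  ins <- matrix(0L, nrow = length(pws), ncol = cpos)
  for (w in seq_along(pws)) {
    ca <- strsplit(pws[[w]]$a, "")[[1]]
    ci <- 1L; run <- 0L
    for (ch in ca) {
      if (ch == "-") run <- run + 1L
      else { ins[w, ci] <- run; run <- 0L; ci <- ci + 1L }
    }
    ins[w, cpos] <- run
  }
  maxins <- apply(ins, 2, max)
  pad <- function(gapped_center, gapped_other, w) {
    oa <- strsplit(gapped_center, "")[[1]]
    ob <- strsplit(gapped_other, "")[[1]]
    out <- character()
    ci <- 1L; run_take <- 0L; buf <- character()
    flush <- function(buf, ci) c(buf, rep("-", maxins[ci] - length(buf)))
    for (t in seq_along(oa)) {
      if (oa[t] == "-") { buf <- c(buf, ob[t]) }
      else {
        out <- c(out, flush(buf, ci), ob[t]); buf <- character(); ci <- ci + 1L
      }
    }
    out <- c(out, flush(buf, cpos))
    paste(out, collapse = "")
  }
  aligned <- character(length(seqs))
  # center row: its own "pairwise" alignment is itself with no gaps
  aligned[1] <- pad(center, center, 0L)
  for (w in seq_along(pws))
    aligned[w + 1L] <- pad(pws[[w]]$a, pws[[w]]$b, w)
  names(aligned) <- names(seqs)
  stopifnot(length(unique(nchar(aligned))) == 1L)
  aligned
}

#' Build a concatenated supermatrix from per-gene alignments
#'
#' Removes every column containing a gap or non-ACGT character in any taxon,
#' concatenates the genes in list order, and records 1-based inclusive
#' partition spans. A gene whose columns are all stripped contributes length
#' 0 and no partition (logged via message).
#'
#' @param per_gene_alignments named list gene -> named character vector of
#'   aligned sequences; every alignment must contain every taxon exactly once.
#' @return object of class `supermatrix`: `taxa`, `genes`, `matrix` (named
#'   character vector), `partitions` (data.frame gene/start/end).
#' @export
build_supermatrix <- function(per_gene_alignments) {
  genes <- names(per_gene_alignments)
  taxa <- names(per_gene_alignments[[1]])
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  pos <- 0L
  for (g in genes) {
    aln <- per_gene_alignments[[g]]
    if (!setequal(names(aln), taxa) || anyDuplicated(names(aln)))
      stop(sprintf("alignment of %s must contain every taxon exactly once", g))
    aln <- aln[taxa]
    if (length(unique(nchar(aln))) != 1L)
      stop(sprintf("alignment of %s has unequal row lengths", g))
    mat <- do.call(rbind, strsplit(toupper(aln), ""))
    keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    stripped <- mat[, keep, drop = FALSE]
    glen <- ncol(stripped)
    if (glen == 0L) {
      message(sprintf("gene %s: all columns stripped; contributes length 0", g))
      next
    }
    for (t in seq_along(taxa))
      rows[t] <- paste0(rows[t], paste(stripped[t, ], collapse = ""))
    parts[[g]] <- data.frame(gene = g, start = pos + 1L, end = pos + glen,
                             stringsAsFactors = FALSE)
    pos <- pos + glen
  }
  partitions <- if (length(parts)) do.call(rbind, parts) else
    data.frame(gene = character(), start = integer(), end = integer())
  rownames(partitions) <- NULL
  stopifnot(length(unique(nchar(rows))) == 1L,
            nchar(rows[1]) == pos)
  structure(list(taxa = taxa, genes = genes, matrix = rows,
                 partitions = partitions),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d bp, %d partitions\n",
              length(x$taxa), nchar(x$matrix[1]), nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix as FASTA
#' @param sm supermatrix.
#' @param path output path.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sm$matrix), path)
  invisible(path)
}

#' Write a supermatrix as relaxed PHYLIP
#' @param sm supermatrix.
#' @param path output path.
#' @export
write_supermatrix_phylip <- function(sm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), nchar(sm$matrix[1])), con)
  for (t in sm$taxa) writeLines(sprintf("%s  %s", t, sm$matrix[[t]]), con)
  invisible(path)
}

#' Write RAxML-style partition definitions
#' @param sm supermatrix.
#' @param path output path.
#' @export
write_raxml_partitions <- function(sm, path) {
  lines <- sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                   sm$partitions$start, sm$partitions$end)
  writeLines(lines, path)
  invisible(path)
}

#' Write a NEXUS sets block with the partition charsets
#' @param sm supermatrix.
#' @param path output path.
#' @export
write_nexus_sets <- function(sm, path) {
  lines <- c("#NEXUS", "begin sets;",
             sprintf("  charset %s = %d-%d;", sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end),
             "end;")
  writeLines(lines, path)
  invisible(path)
}
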