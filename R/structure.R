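## Quadripartite structure: inverted-repeat detection, IR/SSC junction
## profiling relative to ycf1, and ndh gene status classification.

#' Detect the inverted repeats and quadripartite partition
#'
#' Finds the maximal-length pair of disjoint regions whose sequences are
#' reverse complements of each other (up to `max_mismatch_frac`), by 31-mer
#' seeding of the sequence against its reverse complement followed by greedy
#' extension. The two gaps between the repeats are labeled LSC and SSC by
#' size. Plastomes without an inverted duplication of at least `min_ir` bp
#' yield an explicit no-IR partition, not an error.
#'
#' @param p plastome.
#' @param min_ir minimum repeat length in bp (default 10000, the scale of
#'   seed-plant plastome IRs).
#' @param max_mismatch_frac tolerated mismatch fraction between the two
#'   copies (default 0.001).
#' @param k seed k-mer size (default 31).
#' @return an object of class `quadripartite`: either `no_ir = TRUE`, or
#'   fields `ira`, `irb`, `lsc`, `ssc` (0-based half-open; `ssc`/`lsc` may
#'   wrap the origin), `ir_length`, `lsc_length`, `ssc_length`, `mismatches`.
#' @export
detect_inverted_repeats <- function(p, min_ir = 10000, max_mismatch_frac = 0.001,
                                    k = 31) {
  hit <- ir_scan_cpp(p$sequence, as.integer(min_ir), max_mismatch_frac,
                     as.integer(k))
  if (!isTRUE(hit$found))
    return(structure(list(no_ir = TRUE, plastome_length = p$length),
                     class = "quadripartite"))
  L <- p$length
  ira <- c(hit$a_start, hit$a_end)
  irb <- c(hit$b_start, hit$b_end)
  if (ira[1] > irb[1]) { tmp <- ira; ira <- irb; irb <- tmp }
  gap1 <- c(ira[2], irb[1])                     # between IRa end and IRb start
  gap2 <- c(irb[2] %% L, ira[1])                # wraps the origin when irb ends at L
  len1 <- interval_length(gap1[1], gap1[2], L)
  len2 <- interval_length(gap2[1], gap2[2], L)
  if (len1 >= len2) { lsc <- gap1; ssc <- gap2; lsc_len <- len1; ssc_len <- len2 }
  else              { lsc <- gap2; ssc <- gap1; lsc_len <- len2; ssc_len <- len1 }
  ir_len <- hit$length
  stopifnot(2L * ir_len + lsc_len + ssc_len == L)  # tiling identity
  structure(list(no_ir = FALSE, ira = ira, irb = irb, lsc = lsc, ssc = ssc,
                 ir_length = ir_len, lsc_length = lsc_len,
                 ssc_length = ssc_len, mismatches = hit$mismatches,
                 plastome_length = L),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (x$no_ir) cat("<quadripartite> no inverted repeat detected\n")
  else cat(sprintf("<quadripartite> IR %d bp [%d,%d)+[%d,%d), LSC %d bp, SSC %d bp\n",
                   x$ir_length, x$ira[1], x$ira[2], x$irb[1], x$irb[2],
                   x$lsc_length, x$ssc_length))
  invisible(x)
}

## is the (possibly wrapping) interval fully inside [rs, re)?
inside_region <- function(start, end, rs, re, L) {
  if (end <= start) return(FALSE)   # wrapping features never fit in a non-wrapping IR
  start >= rs && end <= re
}

#' IR/SSC junction profile relative to ycf1
#'
#' Measures the circular distance in bp from the strand-aware 5' end of the
#' ycf1 gene to the nearest IR/SSC junction, and lists the genes whose full
#' span lies inside either inverted repeat.
#'
#' @param p plastome with a ycf1 (or ycf1 pseudogene) annotation.
#' @param q quadripartite partition from [detect_inverted_repeats()].
#' @return list with `measurable`, `ycf1_to_junction`, `genes_in_ir`.
#' @export
junction_profile <- function(p, q) {
  feats <- p$features
  genes <- feats[feats$key == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) genes <- feats[feats$key %in% c("CDS", "misc"), , drop = FALSE]
  genes_in_ir <- character()
  if (!q$no_ir) {
    for (i in seq_len(nrow(genes))) {
      m <- genes$intervals[[i]]
      s <- min(m[, 1]); e <- max(ifelse(m[, 2] <= m[, 1], NA, m[, 2]))
      if (any(is.na(e))) next
      if (inside_region(s, e, q$ira[1], q$ira[2], p$length) ||
          inside_region(s, e, q$irb[1], q$irb[2], p$length))
        genes_in_ir <- c(genes_in_ir, genes$label[i])
    }
    genes_in_ir <- sort(unique(genes_in_ir))
  }
  hit <- which(same_gene(genes$label, "ycf1"))
  if (!length(hit) || q$no_ir)
    return(list(measurable = FALSE, ycf1_to_junction = NA_integer_,
                genes_in_ir = genes_in_ir))
  f <- genes[hit[1], , drop = FALSE]
  m <- f$intervals[[1]]
  five_prime <- if (f$strand == 1L) m[1, 1] else m[nrow(m), 2]
  L <- p$length
  junctions <- c(q$ssc[1], q$ssc[2] %% L)      # the two IR/SSC boundaries
  circ <- function(a, b) { d <- abs(a - b); min(d, L - d) }
  dist <- min(vapply(junctions, circ, numeric(1), a = five_prime))
  list(measurable = TRUE, ycf1_to_junction = as.integer(dist),
       genes_in_ir = genes_in_ir)
}

#' Names of the 11 plastid ndh genes
#' @export
ndh_gene_names <- function() paste0("ndh", LETTERS[1:11])

#' Typical plastid ndh CDS lengths (bp), used as default references
#'
#' Reference expected CDS lengths for functionality classification; override
#' with lineage-specific values where available.
#' @export
ndh_reference_lengths <- function() {
  c(ndhA = 1080, ndhB = 1533, ndhC = 363, ndhD = 1503, ndhE = 306,
    ndhF = 2241, ndhG = 531, ndhH = 1182, ndhI = 543, ndhJ = 477, ndhK = 678)
}

has_internal_stop <- function(cds) {
  nc <- nchar(cds)
  if (nc < 6L || nc %% 3L != 0L) return(NA)
  codons <- substring(cds, seq(1, nc - 3, 3), seq(3, nc - 1, 3))
  any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA"))
}

#' Classify the status of the 11 ndh genes
#'
#' A gene is `functional` when an annotated CDS is present, its length is a
#' multiple of 3 and at least `min_frac` of the reference length, and its
#' reading frame has no internal stop codon; `truncated` when annotated but
#' failing any criterion; `lost` when unannotated.
#'
#' @param p plastome.
#' @param reference_lengths named numeric map gene -> expected CDS bp
#'   (default [ndh_reference_lengths()]).
#' @param min_frac minimum fraction of the reference length (default 0.5).
#' @return object of class `ndh_status`: data.frame (gene, status, length)
#'   with attribute `n_functional`.
#' @export
classify_ndh <- function(p, reference_lengths = ndh_reference_lengths(),
                         min_frac = 0.5) {
  genes <- ndh_gene_names()
  cds <- p$features[p$features$key == "CDS", , drop = FALSE]
  status <- character(length(genes)); lens <- integer(length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    hit <- which(same_gene(cds$label, g))
    if (!length(hit)) { status[gi] <- "lost"; lens[gi] <- NA_integer_; next }
    f <- cds[hit[1], , drop = FALSE]
    seq <- feature_sequence(p, f)
    len <- nchar(seq)
    lens[gi] <- len
    ref <- reference_lengths[[g]]
    ok <- len %% 3L == 0L && !is.null(ref) && len >= min_frac * ref &&
      identical(has_internal_stop(seq), FALSE)
    status[gi] <- if (isTRUE(ok)) "functional" else "truncated"
  }
  out <- data.frame(gene = genes, status = status, length = lens,
                    stringsAsFactors = FALSE)
  attr(out, "n_functional") <- sum(status == "functional")
  class(out) <- c("ndh_status", class(out))
  out
}

#' Number of functional ndh genes in a classification
#' @param x an `ndh_status` object.
#' @export
n_functional <- function(x) attr(x, "n_functional")

#' Per-plastome structure report
#'
#' One TSV-ready row per plastome: lengths of the four regions, GC content,
#' ndh status count, and the junction profile.
#'
#' @param plastomes list of plastome objects.
#' @param min_ir,max_mismatch_frac passed to [detect_inverted_repeats()].
#' @param reference_lengths passed to [classify_ndh()].
#' @return data.frame.
#' @export
structure_report <- function(plastomes, min_ir = 10000, max_mismatch_frac = 0.001,
                             reference_lengths = ndh_reference_lengths()) {
  rows <- lapply(plastomes, function(p) {
    q <- detect_inverted_repeats(p, min_ir, max_mismatch_frac)
    j <- junction_profile(p, q)
    nd <- classify_ndh(p, reference_lengths)
    data.frame(plastome_id = p$id, genus = p$genus, species = p$species,
               length = p$length, gc = round(gc_content(p$sequence), 2),
               ir_length = if (q$no_ir) NA_integer_ else q$ir_length,
               lsc_length = if (q$no_ir) NA_integer_ else q$lsc_length,
               ssc_length = if (q$no_ir) NA_integer_ else q$ssc_length,
               n_functional_ndh = n_functional(nd),
               ycf1_to_junction = j$ycf1_to_junction,
               genes_in_ir = paste(j$genes_in_ir, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
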