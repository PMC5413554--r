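## Pairwise alignment of congeneric locus copies, DnaSP-style event counting,
## the sequence-variability statistic SV, per-genus aggregation and hotspot
## ranking. SV = 100 * (M + I) / (C + M + I), where M counts mutated columns,
## I counts indel events (one maximal gap run = one event, terminal runs
## excluded), and C counts conserved columns.

#' Global pairwise alignment with affine gap penalties
#'
#' Deterministic Needleman-Wunsch/Gotoh alignment. Scoring defaults: match
#' +2, mismatch -3, gap open -5, gap extend -2 (a gap of length L scores
#' `open + L * extend`). Traceback prefers diagonal, then up, then left. The
#' two inputs are ordered canonically before alignment so that
#' `align_pair(a, b)` and `align_pair(b, a)` return row-swapped identical
#' column sets.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @param backend optional replacement aligner: a `function(a, b)` returning
#'   a list with gapped strings `a` and `b`. Its output is validated against
#'   the same contract (equal row lengths, rows degap to the inputs, no
#'   all-gap columns) so downstream counting is backend-agnostic.
#' @return list with gapped strings `a`, `b` and the alignment `score`; no
#'   column has gaps in both rows.
#' @export
align_pair <- function(a, b, match = 2, mismatch = -3, gap_open = -5,
                       gap_ext = -2, backend = NULL) {
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  flip <- a > b
  if (flip) { tmp <- a; a <- b; b <- tmp }
  if (is.null(backend)) {
    res <- gotoh_align_cpp(a, b, as.integer(match), as.integer(mismatch),
                           as.integer(gap_open), as.integer(gap_ext))
  } else {
    res <- backend(a, b)
    if (!is.list(res) || is.null(res$a) || is.null(res$b) ||
        nchar(res$a) != nchar(res$b) ||
        gsub("-", "", res$a, fixed = TRUE) != a ||
        gsub("-", "", res$b, fixed = TRUE) != b)
      stop("backend aligner violated the alignment contract")
    ca <- strsplit(res$a, "")[[1]]; cb <- strsplit(res$b, "")[[1]]
    if (any(ca == "-" & cb == "-"))
      stop("backend aligner violated the alignment contract")
    if (is.null(res$score)) res$score <- NA_integer_
  }
  if (flip) res <- list(a = res$b, b = res$a, score = res$score)
  res
}

#' Count mutation and indel events in a pairwise alignment
#'
#' First trims terminal gap runs: any maximal gap run in either row that
#' touches the first or last column is removed (iteratively, so indels at the
#' alignment ends never count). Over the remaining columns, `C` counts
#' identical non-gap base columns, `M` columns with unequal non-gap bases,
#' and `I` the number of maximal gap runs (a run of any length is one event).
#' Columns containing N are excluded from `C` and `M`; an N splits a gap run
#' only when it interrupts the gap characters themselves.
#'
#' @param aln alignment from [align_pair()] (list with gapped `a`, `b`).
#' @return named integer vector `c(M, I, C)`.
#' @export
count_events <- function(aln) {
  A <- strsplit(aln$a, "")[[1]]
  B <- strsplit(aln$b, "")[[1]]
  if (length(A) != length(B)) stop("alignment rows differ in length")
  # iterative terminal trimming
  repeat {
    n <- length(A)
    if (n == 0L) break
    changed <- FALSE
    if (A[1] == "-" || B[1] == "-") {
      row <- if (A[1] == "-") A else B
      run <- which(cumprod(row == "-") == 1)
      A <- A[-run]; B <- B[-run]; changed <- TRUE
    }
    n <- length(A)
    if (n > 0L && (A[n] == "-" || B[n] == "-")) {
      row <- if (A[n] == "-") A else B
      run <- which(rev(cumprod(rev(row == "-")) == 1))
      A <- A[-run]; B <- B[-run]; changed <- TRUE
    }
    if (!changed) break
  }
  if (!length(A)) {
    warning("alignment empty after terminal-gap trimming")
    return(c(M = 0L, I = 0L, C = 0L))
  }
  gap_runs <- function(v) {
    r <- rle(v == "-")
    sum(r$values)
  }
  I <- gap_runs(A) + gap_runs(B)
  base <- c("A", "C", "G", "T")
  both <- A %in% base & B %in% base
  C <- sum(both & A == B)
  M <- sum(both & A != B)
  c(M = as.integer(M), I = as.integer(I), C = as.integer(C))
}

#' Sequence variability of one congeneric pair at one locus
#'
#' Aligns the two copies, counts events, and computes
#' SV = 100 (M + I) / (C + M + I).
#'
#' @param a,b locus sequences of the two species.
#' @param ... scoring parameters passed to [align_pair()].
#' @return one-row data.frame `M`, `I`, `C`, `sv`.
#' @export
pairwise_sv <- function(a, b, ...) {
  ev <- count_events(align_pair(a, b, ...))
  tot <- sum(ev)
  sv <- if (tot > 0) 100 * (ev[["M"]] + ev[["I"]]) / tot else 0
  data.frame(M = ev[["M"]], I = ev[["I"]], C = ev[["C"]], sv = sv)
}

#' Per-genus SV summary for one syntenic locus
#'
#' Computes the pairwise comparison for every unordered pair of the genus's
#' members carrying the locus, then the mean and sample (n-1) standard
#' deviation of SV, the pair count, and the mean GC content of the member
#' sequences.
#'
#' @param group one syntenic group from [group_syntenic()].
#' @param genus genus name; needs >= 2 members carrying the locus.
#' @param ... scoring parameters passed to [align_pair()].
#' @return one-row data.frame, or NULL (with a message) when < 2 members.
#' @export
genus_sv <- function(group, genus, ...) {
  mem <- group$members[group$members$genus == genus, , drop = FALSE]
  k <- nrow(mem)
  if (k < 2L) {
    message(sprintf("locus %s: %d member(s) in %s; skipped", group$key, k, genus))
    return(NULL)
  }
  prs <- combn(k, 2)
  svs <- vapply(seq_len(ncol(prs)), function(j) {
    pairwise_sv(mem$sequence[prs[1, j]], mem$sequence[prs[2, j]], ...)$sv
  }, numeric(1))
  stopifnot(all(svs >= 0 & svs <= 100))
  data.frame(genus = genus, key = group$key, kind = group$kind,
             mean_sv = mean(svs), sd_sv = if (length(svs) > 1) sd(svs) else 0,
             n_pairs = ncol(prs),
             mean_gc = mean(vapply(mem$sequence, gc_content, numeric(1))),
             region_class = group$region_class, stringsAsFactors = FALSE)
}

#' Per-genus SV table over all syntenic loci
#' @param groups output of [group_syntenic()].
#' @param genus genus name.
#' @param require_all_members require every genus member to carry the locus
#'   (default TRUE, the strict synteny reading).
#' @param ... passed to [genus_sv()].
#' @export
genus_sv_table <- function(groups, genus, require_all_members = TRUE, ...) {
  n_in_genus <- max(vapply(groups, function(g)
    sum(g$members$genus == genus), integer(1)), 0L)
  rows <- lapply(groups, function(g) {
    k <- sum(g$members$genus == genus)
    if (require_all_members && k < n_in_genus) return(NULL)
    suppressMessages(genus_sv(g, genus, ...))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank the mutational hotspots of a genus
#'
#' Sorts loci by mean SV (descending; ties broken by locus key ascending) and
#' keeps the top `k`, attaching SSR census counts when supplied.
#'
#' @param rows [genus_sv_table()] output for one genus.
#' @param k table size (default 10); fewer loci yield a shorter table.
#' @param ssr_census optional [genus_ssr_census()] output to join on `key`.
#' @return data.frame ranked by `mean_sv`.
#' @export
rank_hotspots <- function(rows, k = 10, ssr_census = NULL) {
  if (!nrow(rows)) return(rows)
  o <- order(-rows$mean_sv, rows$key, method = "radix")
  top <- head(rows[o, , drop = FALSE], k)
  if (!is.null(ssr_census) && nrow(ssr_census)) {
    top$ssr_count <- ssr_census$n_ssr[match(top$key, ssr_census$key)]
    top$ssr_count[is.na(top$ssr_count)] <- 0L
  } else top$ssr_count <- NA_integer_
  rownames(top) <- NULL
  top
}

#' Mann-Whitney comparison of SV between single-copy and IR loci
#'
#' @param rows [genus_sv_table()] output for one genus; both region classes
#'   must be represented.
#' @param exact_limit passed to [mann_whitney_two_sided()].
#' @return list `U`, `p`, `direction` ("SC" or "IR": the class with the
#'   larger rank sum), or NULL with a message when a class is absent.
#' @export
sc_vs_ir_test <- function(rows, exact_limit = 20) {
  sc <- rows$mean_sv[rows$region_class == "SC"]
  ir <- rows$mean_sv[rows$region_class == "IR"]
  if (!length(sc) || !length(ir)) {
    message("one region class absent; SC-vs-IR test skipped")
    return(NULL)
  }
  mw <- mann_whitney_two_sided(sc, ir, exact_limit)
  dir <- switch(mw$direction, first = "SC", second = "IR", "none")
  list(U = mw$U, p = mw$p, direction = dir)
}

#' Spearman correlation between mean GC and mean SV across loci
#' @param rows [genus_sv_table()] output for one genus.
#' @export
gc_sv_correlation <- function(rows) {
  spearman_test(rows$mean_gc, rows$mean_sv)
}

#' Cross-genus Spearman correlation of locus SV profiles
#'
#' Pairs loci present in both genus tables and correlates their mean SV.
#'
#' @param rows_a,rows_b [genus_sv_table()] outputs for two genera.
#' @export
cross_genus_correlation <- function(rows_a, rows_b) {
  shared <- intersect(rows_a$key, rows_b$key)
  if (length(shared) < 3L) stop("fewer than 3 shared loci")
  spearman_test(rows_a$mean_sv[match(shared, rows_a$key)],
                rows_b$mean_sv[match(shared, rows_b$key)])
}
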