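## Non-coding locus extraction and synteny grouping. Intergenic loci are the
## maximal gaps between gene-level annotations around the circle; intronic
## loci are the gaps between consecutive exons of a spliced feature. Loci are
## grouped across plastomes by the canonical (unordered) flanking-gene pair.

#' Canonical synteny key for a flank pair
#'
#' The unordered, strand-insensitive pair rendered in lexicographic order, so
#' "trnS-trnG" and "trnG-trnS" collapse to the same key.
#'
#' @param left,right flanking gene/exon labels (non-empty).
#' @return character key.
#' @export
canonical_key <- function(left, right) {
  if (!nzchar(left) || !nzchar(right)) stop("flank labels must be non-empty")
  pair <- sort(c(left, right), method = "radix")
  paste(pair, collapse = "-")
}

#' Canonical key for an intron locus
#' @param gene host gene label.
#' @param n intron ordinal (biological order, 1-based).
#' @export
intron_key <- function(gene, n) paste0(gene, "@intron", n)

#' Extract intergenic and intronic loci from one plastome
#'
#' Intergenic loci are maximal intervals not covered by any gene-level
#' annotation; overlapping gene annotations simply yield no locus over the
#' overlap. Intronic loci are the gaps between consecutive exons of spliced
#' CDS/tRNA features, numbered in biological (strand-aware) order. Instances
#' shorter than `min_len` are kept but flagged `rejected`. Each instance is
#' classed `IR` when it lies fully inside either inverted repeat, else `SC`.
#'
#' @param p plastome.
#' @param q quadripartite partition (or NULL / no-IR: everything is SC).
#' @param min_len minimum locus length in bp (default 150).
#' @return data.frame of locus instances.
#' @export
extract_noncoding <- function(p, q = NULL, min_len = 150) {
  L <- p$length
  feats <- p$features
  genes <- feats[feats$key == "gene", , drop = FALSE]
  if (nrow(genes) == 0L)
    genes <- feats[feats$key %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  out <- list()

  if (nrow(genes) > 0L) {
    # unwrap each gene span into linear arcs with its label
    arcs <- list()
    for (i in seq_len(nrow(genes))) {
      m <- genes$intervals[[i]]
      s <- m[1, 1]; e <- m[nrow(m), 2]
      span_wraps <- e <= s
      if (span_wraps) {
        arcs[[length(arcs) + 1L]] <- c(s, L, i)
        arcs[[length(arcs) + 1L]] <- c(0L, e, i)
      } else {
        arcs[[length(arcs) + 1L]] <- c(s, e, i)
      }
    }
    am <- do.call(rbind, arcs)
    am <- am[order(am[, 1], am[, 2]), , drop = FALSE]
    # merge into covered blocks, remembering which gene ends/starts each block
    blocks <- list()
    cs <- am[1, 1]; ce <- am[1, 2]
    start_g <- am[1, 3]; end_g <- am[1, 3]
    for (r in seq_len(nrow(am))[-1]) {
      if (am[r, 1] <= ce) {
        if (am[r, 2] > ce) { ce <- am[r, 2]; end_g <- am[r, 3] }
      } else {
        blocks[[length(blocks) + 1L]] <- list(s = cs, e = ce,
                                              sg = start_g, eg = end_g)
        cs <- am[r, 1]; ce <- am[r, 2]; start_g <- am[r, 3]; end_g <- am[r, 3]
      }
    }
    blocks[[length(blocks) + 1L]] <- list(s = cs, e = ce, sg = start_g, eg = end_g)
    # merge first/last blocks across the origin if they touch
    nb <- length(blocks)
    wrap_merged <- FALSE
    if (nb > 1L && blocks[[nb]]$e >= L && blocks[[1]]$s == 0L) {
      blocks[[1]]$s <- blocks[[nb]]$s
      blocks[[1]]$sg <- blocks[[nb]]$sg
      blocks[[nb]] <- NULL
      nb <- nb - 1L
      wrap_merged <- TRUE
    }
    covered <- sum(vapply(blocks, function(b)
      interval_length(b$s %% L, b$e %% L, L), numeric(1)))
    for (bi in seq_len(nb)) {
      if (covered >= L) break   # annotations tile the whole circle
      nxt <- if (bi == nb) 1L else bi + 1L
      gs <- blocks[[bi]]$e %% L
      ge <- blocks[[nxt]]$s %% L
      if (gs == ge && nb > 1L) next        # touching blocks: zero gap
      len <- interval_length(gs, ge, L)
      if (is.na(len) || len <= 0L || len >= L) next
      left <- genes$label[blocks[[bi]]$eg]
      right <- genes$label[blocks[[nxt]]$sg]
      out[[length(out) + 1L]] <- locus_row(p, q, gs, (gs + len) %% L,
                                           kind = "intergenic",
                                           left, right,
                                           canonical_key(left, right), min_len)
    }
  }

  # intronic loci from spliced CDS/tRNA/rRNA features
  spliced <- feats[feats$key %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  for (i in seq_len(nrow(spliced))) {
    m <- spliced$intervals[[i]]
    if (nrow(m) < 2L) next
    gene <- spliced$label[i]
    n_int <- nrow(m) - 1L
    for (gidx in seq_len(n_int)) {
      gs <- m[gidx, 2]; ge <- m[gidx + 1L, 1]
      if (ge <= gs) next  # adjacent or wrap-adjacent exons: no intron interval
      ord <- if (spliced$strand[i] == 1L) gidx else n_int - gidx + 1L
      out[[length(out) + 1L]] <- locus_row(p, q, gs, ge, kind = "intron",
                                           left = gene, right = gene,
                                           key = intron_key(gene, ord), min_len)
    }
  }
  if (!length(out)) return(empty_locus_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

locus_row <- function(p, q, start, end, kind, left, right, key, min_len) {
  L <- p$length
  len <- interval_length(start, end, L)
  seq <- region_sequence(p, start, end)
  rc <- "SC"
  if (!is.null(q) && !isTRUE(q$no_ir)) {
    if (end > start &&
        (inside_region(start, end, q$ira[1], q$ira[2], L) ||
         inside_region(start, end, q$irb[1], q$irb[2], L)))
      rc <- "IR"
  }
  data.frame(plastome_id = p$id, genus = p$genus, key = key, kind = kind,
             left_flank = left, right_flank = right,
             start = start, end = end, length = len,
             region_class = rc, rejected = len < min_len,
             sequence = seq, stringsAsFactors = FALSE)
}

empty_locus_table <- function() {
  data.frame(plastome_id = character(), genus = character(), key = character(),
             kind = character(), left_flank = character(),
             right_flank = character(), start = integer(), end = integer(),
             length = integer(), region_class = character(),
             rejected = logical(), sequence = character(),
             stringsAsFactors = FALSE)
}

#' Group locus instances into syntenic groups across plastomes
#'
#' Instances are grouped by canonical key. Within one plastome, duplicate
#' copies of a key (the IRa/IRb duplication) collapse to the copy with the
#' smallest start coordinate (the IRa representative). A group is
#' `fully_syntenic` when every plastome in `scope` contributes a member.
#' Instances flagged `rejected` (below the length filter) are excluded first.
#'
#' @param instances row-bound output of [extract_noncoding()] over plastomes.
#' @param scope character vector of plastome ids (default: all seen).
#' @return list of syntenic groups, each a list with `key`, `kind`,
#'   `members` (data.frame), `n_members`, `fully_syntenic`, `genera_present`,
#'   `region_class` (majority vote across members).
#' @export
group_syntenic <- function(instances, scope = unique(instances$plastome_id)) {
  inst <- instances[!instances$rejected & instances$plastome_id %in% scope, ,
                    drop = FALSE]
  if (nrow(inst) == 0L) return(list())
  inst <- inst[order(inst$key, inst$plastome_id, inst$start), , drop = FALSE]
  dup <- duplicated(inst[, c("key", "plastome_id")])
  inst <- inst[!dup, , drop = FALSE]
  keys <- sort(unique(inst$key))
  groups <- lapply(keys, function(k) {
    mem <- inst[inst$key == k, , drop = FALSE]
    rc <- names(sort(table(mem$region_class), decreasing = TRUE))[1]
    list(key = k, kind = mem$kind[1], members = mem, n_members = nrow(mem),
         fully_syntenic = all(scope %in% mem$plastome_id),
         genera_present = sort(unique(mem$genus)), region_class = rc)
  })
  names(groups) <- keys
  groups
}

#' Summary table of syntenic groups
#' @param groups output of [group_syntenic()].
#' @export
syntenic_summary <- function(groups) {
  if (!length(groups)) return(data.frame())
  do.call(rbind, lapply(groups, function(g)
    data.frame(key = g$key, kind = g$kind, n_members = g$n_members,
               fully_syntenic = g$fully_syntenic,
               region_class = g$region_class,
               genera = paste(g$genera_present, collapse = ","),
               stringsAsFactors = FALSE)))
}

#' FASTA export of one syntenic group (one record per member)
#' @param group one element of [group_syntenic()] output.
#' @param path output path.
#' @export
write_group_fasta <- function(group, path) {
  seqs <- group$members$sequence
  names(seqs) <- paste0(group$members$plastome_id, "|", group$key)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Report near-syntenic locus groups (exactly one shared flank)
#'
#' Pairs of intergenic groups whose canonical flank pairs share exactly one
#' gene label. Near-synteny is reported for inspection only; it never enters
#' the SV analyses, which require both flanks identical.
#'
#' @param groups output of [group_syntenic()].
#' @return data.frame with `key_a`, `key_b`, `shared_flank`.
#' @export
near_syntenic_pairs <- function(groups) {
  inter <- Filter(function(g) g$kind == "intergenic", groups)
  if (length(inter) < 2L)
    return(data.frame(key_a = character(), key_b = character(),
                      shared_flank = character(), stringsAsFactors = FALSE))
  flanks <- lapply(inter, function(g)
    unique(norm_label(c(g$members$left_flank, g$members$right_flank))))
  keys <- vapply(inter, `[[`, character(1), "key")
  rows <- list()
  prs <- combn(length(inter), 2)
  for (j in seq_len(ncol(prs))) {
    shared <- intersect(flanks[[prs[1, j]]], flanks[[prs[2, j]]])
    if (length(shared) == 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        key_a = keys[prs[1, j]], key_b = keys[prs[2, j]],
        shared_flank = shared, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(key_a = character(), key_b = character(),
                      shared_flank = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
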