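## Synthetic annotated plastome cohorts with planted truth. The generator
## emulates the statistical structure the comparative pipeline assumes: a
## circular quadripartite genome (IRb the exact reverse complement of IRa),
## gene annotations including the 11 ndh genes and a ycf1 spanning the
## IRb/SSC junction, congeneric species diverged from a common ancestor by
## locus-specific substitution and indel processes, planted perfect SSRs,
## and an ndh-loss/IR-expansion scenario. Every planted event is recorded in
## a truth ledger sufficient to compute the expected SV of any pair exactly
## (for loci not touching region boundaries).

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.33) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## random in-frame CDS: ATG start, TAA end, no internal stop
random_cds <- function(len, gc = 0.38) {
  stopifnot(len >= 6)
  n_cod <- ceiling(len / 3)
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_cod)
  for (i in seq_len(n_cod)) {
    repeat {
      c3 <- random_dna(3, gc)
      if (!(c3 %in% stops)) break
    }
    codons[i] <- c3
  }
  codons[1] <- "ATG"; codons[n_cod] <- "TAA"
  substr(paste(codons, collapse = ""), 1, len)
}

## break any near-threshold tandem run so the only SSRs are planted ones
scrub_ssrs <- function(seq, mono = 6, multi = 4, max_period = 6) {
  repeat {
    hits <- find_ssrs(seq, max_period, mono, multi)
    if (!nrow(hits)) return(seq)
    h <- hits[1, ]
    mid <- h$start + (h$end - h$start) %/% 2 + 1L
    cur <- substr(seq, mid, mid)
    substr(seq, mid, mid) <- sample(setdiff(BASES, cur), 1)
  }
}

#' Configuration for the synthetic plastome generator
#'
#' Defaults define the simulated study conditions: congeneric cohorts of 5
#' species diverged from a shared ancestor at per-site substitution
#' probability 0.01 and 0.5 indel events per non-coding locus (geometric
#' lengths, p = 0.5), on a quadripartite genome with a 4.3 kb IR and a ycf1
#' spanning the IRb/SSC junction.
#'
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @param n_genera,species_per_genus cohort shape.
#' @param template `"quadripartite"` (full genome structure) or `"sv_bench"`
#'   (a single-copy circle of `n_bench_loci` spacers between marker genes,
#'   for SV/hotspot calibration).
#' @param lsc_length,ir_length,ssc_length region size targets in bp.
#' @param sub_rate per-site substitution probability for non-coding loci;
#'   scalar or named vector keyed by locus element name.
#' @param indel_rate expected indel events per locus (Poisson).
#' @param indel_geom_p geometric length parameter for indels.
#' @param coding_sub_rate per-codon replacement probability in unspliced CDS
#'   (non-stop codon swaps, so functionality is preserved).
#' @param spacer_gc GC fraction of spacers; scalar or named by element.
#' @param ycf1_ssc_overhang bp of ycf1 upstream of the IRb/SSC junction.
#' @param min_spacer minimum spacer length (template overflow error if the
#'   region targets cannot accommodate it).
#' @param scenario `"baseline"` or `"ndh_loss_ir_expansion"`; may be a vector
#'   recycled over genera.
#' @param ssr_plants data.frame (element, motif, units) of perfect SSRs to
#'   embed; NULL plants a small default set (quadripartite template only).
#' @param genus_rate_permute permute the named `sub_rate` vector
#'   independently per genus (genus-specific rate profiles).
#' @param n_bench_loci,bench_locus_len,bench_gene_len sv_bench geometry.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_genera = 1L, species_per_genus = 5L,
                             template = c("quadripartite", "sv_bench"),
                             lsc_length = 9500, ir_length = 4300,
                             ssc_length = 8500,
                             sub_rate = 0.01, indel_rate = 0.5,
                             indel_geom_p = 0.5, coding_sub_rate = 0.002,
                             spacer_gc = 0.33, ycf1_ssc_overhang = 999,
                             min_spacer = 150,
                             scenario = "baseline", ssr_plants = NULL,
                             genus_rate_permute = FALSE,
                             n_bench_loci = 40, bench_locus_len = 300,
                             bench_gene_len = 300) {
  template <- match.arg(template)
  stopifnot(all(sub_rate >= 0 & sub_rate <= 1), indel_rate >= 0,
            indel_geom_p > 0, indel_geom_p <= 1,
            all(scenario %in% c("baseline", "ndh_loss_ir_expansion")),
            2 * ir_length < lsc_length + 2 * ir_length + ssc_length)
  if (is.null(ssr_plants) && template == "quadripartite")
    ssr_plants <- data.frame(
      element = c("sp_lsc_02", "sp_lsc_05", "sp_lsc_08", "sp_ssc_04", "sp_ira_03"),
      motif = c("A", "AT", "AAT", "T", "AG"),
      units = c(10L, 6L, 5L, 9L, 5L), stringsAsFactors = FALSE)
  if (is.null(ssr_plants))
    ssr_plants <- data.frame(element = character(), motif = character(),
                             units = integer(), stringsAsFactors = FALSE)
  structure(list(seed = as.integer(seed), n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 template = template, lsc_length = lsc_length,
                 ir_length = ir_length, ssc_length = ssc_length,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_geom_p = indel_geom_p,
                 coding_sub_rate = coding_sub_rate, spacer_gc = spacer_gc,
                 ycf1_ssc_overhang = ycf1_ssc_overhang,
                 min_spacer = min_spacer, scenario = scenario,
                 ssr_plants = ssr_plants,
                 genus_rate_permute = genus_rate_permute,
                 n_bench_loci = as.integer(n_bench_loci),
                 bench_locus_len = bench_locus_len,
                 bench_gene_len = bench_gene_len),
            class = "generator_config")
}

## ---- template construction -------------------------------------------------

gene_el <- function(name, kind, len, strand = 1L, exon_lens = NULL,
                    intron_lens = NULL, part = NULL) {
  list(type = "gene", name = name, kind = kind, len = len, strand = strand,
       exon_lens = exon_lens, intron_lens = intron_lens, part = part,
       seq = NULL)
}
spacer_el <- function(name, len) {
  list(type = "spacer", name = name, len = len, strand = 1L, seq = NULL)
}

spacer_lengths <- function(target, gene_total, n_spacers, min_spacer) {
  leftover <- target - gene_total
  if (leftover < n_spacers * min_spacer)
    stop(sprintf("template overflow: %d bp left for %d spacers (need >= %d)",
                 leftover, n_spacers, n_spacers * min_spacer))
  base <- leftover %/% n_spacers
  lens <- rep(base, n_spacers)
  extra <- leftover - base * n_spacers
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  lens
}

## interleave spacers around a gene list; trailing spacer optional
with_spacers <- function(genes, target, prefix, min_spacer, trailing = TRUE) {
  gene_total <- sum(vapply(genes, `[[`, numeric(1), "len"))
  n_sp <- length(genes) + if (trailing) 1L else 0L
  lens <- spacer_lengths(target, gene_total, n_sp, min_spacer)
  out <- list()
  for (i in seq_along(genes)) {
    out[[length(out) + 1L]] <- spacer_el(sprintf("%s_%02d", prefix, i), lens[i])
    out[[length(out) + 1L]] <- genes[[i]]
  }
  if (trailing)
    out[[length(out) + 1L]] <- spacer_el(sprintf("%s_%02d", prefix, n_sp),
                                         lens[n_sp])
  out
}

quadripartite_template <- function(config) {
  ov <- config$ycf1_ssc_overhang
  frag_len <- 501
  lsc_genes <- list(
    gene_el("psbA", "CDS", 600, -1L), gene_el("trnK-UUU", "tRNA", 72),
    gene_el("matK", "CDS", 900),
    gene_el("rps16", "CDS", 567, exon_lens = c(40, 227), intron_lens = 300),
    gene_el("trnQ-UGG", "tRNA", 72), gene_el("atpA", "CDS", 600),
    gene_el("rbcL", "CDS", 600), gene_el("trnS-GCU", "tRNA", 87),
    gene_el("trnG-UCC", "tRNA", 71), gene_el("clpP", "CDS", 591),
    gene_el("psbB", "CDS", 600), gene_el("ndhC", "CDS", 363),
    gene_el("ndhJ", "CDS", 477), gene_el("ndhK", "CDS", 678),
    gene_el("trnL-UAA", "tRNA", 80), gene_el("trnF-GAA", "tRNA", 73))
  ira_genes <- list(
    gene_el("ndhB", "CDS", 1533), gene_el("trnV-GAC", "tRNA", 72),
    gene_el("rrn16", "rRNA", 990), gene_el("trnI-GAU", "tRNA", 74),
    gene_el("rrn5", "rRNA", 121),
    gene_el("ycf1frag", "misc", frag_len, -1L, part = "frag"))
  ssc_genes <- list(
    gene_el("ndhF", "CDS", 900), gene_el("ccsA", "CDS", 540, -1L),
    gene_el("psaC", "CDS", 246), gene_el("ndhE", "CDS", 306),
    gene_el("ndhG", "CDS", 531), gene_el("ndhI", "CDS", 543),
    gene_el("ndhA", "CDS", 1200, exon_lens = c(540, 360), intron_lens = 300),
    gene_el("ndhH", "CDS", 600), gene_el("ndhD", "CDS", 600),
    gene_el("rps15", "CDS", 273),
    gene_el("ycf1", "CDS", ov, part = "five"))
  list(
    lsc = with_spacers(lsc_genes, config$lsc_length, "sp_lsc",
                       config$min_spacer),
    ira = with_spacers(ira_genes, config$ir_length, "sp_ira",
                       config$min_spacer, trailing = FALSE),
    ssc = with_spacers(ssc_genes, config$ssc_length, "sp_ssc",
                       config$min_spacer, trailing = FALSE),
    frag_len = frag_len)
}

sv_bench_template <- function(config) {
  n <- config$n_bench_loci
  els <- list(gene_el("g00", "CDS", config$bench_gene_len))
  for (i in seq_len(n)) {
    els[[length(els) + 1L]] <- spacer_el(sprintf("sp%02d", i),
                                         config$bench_locus_len)
    els[[length(els) + 1L]] <- gene_el(sprintf("g%02d", i), "CDS",
                                       config$bench_gene_len)
  }
  list(lsc = els, ira = list(), ssc = list(), frag_len = 0L)
}

spacer_gc_of <- function(config, name) {
  gcv <- config$spacer_gc
  if (!is.null(names(gcv)) && name %in% names(gcv)) return(gcv[[name]])
  if (is.null(names(gcv))) return(gcv[[1]])
  gcv[[1]]
}

fill_sequences <- function(layout, config) {
  ycf1_cds <- NULL
  if (!is.null(layout$frag_len) && layout$frag_len > 0)
    ycf1_cds <- random_cds(config$ycf1_ssc_overhang + layout$frag_len)
  for (rg in c("lsc", "ira", "ssc")) {
    for (i in seq_along(layout[[rg]])) {
      el <- layout[[rg]][[i]]
      if (el$type == "spacer") {
        el$seq <- scrub_ssrs(random_dna(el$len, spacer_gc_of(config, el$name)))
      } else if (identical(el$part, "frag")) {
        el$seq <- revcomp(substr(ycf1_cds, config$ycf1_ssc_overhang + 1L,
                                 nchar(ycf1_cds)))
      } else if (identical(el$part, "five")) {
        el$seq <- substr(ycf1_cds, 1L, config$ycf1_ssc_overhang)
      } else if (!is.null(el$intron_lens)) {
        cds <- random_cds(sum(el$exon_lens))
        intr <- scrub_ssrs(random_dna(el$intron_lens[1],
                                      spacer_gc_of(config, el$name)))
        el$seq <- paste0(substr(cds, 1, el$exon_lens[1]), intr,
                         substr(cds, el$exon_lens[1] + 1L, nchar(cds)))
        if (el$strand == -1L) stop("spliced genes must be on the plus strand")
      } else if (el$kind == "CDS") {
        cds <- random_cds(el$len)
        el$seq <- if (el$strand == -1L) revcomp(cds) else cds
      } else {
        el$seq <- random_dna(el$len, 0.45)
      }
      layout[[rg]][[i]] <- el
    }
  }
  layout
}

plant_ssrs <- function(layout, config) {
  plants <- config$ssr_plants
  truth <- list()
  for (r in seq_len(nrow(plants))) {
    el_name <- plants$element[r]; motif <- plants$motif[r]
    units <- plants$units[r]; p <- nchar(motif)
    found <- FALSE
    for (rg in c("lsc", "ira", "ssc")) {
      for (i in seq_along(layout[[rg]])) {
        el <- layout[[rg]][[i]]
        if (el$name != el_name || el$type != "spacer") next
        rep_seq <- paste(rep(motif, units), collapse = "")
        need <- nchar(rep_seq) + 2L
        if (el$len < need + 20L)
          stop(sprintf("spacer %s too short for planted SSR", el_name))
        st <- 10L  # fixed interior offset; flanks guarded below
        guard <- setdiff(BASES, c(substr(motif, p, p), substr(motif, 1, 1)))[1]
        s <- el$seq
        substr(s, st, st) <- guard
        substr(s, st + 1L, st + nchar(rep_seq)) <- rep_seq
        substr(s, st + nchar(rep_seq) + 1L, st + nchar(rep_seq) + 1L) <- guard
        el$seq <- s
        layout[[rg]][[i]] <- el
        truth[[length(truth) + 1L]] <-
          data.frame(element = el_name, motif = motif, units = units,
                     start_rel = st, stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
    if (!found) stop("ssr_plants element not found: ", el_name)
  }
  attr(layout, "ssr_truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(element = character(), motif = character(), units = integer(),
               start_rel = integer())
  layout
}

## first base of the SSC must not reverse-complement-pair with its last base,
## otherwise the maximal inverted repeat would extend one base past the
## planted boundary
enforce_junction_guard <- function(layout) {
  if (!length(layout$ssc)) return(layout)
  first_el <- layout$ssc[[1]]
  if (first_el$type != "spacer") return(layout)
  last_el <- layout$ssc[[length(layout$ssc)]]
  lastch <- substr(last_el$seq, nchar(last_el$seq), nchar(last_el$seq))
  comp <- chartr("ACGT", "TGCA", lastch)
  if (substr(first_el$seq, 1, 1) == comp) {
    repl <- setdiff(BASES, c(comp, substr(first_el$seq, 2, 2)))[1]
    substr(first_el$seq, 1, 1) <- repl
    layout$ssc[[1]] <- first_el
  }
  layout
}

## ---- assembly --------------------------------------------------------------

element_len <- function(el) nchar(el$seq)

region_seq <- function(els) paste(vapply(els, `[[`, character(1), "seq"),
                                  collapse = "")

## feature rows for one gene element at absolute offset
element_features <- function(el, off, frag_len, irb_span = NULL) {
  len <- element_len(el)
  rows <- list()
  add <- function(key, label, strand, iv)
    rows[[length(rows) + 1L]] <<- list(key = key, label = label,
                                       strand = strand, iv = iv)
  if (identical(el$part, "frag")) {
    add("gene", el$name, el$strand, matrix(c(off, off + len), ncol = 2))
  } else if (identical(el$part, "five")) {
    # ycf1 runs from here across the SSC/IRb junction into the IR
    add("gene", "ycf1", 1L, matrix(c(off, off + len + frag_len), ncol = 2))
    add("CDS", "ycf1", 1L, matrix(c(off, off + len + frag_len), ncol = 2))
  } else {
    add("gene", el$name, el$strand, matrix(c(off, off + len), ncol = 2))
    if (!is.null(el$intron_lens)) {
      e1 <- el$exon_lens[1]; intr <- el$intron_lens[1]
      iv <- rbind(c(off, off + e1), c(off + e1 + intr, off + len))
      add(el$kind, el$name, el$strand, iv)
    } else if (el$kind != "misc") {
      add(el$kind, el$name, el$strand, matrix(c(off, off + len), ncol = 2))
    }
  }
  rows
}

mirror_feature_rows <- function(rows, B, C) {
  ## mirror of [x, y) in IRa = [C + (B - y), C + (B - x)) in IRb
  lapply(rows, function(r) {
    iv <- r$iv
    miv <- cbind(C + (B - iv[, 2]), C + (B - iv[, 1]))
    miv <- miv[order(miv[, 1]), , drop = FALSE]
    list(key = r$key, label = r$label, strand = -r$strand,
         iv = matrix(as.integer(miv), ncol = 2))
  })
}

assemble_plastome <- function(layout, id, genus = "", species = "") {
  lsc_seq <- region_seq(layout$lsc)
  ira_seq <- region_seq(layout$ira)
  ssc_seq <- region_seq(layout$ssc)
  irb_seq <- if (nchar(ira_seq)) revcomp(ira_seq) else ""
  genome <- paste0(lsc_seq, ira_seq, ssc_seq, irb_seq)
  A <- nchar(lsc_seq); B <- A + nchar(ira_seq)
  C <- B + nchar(ssc_seq); L <- nchar(genome)
  frag_len <- if (is.null(layout$frag_len)) 0L else layout$frag_len
  rows <- list()
  off <- 0L
  for (rg in c("lsc", "ira", "ssc")) {
    for (el in layout[[rg]]) {
      if (el$type == "gene") {
        fr <- element_features(el, off, frag_len)
        rows <- c(rows, fr)
        if (rg == "ira" && !identical(el$part, "frag"))
          rows <- c(rows, mirror_feature_rows(fr, B, C))
      }
      off <- off + element_len(el)
    }
  }
  feats <- feature_table(
    key = vapply(rows, `[[`, character(1), "key"),
    label = vapply(rows, `[[`, character(1), "label"),
    strand = vapply(rows, function(r) as.integer(r$strand), integer(1)),
    intervals = lapply(rows, `[[`, "iv"))
  p <- plastome(id = id, sequence = genome, circular = TRUE, features = feats,
                genus = genus, species = species)
  coords <- if (B > A)
    list(ira = c(A, B), irb = c(C, L), lsc = c(0L, A), ssc = c(B, C),
         ir_length = B - A) else NULL
  list(plastome = p, coords = coords)
}

## ---- mutation --------------------------------------------------------------

## mutate one non-coding locus; positions are 1-based in the ancestral
## locus-local frame; events never touch the first/last `margin` bases and
## never overlap each other
mutate_locus <- function(seq, sub_rate, indel_rate, geom_p,
                         margin = 1L, max_indel = 8L) {
  chars <- strsplit(seq, "")[[1]]
  L0 <- length(chars)
  elig <- if (L0 > 2L * margin) (margin + 1L):(L0 - margin) else integer()
  spos <- elig[runif(length(elig)) < sub_rate]
  subs <- if (length(spos)) {
    to <- vapply(spos, function(i) sample(setdiff(BASES, chars[i]), 1),
                 character(1))
    data.frame(pos = spos, from = chars[spos], to = to,
               stringsAsFactors = FALSE)
  } else data.frame(pos = integer(), from = character(), to = character(),
                    stringsAsFactors = FALSE)
  occupied <- spos
  n_ind <- rpois(1, indel_rate)
  indels <- data.frame(type = character(), pos = integer(), len = integer(),
                       seq = character(), stringsAsFactors = FALSE)
  for (e in seq_len(n_ind)) {
    type <- sample(c("ins", "del"), 1)
    len <- min(rgeom(1, geom_p) + 1L, max_indel)
    for (try in 1:50) {
      if (type == "del") {
        lo <- margin + 1L; hi <- L0 - margin - len + 1L
        if (hi <= lo) break
        st <- sample(lo:hi, 1)
        span <- (st - 1L):(st + len)
        if (any(span %in% occupied)) next
        indels <- rbind(indels, data.frame(
          type = "del", pos = st, len = len,
          seq = paste(chars[st:(st + len - 1L)], collapse = ""),
          stringsAsFactors = FALSE))
        occupied <- c(occupied, span)
      } else {
        lo <- margin + 1L; hi <- L0 - margin - 1L
        if (hi <= lo) break
        st <- sample(lo:hi, 1)          # insertion after ancestral position st
        span <- st:(st + 1L)
        if (any(span %in% occupied)) next
        indels <- rbind(indels, data.frame(
          type = "ins", pos = st, len = len, seq = random_dna(len, 0.33),
          stringsAsFactors = FALSE))
        occupied <- c(occupied, span)
      }
      break
    }
  }
  out <- as.list(chars)
  if (nrow(subs)) for (r in seq_len(nrow(subs))) out[[subs$pos[r]]] <- subs$to[r]
  if (nrow(indels)) for (r in seq_len(nrow(indels))) {
    if (indels$type[r] == "del") {
      for (q in indels$pos[r]:(indels$pos[r] + indels$len[r] - 1L)) out[[q]] <- ""
    } else {
      out[[indels$pos[r]]] <- paste0(out[[indels$pos[r]]], indels$seq[r])
    }
  }
  list(seq = paste(unlist(out), collapse = ""), subs = subs, indels = indels)
}

## non-stop codon swaps in an unspliced CDS element (functionality-preserving)
mutate_coding <- function(el, rate) {
  if (el$type != "gene" || el$kind != "CDS" || !is.null(el$intron_lens) ||
      !is.null(el$part) || rate <= 0) return(el)
  cds <- if (el$strand == -1L) revcomp(el$seq) else el$seq
  n_cod <- nchar(cds) %/% 3L
  if (n_cod < 4L) return(el)
  hit <- which(runif(n_cod - 2L) < rate) + 1L   # spare first and last codon
  if (length(hit)) {
    stops <- c("TAA", "TAG", "TGA")
    for (ci in hit) {
      repeat { c3 <- random_dna(3, 0.38); if (!(c3 %in% stops)) break }
      substr(cds, 3L * ci - 2L, 3L * ci) <- c3
    }
    el$seq <- if (el$strand == -1L) revcomp(cds) else cds
  }
  el
}

## ---- locus enumeration / truth keys ----------------------------------------

## the mutable loci of a layout, with the canonical flank keys the pipeline
## will assign, and a cleanliness flag (clean = flanked by genes on both
## sides, so pipeline locus == template element exactly)
layout_loci <- function(layout) {
  seq_regions <- c("lsc", "ira", "ssc")
  els <- list()
  for (rg in seq_regions) for (el in layout[[rg]])
    els[[length(els) + 1L]] <- c(el, list(region = toupper(sub("a$", "", rg))))
  n <- length(els)
  # virtual circular order: lsc, ira, ssc, then the IRb mirror of ira reversed
  mirror <- rev(lapply(layout$ira, function(e)
    c(e, list(region = "IR", mirrored = TRUE))))
  circle <- c(els, mirror)
  nc <- length(circle)
  lab <- function(e) if (identical(e$part, "five")) "ycf1" else e$name
  rows <- list()
  for (i in seq_len(nc)) {
    el <- circle[[i]]
    if (isTRUE(el$mirrored)) next
    prev_i <- if (i == 1L) nc else i - 1L
    next_i <- if (i == nc) 1L else i + 1L
    if (el$type == "spacer") {
      prev_el <- circle[[prev_i]]; next_el <- circle[[next_i]]
      clean <- prev_el$type == "gene" && next_el$type == "gene"
      key <- if (clean) canonical_key(lab(prev_el), lab(next_el)) else
        NA_character_
      region <- if (el$region == "IR") "IR" else "SC"
      rows[[length(rows) + 1L]] <- data.frame(
        element = el$name, locus = el$name, key = key, kind = "intergenic",
        region_class = region, clean = clean,
        anc_len = element_len(el), anc_seq = el$seq,
        stringsAsFactors = FALSE)
    } else if (!is.null(el$intron_lens)) {
      e1 <- el$exon_lens[1]
      intr_seq <- substr(el$seq, e1 + 1L, e1 + el$intron_lens[1])
      rows[[length(rows) + 1L]] <- data.frame(
        element = el$name, locus = paste0(el$name, "@intron"),
        key = intron_key(el$name, 1L), kind = "intron",
        region_class = if (el$region == "IR") "IR" else "SC", clean = TRUE,
        anc_len = el$intron_lens[1], anc_seq = intr_seq,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## per-locus substitution rates resolved from the config
locus_rates <- function(config, loci) {
  r <- config$sub_rate
  if (is.null(names(r))) return(stats::setNames(rep(r[[1]], nrow(loci)),
                                                loci$locus))
  out <- rep(if ("default" %in% names(r)) r[["default"]] else 0, nrow(loci))
  names(out) <- loci$locus
  hit <- match(loci$element, names(r))
  out[!is.na(hit)] <- r[hit[!is.na(hit)]]
  out
}

## ---- scenario transform -----------------------------------------------------

apply_ndh_loss_ir_expansion <- function(layout, config) {
  drop <- setdiff(ndh_gene_names(), "ndhB")
  for (rg in c("lsc", "ira", "ssc"))
    layout[[rg]] <- Filter(function(e) !(e$name %in% drop), layout[[rg]])
  # reconstitute the full ycf1 from the SSC 5' part and the IRa fragment
  frag_i <- which(vapply(layout$ira, function(e) identical(e$part, "frag"),
                         logical(1)))
  five_i <- which(vapply(layout$ssc, function(e) identical(e$part, "five"),
                         logical(1)))
  stopifnot(length(frag_i) == 1L, length(five_i) == 1L)
  part3 <- revcomp(layout$ira[[frag_i]]$seq)
  full <- paste0(layout$ssc[[five_i]]$seq, part3)
  ycf1_full <- gene_el("ycf1", "CDS", nchar(full))
  ycf1_full$seq <- full
  layout$ira[[frag_i]] <- NULL
  layout$ssc[[five_i]] <- NULL
  layout$frag_len <- 0L
  # move the SSC tail (spacer, rps15, spacer, ycf1) into the IR: append the
  # reverse-complemented tail to IRa so that IRb (= revcomp IRa) begins with
  # the tail in its original orientation
  rps_i <- which(vapply(layout$ssc, function(e) e$name == "rps15", logical(1)))
  stopifnot(length(rps_i) == 1L)
  tail_els <- c(layout$ssc[(rps_i - 1L):length(layout$ssc)], list(ycf1_full))
  layout$ssc <- layout$ssc[seq_len(rps_i - 2L)]
  mirror_tail <- rev(lapply(tail_els, function(e) {
    e$seq <- revcomp(e$seq); e$strand <- -e$strand
    if (e$type == "spacer") e$name <- paste0(e$name, "_m")
    e
  }))
  layout$ira <- c(layout$ira, mirror_tail)
  # 5' offset of ycf1 within the moved tail = its distance to the SSC/IR junction
  off <- 0L
  for (e in tail_els) { if (e$name == "ycf1") break; off <- off + nchar(e$seq) }
  attr(layout, "ycf1_to_junction") <- off
  layout
}

## ---- ancestor / evolution ---------------------------------------------------

#' Build the ancestral annotated plastome
#'
#' Deterministic given `config$seed`. The returned object carries the element
#' layout (used by [evolve_genus()]), the assembled [plastome()], planted SSR
#' truth, and the planted ndh reference CDS lengths.
#'
#' @param config a [generator_config()].
#' @return object of class `plastome_ancestor`.
#' @export
make_ancestor <- function(config) {
  set.seed(config$seed %% 2147483647L)
  layout <- if (config$template == "quadripartite") quadripartite_template(config)
            else sv_bench_template(config)
  layout <- fill_sequences(layout, config)
  layout <- plant_ssrs(layout, config)
  layout <- enforce_junction_guard(layout)
  asm <- assemble_plastome(layout, id = "ancestor")
  ndh_ref <- numeric()
  for (e in c(layout$lsc, layout$ira, layout$ssc))
    if (e$type == "gene" && e$name %in% ndh_gene_names())
      ndh_ref[e$name] <- if (!is.null(e$exon_lens)) sum(e$exon_lens) else e$len
  structure(list(layout = layout, config = config, plastome = asm$plastome,
                 coords = asm$coords,
                 ssr_truth = attr(layout, "ssr_truth"),
                 ndh_reference = ndh_ref),
            class = "plastome_ancestor")
}

ycf1_truth <- function(layout, config, scenario) {
  if (scenario == "ndh_loss_ir_expansion") {
    # ycf1 sits in the IRb copy of the moved tail; its 5' offset from the
    # SSC/IRb junction is the summed current length of the tail elements
    # after its mirror in IRa
    yi <- which(vapply(layout$ira, function(e) e$name == "ycf1", logical(1)))
    if (!length(yi)) return(NA_integer_)
    rest <- layout$ira[seq_along(layout$ira) > yi[1]]
    return(sum(vapply(rest, element_len, numeric(1))))
  }
  if (!is.null(layout$frag_len) && layout$frag_len > 0)
    return(min(config$ycf1_ssc_overhang,
               sum(vapply(layout$ssc, element_len, numeric(1))) -
                 config$ycf1_ssc_overhang))
  NA_integer_
}

#' Evolve one congeneric species set from the ancestor
#'
#' Each species is an independent draw from the ancestor: per non-coding
#' locus, Bernoulli(s) substitutions per eligible site and Poisson(i) indel
#' events with geometric lengths, never overlapping each other or the locus
#' ends; unspliced CDSs receive functionality-preserving codon swaps; IRa
#' and IRb stay identical (mirror assembly). Under the
#' `ndh_loss_ir_expansion` scenario, 10 of the 11 ndh genes are deleted
#' (ndhB retained) and the IR expands to capture rps15 and ycf1.
#'
#' @param ancestor from [make_ancestor()].
#' @param config the [generator_config()] (its `scenario` entry for
#'   `genus_index` applies).
#' @param genus_id genus label for the emitted plastomes.
#' @param genus_index 1-based index used to derive the genus seed.
#' @return list with `plastomes` (list), `loci` (truth locus table),
#'   `events` (per plastome, per locus), `truth` (per-plastome structural
#'   truth), `rates` (realized per-locus substitution rates).
#' @export
evolve_genus <- function(ancestor, config, genus_id, genus_index = 1L) {
  set.seed((config$seed %% 1000000000L) + 1009L * genus_index)
  scenario <- rep(config$scenario, length.out = max(genus_index, 1L))[genus_index]
  layout <- ancestor$layout
  if (scenario == "ndh_loss_ir_expansion")
    layout <- apply_ndh_loss_ir_expansion(layout, config)
  loci <- layout_loci(layout)
  rates <- locus_rates(config, loci)
  if (isTRUE(config$genus_rate_permute))
    rates <- stats::setNames(sample(rates), names(rates))
  plastomes <- list(); events <- list(); truth <- list()
  for (j in seq_len(config$species_per_genus)) {
    lay2 <- layout
    ev_sp <- list()
    for (rg in c("lsc", "ira", "ssc")) {
      for (i in seq_along(lay2[[rg]])) {
        el <- lay2[[rg]][[i]]
        if (el$type == "spacer") {
          mut <- mutate_locus(el$seq, rates[[el$name]], config$indel_rate,
                              config$indel_geom_p)
          el$seq <- mut$seq
          ev_sp[[el$name]] <- mut[c("subs", "indels")]
        } else if (!is.null(el$intron_lens)) {
          locus <- paste0(el$name, "@intron")
          e1 <- el$exon_lens[1]
          intr <- substr(el$seq, e1 + 1L, e1 + el$intron_lens[1])
          mut <- mutate_locus(intr, rates[[locus]], config$indel_rate,
                              config$indel_geom_p)
          el$seq <- paste0(substr(el$seq, 1L, e1), mut$seq,
                           substr(el$seq, e1 + el$intron_lens[1] + 1L,
                                  nchar(el$seq)))
          el$intron_lens[1] <- nchar(mut$seq)
          ev_sp[[locus]] <- mut[c("subs", "indels")]
        } else {
          el <- mutate_coding(el, config$coding_sub_rate)
        }
        lay2[[rg]][[i]] <- el
      }
    }
    lay2 <- enforce_junction_guard(lay2)
    id <- sprintf("%s_sp%02d", genus_id, j)
    asm <- assemble_plastome(lay2, id = id, genus = genus_id,
                             species = sprintf("sp%02d", j))
    plastomes[[id]] <- asm$plastome
    events[[id]] <- ev_sp
    truth[[id]] <- list(
      coords = asm$coords, scenario = scenario,
      ycf1_to_junction = ycf1_truth(lay2, config, scenario),
      n_functional_ndh = if (scenario == "ndh_loss_ir_expansion") 1L else
        sum(ndh_gene_names() %in% vapply(
          c(layout$lsc, layout$ira, layout$ssc),
          function(e) e$name, character(1))))
  }
  list(plastomes = plastomes, loci = loci, events = events, truth = truth,
       rates = rates, scenario = scenario)
}

#' Simulate a full multi-genus cohort with truth ledger
#'
#' @param config a [generator_config()].
#' @return object of class `plastome_cohort`: `plastomes` (named list),
#'   `manifest` (data.frame plastome_id/genus/species/scenario), `ledger`
#'   (per-genus truth: loci, events, rates, per-plastome structure, planted
#'   SSRs, ndh reference lengths), `config`, `ancestor`.
#' @export
simulate_cohort <- function(config) {
  anc <- make_ancestor(config)
  plastomes <- list(); manifest <- list(); ledger <- list()
  for (g in seq_len(config$n_genera)) {
    genus_id <- sprintf("Genus%s", LETTERS[g])
    res <- evolve_genus(anc, config, genus_id, g)
    plastomes <- c(plastomes, res$plastomes)
    for (id in names(res$plastomes))
      manifest[[id]] <- data.frame(plastome_id = id, genus = genus_id,
                                   species = plastomes[[id]]$species,
                                   scenario = res$scenario,
                                   stringsAsFactors = FALSE)
    ledger[[genus_id]] <- res[c("loci", "events", "truth", "rates", "scenario")]
  }
  structure(list(plastomes = plastomes,
                 manifest = do.call(rbind, unname(manifest)),
                 ledger = c(ledger,
                            list(ssr_truth = anc$ssr_truth,
                                 ndh_reference = anc$ndh_reference)),
                 config = config, ancestor = anc),
            class = "plastome_cohort")
}

#' @export
print.plastome_cohort <- function(x, ...) {
  cat(sprintf("<plastome_cohort> %d plastomes, %d genera, template %s\n",
              length(x$plastomes), x$config$n_genera, x$config$template))
  invisible(x)
}

#' Expected pairwise (M, I, C) and SV from the truth ledger
#'
#' Reconstructs, from the planted event records of two congeneric species,
#' the event counts a perfect aligner would recover: M = ancestral sites
#' present in both and differing, C = present in both and equal, I = indel
#' events not shared identically by the pair. Exact for loci whose planted
#' events are disjoint and interior (the generator enforces both within each
#' species).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param genus genus id.
#' @param locus locus name (ledger `loci$locus`).
#' @param id1,id2 plastome ids of the pair.
#' @return list `M`, `I`, `C`, `sv`.
#' @export
truth_pair_sv <- function(cohort, genus, locus, id1, id2) {
  led <- cohort$ledger[[genus]]
  row <- led$loci[led$loci$locus == locus, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  anc <- strsplit(row$anc_seq, "")[[1]]
  L0 <- length(anc)
  get <- function(id) led$events[[id]][[locus]]
  e1 <- get(id1); e2 <- get(id2)
  apply_subs <- function(ev) {
    b <- anc
    if (nrow(ev$subs)) b[ev$subs$pos] <- ev$subs$to
    b
  }
  del_mask <- function(ev) {
    m <- rep(FALSE, L0)
    d <- ev$indels[ev$indels$type == "del", , drop = FALSE]
    if (nrow(d)) for (r in seq_len(nrow(d)))
      m[d$pos[r]:(d$pos[r] + d$len[r] - 1L)] <- TRUE
    m
  }
  b1 <- apply_subs(e1); b2 <- apply_subs(e2)
  d1 <- del_mask(e1); d2 <- del_mask(e2)
  present <- !d1 & !d2
  M <- sum(present & b1 != b2)
  C <- sum(present & b1 == b2)
  sig <- function(ev) if (nrow(ev$indels))
    paste(ev$indels$type, ev$indels$pos, ev$indels$len, ev$indels$seq) else
      character()
  s1 <- sig(e1); s2 <- sig(e2)
  I <- sum(!(s1 %in% s2)) + sum(!(s2 %in% s1))
  tot <- M + I + C
  list(M = M, I = I, C = C, sv = if (tot > 0) 100 * (M + I) / tot else 0)
}

#' Write a cohort to disk (GenBank files, manifest TSV, ledger JSON)
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$plastomes))
    write_genbank(cohort$plastomes[[id]], file.path(dir, paste0(id, ".gb")))
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  led <- cohort$ledger
  jsonlite::write_json(led, file.path(dir, "truth_ledger.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
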