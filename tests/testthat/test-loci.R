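# Non-coding locus extraction, canonical keys, synteny grouping.

toy_two_gene_circle <- function(id = "toy", L = 500L) {
  set.seed(3)
  plastome(id, rand_dna(L),
           features = feature_table(
             key = c("gene", "gene"), label = c("A", "B"),
             strand = c(1L, 1L),
             intervals = list(matrix(c(0L, 100L), ncol = 2),
                              matrix(c(300L, 400L), ncol = 2))))
}

test_that("intergenic gaps are extracted with flanks, wrap, and length filter", {
  p <- toy_two_gene_circle()
  loci <- extract_noncoding(p, q = NULL, min_len = 150)
  expect_equal(nrow(loci), 2L)
  ab <- loci[loci$start == 100L, ]
  expect_equal(ab$end, 300L)
  expect_equal(ab$length, 200L)
  expect_equal(ab$key, canonical_key("A", "B"))
  expect_false(ab$rejected)
  wrap <- loci[loci$start == 400L, ]
  expect_equal(wrap$length, 100L)          # 400..500 wraps to 0
  expect_true(wrap$rejected)               # below the 150 bp filter
  expect_equal(wrap$key, canonical_key("B", "A"))
})

test_that("introns are the gaps between consecutive exons", {
  set.seed(4)
  p <- plastome("ti", rand_dna(400),
                features = feature_table(
                  key = c("gene", "CDS"), label = c("g", "g"),
                  strand = c(1L, 1L),
                  intervals = list(matrix(c(0L, 300L), ncol = 2),
                                   rbind(c(0L, 50L), c(250L, 300L)))))
  loci <- extract_noncoding(p, min_len = 150)
  intr <- loci[loci$kind == "intron", ]
  expect_equal(nrow(intr), 1L)
  expect_equal(c(intr$start, intr$end, intr$length), c(50L, 250L, 200L))
  expect_equal(intr$key, "g@intron1")
})

test_that("adjacent genes with zero gap emit no intergenic locus", {
  set.seed(6)
  p <- plastome("tz", rand_dna(600),
                features = feature_table(
                  key = c("gene", "gene"), label = c("A", "B"),
                  strand = c(1L, 1L),
                  intervals = list(matrix(c(0L, 200L), ncol = 2),
                                   matrix(c(200L, 400L), ncol = 2))))
  loci <- extract_noncoding(p, min_len = 10)
  expect_false(any(loci$start == 200L & loci$kind == "intergenic"))
  expect_equal(nrow(loci[loci$kind == "intergenic", ]), 1L)  # only the B..A wrap
})

test_that("canonical keys are unordered and strand-insensitive", {
  expect_equal(canonical_key("trnG", "trnS"), canonical_key("trnS", "trnG"))
  expect_equal(canonical_key("rps16", "5'trnK"), canonical_key("5'trnK", "rps16"))
  expect_equal(intron_key("clpP", 1), "clpP@intron1")
  expect_error(canonical_key("", "x"), "non-empty")
})

test_that("synteny grouping collects flank-identical loci across plastomes", {
  ps <- lapply(1:3, function(i) {
    p <- toy_two_gene_circle(paste0("p", i), L = 500L)
    p$genus <- "G"
    p
  })
  inst <- do.call(rbind, lapply(ps, extract_noncoding, q = NULL, min_len = 150))
  groups <- group_syntenic(inst)
  expect_equal(length(groups), 1L)
  expect_equal(groups[[1]]$n_members, 3L)
  expect_true(groups[[1]]$fully_syntenic)
  # a rearrangement breaking the adjacency leaves the group partial
  p4 <- plastome("p4", ps[[1]]$sequence,
                 features = feature_table(
                   key = c("gene", "gene"), label = c("A", "C"),
                   strand = c(1L, 1L),
                   intervals = list(matrix(c(0L, 100L), ncol = 2),
                                    matrix(c(300L, 400L), ncol = 2))))
  p4$genus <- "G"
  inst2 <- rbind(inst[inst$plastome_id != "p3", ],
                 extract_noncoding(p4, min_len = 150))
  groups2 <- group_syntenic(inst2)
  ab <- groups2[[canonical_key("A", "B")]]
  expect_equal(ab$n_members, 2L)
  expect_false(ab$fully_syntenic)
})

test_that("grouping is order-independent and collapses IR duplicates to IRa", {
  cfg <- generator_config(seed = 17)
  anc <- make_ancestor(cfg)
  q <- detect_inverted_repeats(anc$plastome, min_ir = 1000)
  inst <- extract_noncoding(anc$plastome, q)
  g1 <- group_syntenic(inst)
  g2 <- group_syntenic(inst[rev(seq_len(nrow(inst))), ])
  expect_identical(syntenic_summary(g1), syntenic_summary(g2))
  # within one plastome each key keeps at most one member, the earliest copy
  for (g in g1) {
    expect_false(anyDuplicated(g$members$plastome_id) > 0)
  }
  # IR groups live inside one of the repeats, and whenever a key had copies
  # in both IRa and IRb the IRa (smaller start) copy is the representative
  ir_groups <- Filter(function(g) g$region_class == "IR", g1)
  expect_gt(length(ir_groups), 0L)
  for (g in ir_groups) {
    in_a <- g$members$start >= q$ira[1] & g$members$end <= q$ira[2]
    in_b <- g$members$start >= q$irb[1] & g$members$end <= q$irb[2]
    expect_true(all(in_a | in_b))
    both <- inst$key == g$key & !inst$rejected
    if (sum(both) > 1L)
      expect_equal(g$members$start[1], min(inst$start[both]))
  }
})

test_that("gene spans and emitted loci tile the circle at gene level", {
  cfg <- generator_config(seed = 19)
  p <- make_ancestor(cfg)$plastome
  q <- detect_inverted_repeats(p, min_ir = 1000)
  loci <- extract_noncoding(p, q, min_len = 1)
  genes <- p$features[p$features$key == "gene", ]
  arcs <- do.call(rbind, lapply(genes$intervals, function(m) {
    s <- m[1, 1]; e <- m[nrow(m), 2]
    if (e <= s) rbind(c(s, p$length), c(0, e)) else cbind(s, e)
  }))
  arcs <- arcs[order(arcs[, 1]), , drop = FALSE]
  cov <- 0L; cur_s <- arcs[1, 1]; cur_e <- arcs[1, 2]
  for (r in seq_len(nrow(arcs))[-1]) {
    if (arcs[r, 1] <= cur_e) cur_e <- max(cur_e, arcs[r, 2])
    else { cov <- cov + (cur_e - cur_s); cur_s <- arcs[r, 1]; cur_e <- arcs[r, 2] }
  }
  cov <- cov + (cur_e - cur_s)
  inter <- loci[loci$kind == "intergenic", ]
  expect_equal(cov + sum(inter$length), p$length)
  # no intergenic locus overlaps a gene span
  for (r in seq_len(nrow(inter))) {
    s <- inter$start[r]; e <- inter$end[r]
    for (a in seq_len(nrow(arcs))) {
      if (e > s) expect_true(e <= arcs[a, 1] || s >= arcs[a, 2])
    }
  }
})

test_that("near-syntenic groups (one shared flank) are reported separately", {
  mk <- function(id, labels) {
    set.seed(1)
    plastome(id, rand_dna(900),
             features = feature_table(
               rep("gene", 3), labels, rep(1L, 3),
               list(matrix(c(0L, 100L), ncol = 2),
                    matrix(c(300L, 400L), ncol = 2),
                    matrix(c(600L, 700L), ncol = 2))))
  }
  p <- mk("n1", c("A", "B", "C"))
  p$genus <- "G"
  inst <- extract_noncoding(p, min_len = 150)
  groups <- group_syntenic(inst)
  near <- near_syntenic_pairs(groups)
  # A-B and B-C share flank B; C-A (wrap) shares with both
  expect_true(nrow(near) >= 2L)
  expect_true(any(near$shared_flank == "b"))
})
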