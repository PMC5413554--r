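# Perfect SSR scanning, censusing, Fisher exact test.

test_that("unit thresholds are 8 for mono- and 5 for multinucleotide motifs", {
  h <- find_ssrs(strrep("A", 8))
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif, "A")
  expect_equal(h$unit_count, 8L)
  h2 <- find_ssrs(strrep("AT", 5))
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$motif, "AT")
  expect_equal(h2$unit_count, 5L)
  expect_equal(h2$period, 2L)            # no period-1 or period-4 report
  expect_equal(nrow(find_ssrs(strrep("A", 7))), 0L)
})

test_that("motifs are primitive and spans cover whole units", {
  h <- find_ssrs(paste0("GC", strrep("AT", 10), "GC"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif, "AT")            # never ATAT at period 4
  expect_equal(h$end - h$start, h$period * h$unit_count)
  # N interrupts runs
  expect_equal(nrow(find_ssrs(paste0(strrep("A", 5), "N", strrep("A", 5)))), 0L)
})

test_that("scanner equals the brute-force oracle on exhaustive and random strings", {
  for (s in all_strings(7, c("A", "T"))) {
    expect_identical(find_ssrs(s, min_mono = 4, min_multi = 2),
                     ssr_oracle(s, min_mono = 4, min_multi = 2))
  }
  set.seed(90)
  for (r in 1:40) {
    s <- rand_dna(sample(50:400, 1))
    expect_identical(find_ssrs(s), ssr_oracle(s))
  }
})

test_that("planted SSRs are recovered with exact motif and unit count", {
  cfg <- generator_config(seed = 29)
  anc <- make_ancestor(cfg)
  truth <- anc$ssr_truth
  q <- detect_inverted_repeats(anc$plastome, min_ir = 1000)
  inst <- extract_noncoding(anc$plastome, q)
  found <- 0L; extra <- 0L
  for (r in seq_len(nrow(inst))) {
    hits <- find_ssrs(inst$sequence[r])
    if (!nrow(hits)) next
    for (hh in seq_len(nrow(hits))) {
      # an SSR planted in the IR also appears reverse-complemented in the
      # IRb copy of its spacer
      match_r <- (truth$motif == hits$motif[hh] |
                    vapply(truth$motif, revcomp, character(1)) == hits$motif[hh]) &
        truth$units == hits$unit_count[hh]
      if (any(match_r)) found <- found + 1L else extra <- extra + 1L
    }
  }
  expect_gte(found, nrow(truth))
  expect_equal(extra, 0L)
})

test_that("census counts polymorphic SSR sites once per genus", {
  mk_group <- function(seqs) {
    members <- data.frame(plastome_id = paste0("p", seq_along(seqs)),
                          genus = "G", key = "A-B", kind = "intergenic",
                          left_flank = "A", right_flank = "B",
                          start = 0L, end = nchar(seqs), length = nchar(seqs),
                          region_class = "SC", rejected = FALSE,
                          sequence = seqs, stringsAsFactors = FALSE)
    list(`A-B` = list(key = "A-B", kind = "intergenic", members = members,
                      n_members = nrow(members), fully_syntenic = TRUE,
                      genera_present = "G", region_class = "SC"))
  }
  pad <- "GCTGCTGGTTGT"
  g1 <- mk_group(c(paste0(pad, strrep("A", 9), pad),
                   paste0(pad, strrep("A", 11), pad)))
  expect_equal(genus_ssr_census(g1, "G")$n_ssr, 1L)
  g2 <- mk_group(c(paste0(pad, strrep("A", 9), pad, strrep("TA", 6), pad),
                   paste0(pad, strrep("A", 9), pad, strrep("TA", 6), pad)))
  expect_equal(genus_ssr_census(g2, "G")$n_ssr, 2L)
  g0 <- mk_group(c(paste0(pad, pad), paste0(pad, pad)))
  expect_equal(genus_ssr_census(g0, "G")$n_ssr, 0L)
})

test_that("Fisher two-sided p matches the hypergeometric sums", {
  expect_equal(fisher_exact_two_sided(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2)), 1 / 126)
  expect_warning(p0 <- fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2)),
                 "degenerate")
  expect_equal(p0, 1)
})

test_that("Fisher p equals fisher.test across random tables", {
  set.seed(31)
  for (r in 1:200) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (min(rowSums(tab), colSums(tab)) == 0) next
    expect_equal(fisher_exact_two_sided(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("compound SSR merging is off by default and distance-configurable", {
  s <- paste0("GCGGCTGC", strrep("A", 8), "GC", strrep("AT", 5), "GCGGCTGC")
  sep <- find_ssrs(s)
  expect_equal(nrow(sep), 2L)
  merged <- find_ssrs(s, merge_distance = 3)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$motif, "A+AT")
  expect_equal(merged$start, sep$start[1])
  expect_equal(merged$end, sep$end[2])
  # far-apart hits never merge
  far <- find_ssrs(paste0(strrep("A", 8), "GACTTGCAGTCCAAGTGGACCTTGAGGCAT",
                          strrep("AT", 5)),
                   merge_distance = 3)
  expect_equal(nrow(far), 2L)
})
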