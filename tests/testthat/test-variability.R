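# Alignment, event counting, SV aggregation, hotspot ranking, Spearman.

test_that("alignment honours the scoring contract and symmetry", {
  a <- align_pair("ACGT", "ACGT")
  expect_equal(a$a, "ACGT")
  expect_equal(a$b, "ACGT")
  expect_equal(a$score, 8L)
  d <- align_pair("ACGT", "AGT")
  expect_equal(d$a, "ACGT")
  expect_equal(d$b, "A-GT")              # one single-column gap run
  expect_equal(d$score, 3L * 2L - 5L - 2L)
  # swap symmetry: row-swapped identical columns, identical event counts
  set.seed(12)
  for (r in 1:30) {
    x <- rand_dna(sample(5:60, 1)); y <- rand_dna(sample(5:60, 1))
    f <- align_pair(x, y); g <- align_pair(y, x)
    expect_identical(f$a, g$b)
    expect_identical(f$b, g$a)
    expect_identical(count_events(f), count_events(g))
  }
  # no column has gaps in both rows
  for (r in 1:10) {
    f <- align_pair(rand_dna(40), rand_dna(35))
    A <- strsplit(f$a, "")[[1]]; B <- strsplit(f$b, "")[[1]]
    expect_false(any(A == "-" & B == "-"))
  }
})

test_that("event counting trims terminal gaps and counts runs as single events", {
  # 100 columns: 95 identical, 2 mismatches, one internal 3-column gap
  top <- paste0(strrep("A", 40), "CC", strrep("A", 15), "GGG", strrep("A", 40))
  bot <- paste0(strrep("A", 40), "TT", strrep("A", 15), "---", strrep("A", 40))
  ev <- count_events(list(a = top, b = bot))
  expect_equal(ev, c(M = 2L, I = 1L, C = 95L))
  sv <- 100 * (ev[["M"]] + ev[["I"]]) / sum(ev)
  expect_equal(sv, 100 * 3 / 98)
  # identical sequences
  expect_equal(count_events(list(a = "ACGTAC", b = "ACGTAC")),
               c(M = 0L, I = 0L, C = 6L))
  # a gap run touching the 3' end contributes nothing
  ev2 <- count_events(list(a = "ACGTACGT", b = "ACGTAC--"))
  expect_equal(ev2, c(M = 0L, I = 0L, C = 6L))
  # N columns are excluded from C and M
  ev3 <- count_events(list(a = "ACNTA", b = "ACGTA"))
  expect_equal(ev3, c(M = 0L, I = 0L, C = 4L))
})

test_that("column conservation holds after trimming", {
  set.seed(14)
  for (r in 1:30) {
    f <- align_pair(rand_dna(sample(10:80, 1)), rand_dna(sample(10:80, 1)))
    ev <- count_events(f)
    orc <- events_oracle(f$a, f$b)
    expect_identical(ev, orc)
  }
})

test_that("sv is 0 iff no events, and bounded in [0, 100]", {
  x <- pairwise_sv("ACGTACGTAA", "ACGTACGTAA")
  expect_equal(x$sv, 0)
  set.seed(15)
  for (r in 1:20) {
    p <- pairwise_sv(rand_dna(60), rand_dna(60))
    expect_gte(p$sv, 0); expect_lte(p$sv, 100)
    if (p$M == 0 && p$I == 0) expect_equal(p$sv, 0) else expect_gt(p$sv, 0)
  }
})

test_that("genus SV forms choose(k, 2) pairs and aggregates correctly", {
  cfg <- generator_config(seed = 21, template = "sv_bench", n_bench_loci = 3,
                          species_per_genus = 11, bench_locus_len = 200)
  co <- simulate_cohort(cfg)
  res <- run_plastome_pipeline(co, pipeline_config(min_ir = 1e9))
  svt <- res$sv_tables$GenusA
  expect_true(all(svt$n_pairs == choose(11, 2)))
  expect_equal(res$summary$pairs_per_genus[["GenusA"]], choose(11, 2))
  cfg4 <- generator_config(seed = 21, template = "sv_bench", n_bench_loci = 3,
                           species_per_genus = 4, bench_locus_len = 200)
  co4 <- simulate_cohort(cfg4)
  res4 <- run_plastome_pipeline(co4, pipeline_config(min_ir = 1e9))
  expect_true(all(res4$sv_tables$GenusA$n_pairs == 6L))
  # identical members give zero mean and sd
  grp <- list(key = "k", kind = "intergenic", region_class = "SC",
              members = data.frame(plastome_id = c("a", "b"), genus = "G",
                                   sequence = rep(strrep("ACGT", 50), 2),
                                   stringsAsFactors = FALSE))
  row <- genus_sv(grp, "G")
  expect_equal(row$mean_sv, 0)
  expect_equal(row$sd_sv, 0)
  expect_null(suppressMessages(genus_sv(
    list(key = "k", kind = "intergenic", region_class = "SC",
         members = grp$members[1, ]), "G")))
})

test_that("hotspot ranking is by mean SV with deterministic tie-breaks", {
  rows <- data.frame(genus = "G", key = c("c", "a", "b", "d"),
                     kind = "intergenic", mean_sv = c(5, 4, 4, 1),
                     sd_sv = 0, n_pairs = 3, mean_gc = 30,
                     region_class = "SC", stringsAsFactors = FALSE)
  top <- rank_hotspots(rows, k = 2)
  expect_equal(top$key, c("c", "a"))     # tie at 4 broken lexicographically
  top3 <- rank_hotspots(rows, k = 3)
  expect_equal(top3$key, c("c", "a", "b"))
  expect_true(all(diff(top3$mean_sv) <= 0))
  expect_equal(nrow(rank_hotspots(rows[1:2, ], k = 10)), 2L)
})

test_that("Spearman rho and p match closed form and cor.test", {
  expect_equal(spearman_test(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(spearman_test(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(spearman_test(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  set.seed(16)
  for (n in c(5, 7, 9)) {
    x <- sample(100, n); y <- sample(100, n)
    st <- spearman_test(x, y)
    d <- rank(x) - rank(y)
    expect_equal(st$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(st$rho, unname(ref$estimate))
    expect_equal(st$p, ref$p.value, tolerance = 1e-9)
  }
  dg <- spearman_test(rep(1, 5), 1:5)
  expect_true(dg$degenerate)
})

test_that("SC-vs-IR comparison reports exact p and direction", {
  rows <- data.frame(genus = "G", key = letters[1:5], kind = "intergenic",
                     mean_sv = c(5, 6, 7, 1, 2), sd_sv = 0, n_pairs = 3,
                     mean_gc = 30,
                     region_class = c("SC", "SC", "SC", "IR", "IR"),
                     stringsAsFactors = FALSE)
  r <- sc_vs_ir_test(rows)
  expect_equal(r$p, 0.2)                  # 2 of choose(5,2)=10 labelings
  expect_equal(r$direction, "SC")
  expect_equal(sc_vs_ir_test(within(rows, mean_sv <- c(1, 1, 1, 1, 1)))$p, 1)
  expect_message(r0 <- sc_vs_ir_test(rows[rows$region_class == "SC", ]),
                 "skipped")
  expect_null(r0)
})

test_that("genus-specific rate profiles are recoverable across genera", {
  # shared rates -> strong cross-genus correlation; permuted rates -> weak
  rates <- stats::setNames(exp(seq(log(0.002), log(0.03), length.out = 20)),
                           sprintf("sp%02d", 1:20))
  shared_hits <- 0L; permuted_rhos <- numeric()
  for (rep_i in 1:5) {
    cfg_s <- generator_config(seed = 500 + rep_i, template = "sv_bench",
                              n_bench_loci = 20, species_per_genus = 4,
                              n_genera = 2, sub_rate = rates)
    co_s <- simulate_cohort(cfg_s)
    res_s <- run_plastome_pipeline(co_s, pipeline_config(min_ir = 1e9))
    ct <- cross_genus_correlation(res_s$sv_tables$GenusA, res_s$sv_tables$GenusB)
    if (ct$rho > 0.7) shared_hits <- shared_hits + 1L
    cfg_p <- generator_config(seed = 600 + rep_i, template = "sv_bench",
                              n_bench_loci = 20, species_per_genus = 4,
                              n_genera = 2, sub_rate = rates,
                              genus_rate_permute = TRUE)
    co_p <- simulate_cohort(cfg_p)
    res_p <- run_plastome_pipeline(co_p, pipeline_config(min_ir = 1e9))
    ctp <- cross_genus_correlation(res_p$sv_tables$GenusA, res_p$sv_tables$GenusB)
    permuted_rhos <- c(permuted_rhos, ctp$rho)
  }
  expect_gte(shared_hits, 4L)
  expect_lt(mean(abs(permuted_rhos)), 0.5)
})

test_that("a replacement aligner backend is accepted iff it honours the contract", {
  good <- function(a, b) align_pair(a, b)
  r <- align_pair("ACGTACGT", "ACGACGT", backend = good)
  expect_identical(r[c("a", "b")], align_pair("ACGTACGT", "ACGACGT")[c("a", "b")])
  bad <- function(a, b) list(a = paste0(a, "-"), b = paste0("-", b))
  expect_error(align_pair("ACGT", "ACG", backend = bad), "contract")
})
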