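# Quadripartite detection, junction profiling, ndh classification,
# Mann-Whitney exact test.

test_that("planted inverted repeats are recovered exactly across IR sizes", {
  for (ir in c(4200, 5000, 6500)) {
    cfg <- generator_config(seed = 100 + ir, ir_length = ir)
    anc <- make_ancestor(cfg)
    q <- detect_inverted_repeats(anc$plastome, min_ir = 3000)
    expect_false(q$no_ir)
    expect_equal(q$ira, anc$coords$ira)
    expect_equal(q$irb, anc$coords$irb)
    expect_equal(q$ir_length, ir)
    # tiling identity
    expect_equal(2L * q$ir_length + q$lsc_length + q$ssc_length,
                 anc$plastome$length)
    # the two copies mirror each other
    p <- anc$plastome
    expect_identical(region_sequence(p, q$ira[1], q$ira[2]),
                     revcomp(region_sequence(p, q$irb[1], q$irb[2])))
  }
})

test_that("a circle without a long inverted duplication yields a no-IR result", {
  set.seed(77)
  p <- plastome("noir", rand_dna(20000))
  q <- detect_inverted_repeats(p, min_ir = 1000)
  expect_true(q$no_ir)
})

test_that("junction profile measures the strand-aware ycf1 5' end", {
  cfg <- generator_config(seed = 9, ycf1_ssc_overhang = 1200,
                          ssc_length = 8800)
  anc <- make_ancestor(cfg)
  q <- detect_inverted_repeats(anc$plastome, min_ir = 1000)
  j <- junction_profile(anc$plastome, q)
  expect_true(j$measurable)
  expect_equal(j$ycf1_to_junction, 1200L)
})

test_that("ycf1 starting exactly at the junction gives distance 0", {
  set.seed(8)
  p <- plastome("jt", rand_dna(2000),
                features = feature_table("gene", "ycf1", 1L,
                                         list(matrix(c(1500L, 1900L), ncol = 2))))
  q <- structure(list(no_ir = FALSE, ira = c(500L, 800L), irb = c(1700L, 2000L),
                      lsc = c(0L, 500L), ssc = c(800L, 1700L),
                      ir_length = 300L, lsc_length = 500L, ssc_length = 900L,
                      plastome_length = 2000L), class = "quadripartite")
  # 5' end of ycf1 does not sit at a junction here
  expect_equal(junction_profile(p, q)$ycf1_to_junction, 200L)
  p0 <- plastome("jt0", p$sequence,
                 features = feature_table("gene", "ycf1", 1L,
                                          list(matrix(c(1700L, 1900L), ncol = 2))))
  expect_equal(junction_profile(p0, q)$ycf1_to_junction, 0L)
  # missing ycf1 is an explicit not-measurable result
  p_no <- plastome("jtn", p$sequence)
  expect_false(junction_profile(p_no, q)$measurable)
})

test_that("ndh classification distinguishes functional, truncated and lost", {
  cfg <- generator_config(seed = 13)
  anc <- make_ancestor(cfg)
  nd <- classify_ndh(anc$plastome, anc$ndh_reference)
  expect_equal(n_functional(nd), 11L)
  expect_true(all(nd$status == "functional"))
  # no annotations at all
  set.seed(2)
  bare <- plastome("bare", rand_dna(500))
  nd0 <- classify_ndh(bare)
  expect_equal(n_functional(nd0), 0L)
  expect_true(all(nd0$status == "lost"))
  # an internal stop makes a gene truncated, not functional
  cds_ok <- paste0("ATG", strrep("GCT", 40), "TAA")   # 126 bp, clean frame
  cds_stop <- cds_ok
  substr(cds_stop, 10, 12) <- "TAA"
  mk <- function(cds) plastome("t", paste0(cds, "AAAA"),
    features = feature_table("CDS", "ndhB", 1L,
                             list(matrix(c(0L, nchar(cds)), ncol = 2))))
  refs <- c(ndhB = 126)
  expect_equal(classify_ndh(mk(cds_ok), refs)$status[2], "functional")
  expect_equal(classify_ndh(mk(cds_stop), refs)$status[2], "truncated")
})

test_that("Mann-Whitney exact p matches the enumeration examples", {
  r1 <- mann_whitney_two_sided(c(1, 2), c(3, 4))
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 1 / 3)
  r2 <- mann_whitney_two_sided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 0.1)
  # identical multisets: full symmetry
  expect_equal(mann_whitney_two_sided(c(3, 1, 4), c(3, 1, 4))$p, 1)
  expect_error(mann_whitney_two_sided(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free samples", {
  set.seed(41)
  for (na in 2:5) for (nb in 2:(10 - na)) {
    x <- sample(seq_len(50), na)
    y <- sample(setdiff(seq_len(50), x), nb)
    mine <- mann_whitney_two_sided(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                               correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ndh-deficient, IR-expanded genomes show larger IRs than baseline", {
  cfg <- generator_config(seed = 55, n_genera = 2, species_per_genus = 3,
                          scenario = c("baseline", "ndh_loss_ir_expansion"))
  co <- simulate_cohort(cfg)
  irl <- vapply(names(co$plastomes), function(id) {
    q <- detect_inverted_repeats(co$plastomes[[id]], min_ir = 1000)
    q$ir_length
  }, numeric(1))
  base <- irl[co$manifest$scenario == "baseline"]
  exp_ <- irl[co$manifest$scenario == "ndh_loss_ir_expansion"]
  expect_gt(median(exp_), median(base))
  # and the deficient group is ndh-deficient
  nf <- vapply(co$plastomes[co$manifest$scenario == "ndh_loss_ir_expansion"],
               function(p) n_functional(classify_ndh(p, co$ledger$ndh_reference)),
               integer(1))
  expect_true(all(nf == 1L))
})
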