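## End-to-end orchestration: structure -> loci -> SSR -> SV -> tests, with
## TSV/JSON artifact export. Defaults reproduce the comparative study
## settings (150 bp locus filter; SSR unit thresholds 8 and 5; exact tests
## at small n).

#' Pipeline configuration
#'
#' @param min_locus_len minimum non-coding locus length (bp).
#' @param ssr_min_mono,ssr_min_multi SSR unit thresholds for period 1 / >= 2.
#' @param ssr_max_period maximum SSR motif length.
#' @param min_ir,max_mismatch_frac IR detection parameters.
#' @param match,mismatch,gap_open,gap_ext aligner scoring.
#' @param exact_limit combined-n switchover for the exact Mann-Whitney.
#' @param bh_adjust apply Benjamini-Hochberg adjustment across genera.
#' @param ndh_reference named CDS reference lengths for ndh classification.
#' @param hotspot_k hotspot table size.
#' @export
pipeline_config <- function(min_locus_len = 150, ssr_min_mono = 8,
                            ssr_min_multi = 5, ssr_max_period = 6,
                            min_ir = 10000, max_mismatch_frac = 0.001,
                            match = 2, mismatch = -3, gap_open = -5,
                            gap_ext = -2, exact_limit = 20, bh_adjust = TRUE,
                            ndh_reference = ndh_reference_lengths(),
                            hotspot_k = 10) {
  list(min_locus_len = min_locus_len, ssr_min_mono = ssr_min_mono,
       ssr_min_multi = ssr_min_multi, ssr_max_period = ssr_max_period,
       min_ir = min_ir, max_mismatch_frac = max_mismatch_frac,
       match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, exact_limit = exact_limit, bh_adjust = bh_adjust,
       ndh_reference = ndh_reference, hotspot_k = hotspot_k)
}

load_plastome_dir <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  files <- list.files(dir, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE)
  if (!length(files)) stop("no plastomes found in ", dir)
  plastomes <- lapply(files, read_genbank)
  names(plastomes) <- vapply(plastomes, `[[`, character(1), "id")
  manifest <- if (file.exists(manifest_path)) {
    read.delim(manifest_path, stringsAsFactors = FALSE)
  } else {
    data.frame(plastome_id = names(plastomes),
               genus = vapply(plastomes, `[[`, character(1), "genus"),
               species = vapply(plastomes, `[[`, character(1), "species"),
               stringsAsFactors = FALSE)
  }
  for (id in names(plastomes)) {
    hit <- match(id, manifest$plastome_id)
    if (!is.na(hit)) plastomes[[id]]$genus <- manifest$genus[hit]
  }
  list(plastomes = plastomes, manifest = manifest)
}

#' Run the full comparative pipeline
#'
#' Stages: quadripartite structure, junction and ndh profiling per plastome;
#' non-coding locus extraction and synteny grouping; per-genus SSR census,
#' SV table, hotspot ranking; SC-vs-IR Mann-Whitney, GC-SV Spearman, and the
#' SSR SC/IR Fisher test per genus; cross-genus SV correlations.
#'
#' @param input a directory of GenBank files (with optional manifest.tsv) or
#'   a [simulate_cohort()] result.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @return list of result tables and a machine-readable `summary`.
#' @export
run_plastome_pipeline <- function(input, config = pipeline_config(),
                                  out_dir = NULL) {
  if (inherits(input, "plastome_cohort")) {
    plastomes <- input$plastomes
    manifest <- input$manifest
  } else if (is.character(input)) {
    loaded <- load_plastome_dir(input)
    plastomes <- loaded$plastomes
    manifest <- loaded$manifest
  } else stop("input must be a cohort object or a directory path")
  if (!length(plastomes)) stop("no plastomes supplied")

  ## stage 1: structure
  struct <- structure_report(plastomes, min_ir = config$min_ir,
                             max_mismatch_frac = config$max_mismatch_frac,
                             reference_lengths = config$ndh_reference)

  ## stage 2: loci
  instances <- do.call(rbind, lapply(plastomes, function(p) {
    q <- detect_inverted_repeats(p, config$min_ir, config$max_mismatch_frac)
    extract_noncoding(p, q, min_len = config$min_locus_len)
  }))
  rownames(instances) <- NULL
  groups <- group_syntenic(instances)
  rejected <- instances[instances$rejected, , drop = FALSE]

  ## stage 3-5: per-genus analyses
  genera <- sort(unique(manifest$genus))
  genus_sizes <- vapply(genera, function(g)
    sum(manifest$genus == g), integer(1))
  analyzable <- genera[genus_sizes >= 2L]
  sv_tables <- list(); censuses <- list(); hotspots <- list()
  tests <- list()
  for (g in analyzable) {
    svt <- genus_sv_table(groups, g, match = config$match,
                          mismatch = config$mismatch,
                          gap_open = config$gap_open, gap_ext = config$gap_ext)
    cen <- genus_ssr_census(groups, g, config$ssr_max_period,
                            config$ssr_min_mono, config$ssr_min_multi)
    sv_tables[[g]] <- svt
    censuses[[g]] <- cen
    if (nrow(svt)) {
      hotspots[[g]] <- rank_hotspots(svt, config$hotspot_k, cen)
      mw <- sc_vs_ir_test(svt, config$exact_limit)
      gc <- if (nrow(svt) >= 3L) gc_sv_correlation(svt) else NULL
      fis <- if (nrow(cen) && length(unique(cen$region_class)) == 2L)
        ssr_region_association(cen) else NULL
      tests[[g]] <- data.frame(
        genus = g,
        sc_vs_ir_U = if (is.null(mw)) NA_real_ else mw$U,
        sc_vs_ir_p = if (is.null(mw)) NA_real_ else mw$p,
        sc_vs_ir_direction = if (is.null(mw)) NA_character_ else mw$direction,
        gc_sv_rho = if (is.null(gc)) NA_real_ else gc$rho,
        gc_sv_p = if (is.null(gc)) NA_real_ else gc$p,
        ssr_fisher_p = if (is.null(fis)) NA_real_ else fis$p,
        stringsAsFactors = FALSE)
    }
  }
  test_table <- if (length(tests)) do.call(rbind, tests) else data.frame()
  rownames(test_table) <- NULL
  if (nrow(test_table) && config$bh_adjust) {
    test_table$sc_vs_ir_p_bh <- p.adjust(test_table$sc_vs_ir_p, "BH")
    test_table$gc_sv_p_bh <- p.adjust(test_table$gc_sv_p, "BH")
  }

  ## cross-genus SV correlations
  cross <- list()
  if (length(analyzable) >= 2L) {
    prs <- combn(analyzable, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      ta <- sv_tables[[a]]; tb <- sv_tables[[b]]
      if (!nrow(ta) || !nrow(tb)) next
      shared <- intersect(ta$key, tb$key)
      if (length(shared) < 3L) next
      ct <- cross_genus_correlation(ta, tb)
      cross[[length(cross) + 1L]] <- data.frame(
        genus_a = a, genus_b = b, n_shared = length(shared),
        rho = ct$rho, p = ct$p, stringsAsFactors = FALSE)
    }
  }
  cross_table <- if (length(cross)) do.call(rbind, cross) else data.frame()

  pairs_per_genus <- stats::setNames(choose(genus_sizes, 2), genera)
  summary <- list(
    n_plastomes = length(plastomes),
    n_genera = length(genera),
    n_instances = nrow(instances),
    n_rejected = nrow(rejected),
    n_groups = length(groups),
    n_fully_syntenic = sum(vapply(groups, `[[`, logical(1), "fully_syntenic")),
    pairs_per_genus = pairs_per_genus,
    pairs = sum(pairs_per_genus))

  res <- list(structure = struct, instances = instances, groups = groups,
              sv_tables = sv_tables, ssr_censuses = censuses,
              hotspots = hotspots, tests = test_table,
              cross_genus = cross_table, summary = summary,
              manifest = manifest, config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(res$structure, "structure.tsv")
  tsv(res$instances[, setdiff(names(res$instances), "sequence")], "loci.tsv")
  tsv(syntenic_summary(res$groups), "syntenic_groups.tsv")
  for (g in names(res$sv_tables))
    if (nrow(res$sv_tables[[g]])) tsv(res$sv_tables[[g]],
                                      sprintf("sv_%s.tsv", g))
  for (g in names(res$hotspots))
    if (nrow(res$hotspots[[g]])) tsv(res$hotspots[[g]],
                                     sprintf("hotspots_%s.tsv", g))
  if (nrow(res$tests)) tsv(res$tests, "tests.tsv")
  if (nrow(res$cross_genus)) tsv(res$cross_genus, "cross_genus.tsv")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
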