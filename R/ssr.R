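## Perfect simple-sequence-repeat (SSR) scanning and per-genus censusing.
## Thresholds follow the microsatellite screen of the comparative analyses:
## mononucleotide runs need >= 8 units, multinucleotide motifs >= 5 units.

#' Scan a sequence for perfect SSRs
#'
#' Reports every maximal perfect tandem run with a primitive motif (a motif
#' that is not itself a repetition of a shorter motif) meeting the
#' period-specific unit threshold. A run decomposable at several phases is
#' reported from its leftmost start, truncated to whole units, so its span is
#' exactly `period * unit_count`. Runs containing N never contribute. Two
#' hits may overlap only when their primitive motifs differ.
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param max_period maximum motif length (default 6).
#' @param min_mono unit threshold for period 1 (default 8).
#' @param min_multi unit threshold for periods >= 2 (default 5).
#' @param merge_distance when > 0, adjacent hits separated by at most this
#'   many bases are merged into one compound row (motifs joined with "+",
#'   `period` and `unit_count` set to NA). Off (0) by default: compound SSRs
#'   are reported as separate hits.
#' @return data.frame with `motif`, `period`, `unit_count`, `start`, `end`
#'   (0-based half-open within `seq`), sorted by start then period.
#' @export
find_ssrs <- function(seq, max_period = 6, min_mono = 8, min_multi = 5,
                      merge_distance = 0) {
  seq <- toupper(seq)
  df <- ssr_scan_cpp(seq, as.integer(max_period), as.integer(min_mono),
                     as.integer(min_multi))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- df[order(df$start, df$period), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (merge_distance > 0 && nrow(df) > 1L) {
    merged <- df[1, ]
    out <- list()
    for (r in seq_len(nrow(df))[-1]) {
      if (df$start[r] - merged$end <= merge_distance) {
        merged$motif <- paste(merged$motif, df$motif[r], sep = "+")
        merged$period <- NA_integer_
        merged$unit_count <- NA_integer_
        merged$end <- max(merged$end, df$end[r])
      } else {
        out[[length(out) + 1L]] <- merged
        merged <- df[r, ]
      }
    }
    out[[length(out) + 1L]] <- merged
    df <- do.call(rbind, out)
    rownames(df) <- NULL
  }
  df
}

#' Per-genus SSR census over syntenic loci
#'
#' For each syntenic locus, counts SSR sites across the genus's members. A
#' site that segregates among congeneric species (present in some members or
#' with different unit counts) is counted once, not once per species:
#' homologous sites are matched by motif plus ordinal position of that motif
#' within the locus.
#'
#' @param groups output of [group_syntenic()].
#' @param genus genus name.
#' @param max_period,min_mono,min_multi passed to [find_ssrs()].
#' @return data.frame with `key`, `region_class`, `n_ssr` (distinct sites),
#'   `n_members` (genus members carrying the locus).
#' @export
genus_ssr_census <- function(groups, genus, max_period = 6,
                             min_mono = 8, min_multi = 5) {
  rows <- lapply(groups, function(g) {
    mem <- g$members[g$members$genus == genus, , drop = FALSE]
    if (nrow(mem) == 0L) return(NULL)
    sites <- character()
    for (r in seq_len(nrow(mem))) {
      hits <- find_ssrs(mem$sequence[r], max_period, min_mono, min_multi)
      if (!nrow(hits)) next
      hits <- hits[order(hits$start), , drop = FALSE]
      ords <- stats::ave(seq_len(nrow(hits)), hits$motif, FUN = seq_along)
      sites <- c(sites, paste0(hits$motif, "#", ords))
    }
    data.frame(key = g$key, region_class = g$region_class,
               n_ssr = length(unique(sites)), n_members = nrow(mem),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SSR presence vs region class association (SC vs IR)
#'
#' Builds the 2x2 table of SSR-containing vs SSR-lacking loci in single-copy
#' vs inverted-repeat regions and applies the two-sided Fisher exact test.
#'
#' @param census output of [genus_ssr_census()] (or a pooled table).
#' @return list with the 2x2 `table` and the Fisher `p`.
#' @export
ssr_region_association <- function(census) {
  if (!nrow(census)) stop("empty census")
  tab <- matrix(c(sum(census$n_ssr > 0 & census$region_class == "SC"),
                  sum(census$n_ssr > 0 & census$region_class == "IR"),
                  sum(census$n_ssr == 0 & census$region_class == "SC"),
                  sum(census$n_ssr == 0 & census$region_class == "IR")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("SSR", "noSSR"), c("SC", "IR")))
  list(table = tab, p = fisher_exact_two_sided(tab))
}
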