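#' Load a gene/TE annotation as genomic ranges
#'
#' Accepts a `GRanges` directly, or a path to a GFF3 or BED file (imported
#' with \pkg{rtracklayer}, which handles each format's coordinate
#' convention). For GFF3 input, features are filtered to `feature_type`.
#'
#' @param annotation `GRanges` or file path (`.gff`, `.gff3`, `.bed`,
#'   optionally gzipped).
#' @param feature_type GFF3 feature type to keep (default `"gene"`);
#'   ignored for BED input.
#' @return A `GRanges`.
#' @export
read_annotation <- function(annotation, feature_type = "gene") {
  if (methods::is(annotation, "GRanges")) {
    gr <- annotation
    if ("type" %in% names(S4Vectors::mcols(gr)) && !is.null(feature_type)) {
      gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
    }
    return(gr)
  }
  if (!file.exists(annotation)) {
    abort(sprintf("annotation file not found: %s", annotation))
  }
  gr <- rtracklayer::import(annotation)
  if ("type" %in% names(S4Vectors::mcols(gr)) && !is.null(feature_type)) {
    gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
  }
  gr
}

annotation_ids <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("ID", "Name", "gene_id", "name")) {
    if (col %in% names(mc) && !all(is.na(mc[[col]]))) {
      return(as.character(mc[[col]]))
    }
  }
  paste0("feature_", seq_along(gr))
}

sites_as_granges <- function(mat) {
  sites <- meth_sites(mat)
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
}

#' Restrict a call matrix to sites overlapping annotated features
#'
#' Keeps sites whose (0-based) anchor position falls inside any selected
#' feature interval; intervals are treated as half-open on the internal
#' 0-based scale, matching BED semantics.
#'
#' @param mat A `meth_matrix`.
#' @param annotation `GRanges` or GFF3/BED path (see [read_annotation()]).
#' @param feature_type GFF3 feature type (default `"gene"`).
#' @return The sub-matrix of overlapping sites (a `meth_matrix`); empty
#'   with a warning when nothing overlaps.
#' @export
intersect_annotation <- function(mat, annotation, feature_type = "gene") {
  gr <- read_annotation(annotation, feature_type)
  if (length(gr) == 0) {
    warn("annotation has no features of the requested type.")
    return(mat[0, , drop = FALSE])
  }
  hits <- GenomicRanges::findOverlaps(sites_as_granges(mat), gr)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  if (length(keep) == 0) warn("no sites overlap the annotation.")
  mat[keep, , drop = FALSE]
}

#' Per-gene methylation summary for one accession
#'
#' For each annotated gene, computes the fraction of binarized sites in
#' the gene body that are methylated, separately per sequence context, from
#' a single accession's calls.
#'
#' @param calls A binarized call tibble for one accession (see
#'   [binarize_calls()]).
#' @param annotation `GRanges` or GFF3/BED path.
#' @param feature_type GFF3 feature type (default `"gene"`).
#' @return A tibble with one row per gene: `gene_id`, then `n_<ctx>` and
#'   `frac_m<ctx>` for each of CG, CHG, CHH (`frac` is `NA` where a context
#'   has no callable sites).
#' @export
gene_methylation_summary <- function(calls, annotation,
                                     feature_type = "gene") {
  if (!"state" %in% names(calls)) {
    abort("`calls` must be binarized; run binarize_calls().")
  }
  gr <- read_annotation(annotation, feature_type)
  if (length(gr) == 0) abort("annotation has no features.")
  ids <- annotation_ids(gr)
  site_gr <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(site_gr, gr)
  hit_tbl <- tibble::tibble(
    gene_id = ids[S4Vectors::subjectHits(hits)],
    context = calls$context[S4Vectors::queryHits(hits)],
    state = calls$state[S4Vectors::queryHits(hits)]
  )
  long <- hit_tbl |>
    dplyr::filter(!is.na(.data$state)) |>
    dplyr::group_by(.data$gene_id, .data$context) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_m = mean(.data$state == "M"),
      .groups = "drop"
    )
  scaffold <- tidyr::expand_grid(
    gene_id = unique(ids), context = VALID_CONTEXTS
  )
  scaffold |>
    dplyr::left_join(long, by = c("gene_id", "context")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(
      names_from = "context",
      values_from = c("n", "frac_m"),
      names_glue = "{.value}_{context}"
    ) |>
    dplyr::rename(
      frac_mCG = "frac_m_CG", frac_mCHG = "frac_m_CHG",
      frac_mCHH = "frac_m_CHH"
    )
}

#' Classify gene-body methylation status
#'
#' A gene is body-methylated (`BM`) when more than 90% of its CG sites are
#' methylated and fewer than 5% of its CHG and CHH sites are; the CHG/CHH
#' condition filters out genes with TE-like methylation, which are labelled
#' `TE-like` (at least 5% methylated CHG or CHH). Genes with all three
#' fractions below 5% are unmethylated (`UM`). Anything else — including
#' genes with too few callable sites in any context — is `unclassified`.
#'
#' @param summary Output of [gene_methylation_summary()].
#' @param min_sites_per_context Minimum callable sites required in each
#'   context for a confident call (default 5).
#' @return The input with a `class` column
#'   (`BM` / `UM` / `TE-like` / `unclassified`).
#' @export
classify_gene_methylation <- function(summary, min_sites_per_context = 5) {
  summary |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$n_CG < min_sites_per_context |
          .data$n_CHG < min_sites_per_context |
          .data$n_CHH < min_sites_per_context ~ "unclassified",
        .data$frac_mCHG >= 0.05 | .data$frac_mCHH >= 0.05 ~ "TE-like",
        .data$frac_mCG > 0.90 ~ "BM",
        .data$frac_mCG < 0.05 ~ "UM",
        TRUE ~ "unclassified"
      )
    )
}

per_site_diversity <- function(states) {
  n_m <- rowSums(states == "M", na.rm = TRUE)
  n_u <- rowSums(states == "U", na.rm = TRUE)
  k <- n_m + n_u
  ifelse(k >= 2, 2 * n_m * n_u / (k * (k - 1)), NA_real_)
}

#' Methylation diversity in sliding windows
#'
#' Per-site diversity is the pairwise mismatch fraction
#' `2 nM nU / (k (k-1))` over the `k` non-missing accessions at the site
#' (the probability that two sampled accessions differ in state). The
#' track averages this over sites in sliding windows along each
#' chromosome. Windows with no informative sites are flagged undefined;
#' windows with fewer than `min_sites` informative sites are flagged
#' low-confidence.
#'
#' @param mat A `meth_matrix` with site coordinates.
#' @param window Window width in bp (default 1e6).
#' @param step Step between window starts in bp (default 1e5);
#'   `window >= step > 0`.
#' @param min_sites Low-confidence threshold (default 10).
#' @return A tibble of class `diversity_track`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_sites`, `diversity`, `low_confidence`.
#' @export
windowed_diversity <- function(mat, window = 1e6, step = 1e5,
                               min_sites = 10) {
  if (!(window >= step && step > 0)) abort("need window >= step > 0.")
  sites <- meth_sites(mat)
  div <- per_site_diversity(meth_states(mat))
  out <- purrr::map_dfr(split(seq_len(nrow(sites)), sites$chrom),
    function(idx) {
      pos <- sites$pos[idx]
      d <- div[idx]
      starts <- seq(0, max(pos), by = step)
      purrr::map_dfr(starts, function(s) {
        in_win <- pos >= s & pos < s + window
        vals <- d[in_win & !is.na(d)]
        tibble::tibble(
          chrom = sites$chrom[idx[1]],
          start = s, end = s + window,
          n_sites = length(vals),
          diversity = if (length(vals)) mean(vals) else NA_real_,
          low_confidence = length(vals) < min_sites
        )
      })
    })
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  class(out) <- c("diversity_track", class(out))
  out
}

#' Write a diversity track as bedGraph
#'
#' Undefined windows are skipped. Coordinates are 0-based half-open, as
#' bedGraph requires.
#'
#' @param track A `diversity_track` tibble.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = "methylation_diversity") {
  keep <- track[!is.na(track$diversity), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  writeLines(sprintf("%s\t%d\t%d\t%s", keep$chrom, as.integer(keep$start),
                     as.integer(keep$end),
                     format(keep$diversity, digits = 8, trim = TRUE)), con)
  invisible(path)
}
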