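VALID_CONTEXTS <- c("CG", "CHG", "CHH")
VALID_STRANDS <- c("+", "-", "both")

#' Read a per-cytosine methylation report
#'
#' Reads the simple per-cytosine TSV dialect produced by bisulfite callers:
#' six unnamed columns — chromosome, 1-based position, strand (`+`/`-`,
#' or `both` for strand-collapsed CG reports), context (`CG`/`CHG`/`CHH`),
#' methylated read count, total read count.
#' Positions are converted to the package's internal 0-based convention and
#' rows are returned sorted by (chromosome, position, strand). Gzipped
#' files are read transparently.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @param permissive If `FALSE` (default) any malformed row aborts with its
#'   line number; if `TRUE` malformed rows are skipped with a warning.
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `meth_reads`, `total_reads`, `level` (`NA` when
#'   `total_reads` is 0).
#' @export
read_cytosine_report <- function(path, permissive = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "context",
                  "meth_reads", "total_reads"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_double(),
      strand = readr::col_character(),
      context = readr::col_character(),
      meth_reads = readr::col_double(),
      total_reads = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    warn(sprintf("empty cytosine report: %s", path))
    return(empty_calls())
  }
  parse_problems <- readr::problems(raw)
  bad_parse <- unique(parse_problems$row)
  bad <- which(
    is.na(raw$chrom) | is.na(raw$pos) | raw$pos < 1 |
      raw$pos != floor(raw$pos) |
      !(raw$strand %in% VALID_STRANDS) |
      !(raw$context %in% VALID_CONTEXTS) |
      is.na(raw$meth_reads) | is.na(raw$total_reads) |
      raw$meth_reads < 0 | raw$total_reads < 0 |
      raw$meth_reads > raw$total_reads
  )
  bad <- sort(union(bad, bad_parse))
  if (length(bad)) {
    msg <- sprintf(
      "%d malformed row(s) in %s (lines %s%s)",
      length(bad), path,
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""
    )
    if (!permissive) abort(msg)
    warn(paste0(msg, "; skipped."))
    raw <- raw[-bad, , drop = FALSE]
  }
  out <- tibble::tibble(
    chrom = raw$chrom,
    pos = as.integer(raw$pos) - 1L,
    strand = raw$strand,
    context = raw$context,
    meth_reads = as.integer(raw$meth_reads),
    total_reads = as.integer(raw$total_reads),
    level = ifelse(raw$total_reads > 0,
                   raw$meth_reads / raw$total_reads, NA_real_)
  )
  dplyr::arrange(out, .data$chrom, .data$pos, .data$strand)
}

empty_calls <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), strand = character(),
    context = character(), meth_reads = integer(), total_reads = integer(),
    level = double()
  )
}

#' Write a per-cytosine call table in the report TSV dialect
#'
#' Inverse of [read_cytosine_report()]: positions are written 1-based.
#'
#' @param calls A call tibble (see [read_cytosine_report()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path) {
  out <- data.frame(
    chrom = calls$chrom, pos = calls$pos + 1L, strand = calls$strand,
    context = calls$context, meth_reads = calls$meth_reads,
    total_reads = calls$total_reads
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse symmetric CG sites across strands
#'
#' CG methylation is maintained symmetrically on the two strands, so the
#' two cytosines of a CG dinucleotide (plus strand at position `p`, minus
#' strand at `p + 1`) are treated as one epiallele: read counts are pooled
#' and the collapsed site is anchored at the plus-strand position with
#' `strand = "both"`. Unpaired CG sites pass through unchanged, as do all
#' CHG/CHH sites.
#'
#' @param calls A call tibble from [read_cytosine_report()].
#' @return A call tibble with paired CG rows merged.
#' @export
collapse_cg_strands <- function(calls) {
  cg <- calls$context == "CG"
  plus <- calls[cg & calls$strand == "+", , drop = FALSE]
  minus <- calls[cg & calls$strand == "-", , drop = FALSE]
  other <- calls[!cg | calls$strand == "both", , drop = FALSE]

  key_plus <- paste(plus$chrom, plus$pos)
  key_minus <- paste(minus$chrom, minus$pos - 1L)
  i <- match(key_plus, key_minus)
  paired <- !is.na(i)

  merged <- plus[paired, , drop = FALSE]
  j <- i[paired]
  merged$meth_reads <- merged$meth_reads + minus$meth_reads[j]
  merged$total_reads <- merged$total_reads + minus$total_reads[j]
  merged$strand <- "both"
  merged$level <- ifelse(merged$total_reads > 0,
                         merged$meth_reads / merged$total_reads, NA_real_)

  lone_minus <- minus[setdiff(seq_len(nrow(minus)), j), , drop = FALSE]
  out <- dplyr::bind_rows(other, plus[!paired, , drop = FALSE],
                          lone_minus, merged)
  dplyr::arrange(out, .data$chrom, .data$pos, .data$strand)
}

#' Binarize per-site methylation observations
#'
#' A site is called missing when its coverage is below `min_coverage`,
#' methylated (`M`) when its level is at or above `methylated_threshold`
#' (the threshold is inclusive), and unmethylated (`U`) otherwise.
#'
#' @param calls A call tibble.
#' @param min_coverage Minimum total reads for a call (default 3).
#' @param methylated_threshold Level at/above which a site is `M`
#'   (default 0.5).
#' @return The input with a `state` column (`"M"`, `"U"` or `NA`).
#' @export
binarize_calls <- function(calls, min_coverage = 3,
                           methylated_threshold = 0.5) {
  if (min_coverage < 1) abort("`min_coverage` must be >= 1.")
  if (methylated_threshold <= 0 || methylated_threshold > 1) {
    abort("`methylated_threshold` must be in (0, 1].")
  }
  level <- ifelse(calls$total_reads > 0,
                  calls$meth_reads / calls$total_reads, NA_real_)
  calls$state <- dplyr::case_when(
    calls$total_reads < min_coverage ~ NA_character_,
    level >= methylated_threshold ~ "M",
    TRUE ~ "U"
  )
  calls
}

#' Assemble binarized calls from several accessions into a call matrix
#'
#' Aligns sites across accessions by (chromosome, position, strand,
#' context). The `"intersection"` policy keeps only sites with a
#' non-missing state in every accession (complete cases); `"union"` keeps
#' every site seen in any accession and records missing states.
#'
#' @param calls_list Named list of binarized call tibbles (one per
#'   accession; see [binarize_calls()]). At least two accessions.
#' @param policy `"intersection"` (default) or `"union"`.
#' @return A `meth_matrix`: a tibble with site columns `chrom`, `pos`,
#'   `strand`, `context` and one state column per accession, plus an
#'   `accessions` attribute.
#' @export
assemble_call_matrix <- function(calls_list,
                                 policy = c("intersection", "union")) {
  policy <- match.arg(policy)
  if (length(calls_list) < 2) abort("need at least 2 accessions.")
  if (is.null(names(calls_list)) || any(names(calls_list) == "")) {
    abort("`calls_list` must be a named list (accession ids).")
  }
  per_acc <- purrr::imap(calls_list, function(df, id) {
    if (!"state" %in% names(df)) {
      abort(sprintf("accession '%s' is not binarized; run binarize_calls().",
                    id))
    }
    df <- df[c("chrom", "pos", "strand", "context", "state")]
    names(df)[5] <- id
    df
  })
  wide <- purrr::reduce(per_acc, function(a, b) {
    dplyr::full_join(a, b, by = c("chrom", "pos", "strand", "context"))
  })
  wide <- dplyr::arrange(wide, .data$chrom, .data$pos, .data$strand)
  acc <- names(calls_list)
  if (policy == "intersection") {
    keep <- stats::complete.cases(wide[acc])
    wide <- wide[keep, , drop = FALSE]
  }
  new_meth_matrix(wide, acc)
}

new_meth_matrix <- function(tbl, accessions) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("chrom", "pos", "strand", "context") %in% names(tbl)),
            all(accessions %in% names(tbl)))
  states <- as.matrix(tbl[accessions])
  if (!all(states %in% c("M", "U") | is.na(states))) {
    abort("states must be 'M', 'U' or NA.")
  }
  class(tbl) <- c("meth_matrix", class(tbl))
  attr(tbl, "accessions") <- accessions
  tbl
}

#' Accessors for a methylation call matrix
#'
#' `meth_accessions()` returns the accession ids, `meth_states()` the
#' sites-by-accessions character matrix of states, and `meth_sites()` the
#' site metadata columns.
#'
#' @param mat A `meth_matrix` (see [assemble_call_matrix()]).
#' @return See each function's description.
#' @export
meth_accessions <- function(mat) {
  acc <- attr(mat, "accessions")
  if (is.null(acc)) abort("not a meth_matrix: missing accessions attribute.")
  acc
}

#' @rdname meth_accessions
#' @export
meth_states <- function(mat) {
  as.matrix(mat[meth_accessions(mat)])
}

#' @rdname meth_accessions
#' @export
meth_sites <- function(mat) {
  tibble::as_tibble(mat[c("chrom", "pos", "strand", "context")])
}

#' Genome-wide methylation level per accession and context
#'
#' GML is the percentage of (covered) cytosines that are methylated,
#' computed per accession within each requested sequence context over the
#' non-missing sites of the matrix. An accession-context pair with zero
#' non-missing sites is returned with `gml = NA` and `defined = FALSE`,
#' never silently as 0.
#'
#' @param mat A `meth_matrix`.
#' @param contexts Subset of `c("CG", "CHG", "CHH")`.
#' @return A tibble: `accession`, `context`, `n_m`, `n_u`, `gml`
#'   (percentage), `defined`.
#' @export
compute_gml <- function(mat, contexts = VALID_CONTEXTS) {
  contexts <- match.arg(contexts, VALID_CONTEXTS, several.ok = TRUE)
  if (nrow(mat) == 0) abort("matrix has no sites.")
  states <- meth_states(mat)
  ctx <- meth_sites(mat)$context
  purrr::map_dfr(contexts, function(cc) {
    s <- states[ctx == cc, , drop = FALSE]
    tibble::tibble(
      accession = meth_accessions(mat),
      context = cc,
      n_m = unname(colSums(s == "M", na.rm = TRUE)),
      n_u = unname(colSums(s == "U", na.rm = TRUE))
    )
  }) |>
    dplyr::mutate(
      defined = (.data$n_m + .data$n_u) > 0,
      gml = dplyr::if_else(.data$defined,
                           100 * .data$n_m / (.data$n_m + .data$n_u),
                           NA_real_)
    )
}

#' Write / read a methylation call matrix as TSV
#'
#' Sites as rows; columns `chrom`, `pos` (1-based on disk), `strand`,
#' `context`, then one column per accession with values `M`, `U` or `.`
#' for missing. `write_call_matrix()` also writes a JSON sidecar
#' (`<path>.json`) with accession ids and provenance. The round trip is
#' exact.
#'
#' @param mat A `meth_matrix`.
#' @param path Output TSV path.
#' @return `write_call_matrix()` returns `path` invisibly;
#'   `read_call_matrix()` returns the `meth_matrix`.
#' @export
write_call_matrix <- function(mat, path) {
  acc <- meth_accessions(mat)
  out <- as.data.frame(mat)
  out$pos <- out$pos + 1L
  for (a in acc) out[[a]][is.na(out[[a]])] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(
    accessions = acc,
    n_sites = nrow(mat),
    package = "epimsfs",
    version = as.character(packageVersion("epimsfs"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_call_matrix
#' @export
read_call_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    strand = readr::col_character(), context = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  tbl$pos <- tbl$pos - 1L
  acc <- setdiff(names(tbl), c("chrom", "pos", "strand", "context"))
  for (a in acc) tbl[[a]][tbl[[a]] == "."] <- NA_character_
  new_meth_matrix(tbl, acc)
}
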