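#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Methylation site frequency spectrum
#'
#' The mSFS records, over segregating cytosine sites, how many of the `n`
#' sampled accessions carry the unmethylated (U) epiallele. Class `b`
#' (for `b = 1..n-1`) counts sites at which exactly `b` accessions are U;
#' monomorphic sites (`b = 0` or `b = n`) are discarded before analysis.
#' Counts may be fractional when the spectrum was produced by
#' hypergeometric projection.
#'
#' @param counts Numeric vector of class counts, either of length `n - 1`
#'   (classes `1..n-1` in order) or named by class.
#' @param n Sample size.
#' @param n_monomorphic_dropped,n_missing_dropped Bookkeeping: sites
#'   discarded as monomorphic, and sites dropped for missing data.
#' @return A tibble of class `msfs` with columns `b` and `count` and
#'   attributes `n`, `n_monomorphic_dropped`, `n_missing_dropped`,
#'   `n_sites_input`.
#' @examples
#' msfs(c(3, 2, 0, 1), n = 5)
#' @export
msfs <- function(counts, n, n_monomorphic_dropped = 0,
                 n_missing_dropped = 0) {
  if (n < 2 || n != floor(n)) abort("`n` must be an integer >= 2.")
  if (!is.null(names(counts))) {
    full <- setNames(numeric(n - 1L), as.character(seq_len(n - 1L)))
    bad <- setdiff(names(counts), names(full))
    if (length(bad)) {
      abort(paste0("class labels outside 1..n-1: ",
                   paste(bad, collapse = ", ")))
    }
    full[names(counts)] <- counts
    counts <- unname(full)
  }
  if (length(counts) != n - 1L) {
    abort("`counts` must have length n - 1 (classes 1..n-1).")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("counts must be finite and non-negative.")
  }
  out <- tibble::tibble(b = seq_len(n - 1L), count = as.numeric(counts))
  class(out) <- c("msfs", class(out))
  attr(out, "n") <- as.integer(n)
  attr(out, "n_monomorphic_dropped") <- n_monomorphic_dropped
  attr(out, "n_missing_dropped") <- n_missing_dropped
  attr(out, "n_sites_input") <-
    sum(counts) + n_monomorphic_dropped + n_missing_dropped
  out
}

#' @rdname msfs
#' @param x An `msfs` object.
#' @export
msfs_n <- function(x) {
  n <- attr(x, "n")
  if (is.null(n)) abort("not an msfs object: missing `n` attribute.")
  n
}

#' @rdname msfs
#' @export
msfs_counts <- function(x) {
  stopifnot(all(c("b", "count") %in% names(x)))
  x$count[order(x$b)]
}

#' Build the mSFS from a complete-case methylation call matrix
#'
#' For each site, counts the number of accessions in the U state; sites
#' that are monomorphic in the sample (all M or all U) are discarded, and
#' the remaining segregating sites are tallied into epiallelic classes.
#' The input must have no missing states: apply the intersection policy in
#' [assemble_call_matrix()] or use [project_msfs()] for union-policy data.
#'
#' @param mat A [meth_matrix] (see [assemble_call_matrix()]).
#' @return An [msfs()] object.
#' @export
build_msfs <- function(mat) {
  states <- meth_states(mat)
  n <- ncol(states)
  if (n < 2) abort("need at least 2 accessions.")
  if (anyNA(states)) {
    abort(paste(
      "matrix contains missing states; use the intersection policy",
      "or `project_msfs()`."
    ))
  }
  b <- rowSums(states == "U")
  mono <- b == 0 | b == n
  if (all(mono) && length(b) > 0) {
    warn("all sites are monomorphic; the mSFS is empty.")
  }
  tab <- tabulate(b[!mono], nbins = n - 1L)
  msfs(tab, n = n, n_monomorphic_dropped = sum(mono))
}

#' Project an mSFS with missing data down to a common sample size
#'
#' Union-policy call matrices have a different effective sample size `k`
#' at each site. Projection maps each site's observed U-count `b` (out of
#' `k` non-missing accessions) onto expected class counts in a spectrum of
#' size `m`, using hypergeometric subsampling weights
#' `P(j | b, k, m) = dhyper(j, b, k - b, m)`. Mass falling on classes `0`
#' and `m` is monomorphic in the subsample and added to the dropped tally.
#' The resulting counts are expected (fractional) values.
#'
#' @param mat A [meth_matrix], possibly with missing states, or a data
#'   frame with per-site columns `b` (U-count) and `k` (effective sample
#'   size).
#' @param m Target sample size; every site must have `k >= m >= 2`.
#' @return An [msfs()] object with fractional counts.
#' @export
project_msfs <- function(mat, m) {
  if (m < 2 || m != floor(m)) abort("`m` must be an integer >= 2.")
  if (inherits(mat, "meth_matrix")) {
    states <- meth_states(mat)
    site_tbl <- tibble::tibble(
      b = rowSums(states == "U", na.rm = TRUE),
      k = rowSums(!is.na(states))
    )
  } else {
    stopifnot(all(c("b", "k") %in% names(mat)))
    site_tbl <- tibble::as_tibble(mat[c("b", "k")])
  }
  site_tbl <- site_tbl[site_tbl$k > 0, , drop = FALSE]
  if (any(site_tbl$k < m)) {
    abort(sprintf(
      "%d site(s) have effective sample size below m = %d.",
      sum(site_tbl$k < m), m
    ))
  }
  expected <- numeric(m + 1L)
  # group identical (b, k) pairs: one dhyper call per distinct pair
  grp <- dplyr::count(site_tbl, .data$b, .data$k)
  for (i in seq_len(nrow(grp))) {
    w <- dhyper(0:m, grp$b[i], grp$k[i] - grp$b[i], m)
    expected <- expected + grp$n[i] * w
  }
  msfs(expected[2:m], n = m,
       n_monomorphic_dropped = expected[1] + expected[m + 1L])
}

#' @export
print.msfs <- function(x, ...) {
  cat(sprintf(
    "<msfs> n = %d, %s segregating sites in %d classes (%s monomorphic dropped)\n",
    msfs_n(x), format(round(sum(x$count), 2)), nrow(x),
    format(round(attr(x, "n_monomorphic_dropped"), 2))
  ))
  NextMethod()
}

#' Write / read an mSFS as TSV with a JSON metadata header
#'
#' The on-disk form is a two-column TSV (`b`, `count`) preceded by a single
#' comment line `# <json>` carrying `n`, the dropped-site tallies and
#' provenance (package version, timestamp).
#'
#' @param x An [msfs()] object.
#' @param path Output file path.
#' @return `write_msfs()` returns `path` invisibly; `read_msfs()` returns
#'   the [msfs()] object.
#' @export
write_msfs <- function(x, path) {
  header <- jsonlite::toJSON(
    list(
      n = msfs_n(x),
      n_monomorphic_dropped = attr(x, "n_monomorphic_dropped"),
      n_missing_dropped = attr(x, "n_missing_dropped"),
      package = "epimsfs",
      version = as.character(packageVersion("epimsfs"))
    ),
    auto_unbox = TRUE, digits = NA
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines("b\tcount", con)
  writeLines(sprintf("%d\t%s", x$b, format(x$count, digits = 17,
                                           scientific = FALSE,
                                           trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_msfs
#' @export
read_msfs <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# ")) {
    abort("not an mSFS file: missing JSON header line.")
  }
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  body <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  counts <- setNames(body$count, as.character(body$b))
  msfs(counts, n = meta$n,
       n_monomorphic_dropped = meta$n_monomorphic_dropped %||% 0,
       n_missing_dropped = meta$n_missing_dropped %||% 0)
}
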