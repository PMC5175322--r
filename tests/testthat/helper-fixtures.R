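# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A call tibble in the internal (0-based) representation.
make_calls <- function(chrom, pos1, strand, context, meth, total) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos1) - 1L, strand = strand,
    context = context, meth_reads = as.integer(meth),
    total_reads = as.integer(total),
    level = ifelse(total > 0, meth / total, NA_real_)
  )
}

# Build a meth_matrix directly from a character matrix of states
# ("M"/"U"/NA), sites in rows, accessions in columns.
make_matrix <- function(states, pos = NULL, chrom = "chr1",
                        context = "CG") {
  states <- as.matrix(states)
  n_sites <- nrow(states)
  acc <- colnames(states) %||% sprintf("acc%02d", seq_len(ncol(states)))
  colnames(states) <- acc
  tbl <- tibble::tibble(
    chrom = rep(chrom, n_sites),
    pos = as.integer(pos %||% (seq_len(n_sites) * 10L)),
    strand = rep("both", n_sites),
    context = rep(context, n_sites)
  )
  epimsfs:::new_meth_matrix(dplyr::bind_cols(tbl, tibble::as_tibble(states)),
                            acc)
}

# A matrix with a prescribed per-site U-count vector.
matrix_from_ucounts <- function(u_counts, n_acc) {
  states <- t(vapply(u_counts, function(b) {
    s <- rep("M", n_acc)
    if (b > 0) s[seq_len(b)] <- "U"
    s
  }, character(n_acc)))
  make_matrix(states)
}

# The worked-example layout: 5 accessions x 8 sites, exactly two sites
# monomorphic (one all-M, one all-U), six segregating.
fig_toy_matrix <- function() {
  matrix_from_ucounts(c(1, 2, 0, 3, 4, 5, 2, 1), n_acc = 5)
}

# Write a minimal GFF3 gene annotation; ranges are 1-based inclusive.
write_test_gff <- function(path, genes) {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t+\t.\tID=%s",
            genes$chrom,
            if ("type" %in% names(genes)) genes$type else "gene",
            genes$start, genes$end, genes$id)
  )
  writeLines(lines, path)
  path
}

expect_tv_less_than <- function(p_emp, p_model, bound) {
  tv <- 0.5 * sum(abs(p_emp - p_model))
  expect_lt(tv, bound)
}
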