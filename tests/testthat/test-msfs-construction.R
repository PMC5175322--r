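test_that("the 5x8 worked example yields six segregating sites", {
  mat <- fig_toy_matrix()
  sfs <- build_msfs(mat)
  expect_equal(msfs_n(sfs), 5L)
  expect_equal(sum(msfs_counts(sfs)), 6)
  expect_equal(attr(sfs, "n_monomorphic_dropped"), 2)
})

test_that("build_msfs tallies U-counts and drops monomorphic sites", {
  mat <- matrix_from_ucounts(c(1, 2, 2, 0, 3), n_acc = 3)
  sfs <- build_msfs(mat)
  expect_equal(msfs_counts(sfs), c(1, 2))
  expect_equal(attr(sfs, "n_monomorphic_dropped"), 2)
  # conservation: segregating + dropped = input sites
  expect_equal(sum(msfs_counts(sfs)) + attr(sfs, "n_monomorphic_dropped"),
               nrow(mat))
  expect_warning(build_msfs(matrix_from_ucounts(c(0, 3, 3), 3)),
                 "monomorphic")
  with_na <- make_matrix(cbind(a = c("M", NA), b = c("U", "M")))
  expect_error(build_msfs(with_na), "missing")
})

test_that("the spectrum is invariant to accession relabeling", {
  set.seed(3)
  states <- matrix(sample(c("M", "U"), 400, TRUE), 50, 8)
  mat <- make_matrix(states)
  perm <- sample(8)
  mat_perm <- make_matrix(states[, perm])
  expect_equal(msfs_counts(build_msfs(mat)),
               msfs_counts(build_msfs(mat_perm)))
})

test_that("flipping all states mirrors the spectrum", {
  set.seed(4)
  states <- matrix(sample(c("M", "U"), 600, TRUE), 75, 8)
  flipped <- ifelse(states == "M", "U", "M")
  c1 <- msfs_counts(build_msfs(make_matrix(states)))
  c2 <- msfs_counts(build_msfs(make_matrix(flipped)))
  expect_equal(c1, rev(c2))
})

test_that("projection to the original sample size is the identity", {
  set.seed(5)
  states <- matrix(sample(c("M", "U"), 300, TRUE), 50, 6)
  mat <- make_matrix(states)
  direct <- build_msfs(mat)
  proj <- project_msfs(mat, m = 6)
  expect_equal(msfs_counts(proj), msfs_counts(direct), tolerance = 1e-12)
  expect_equal(attr(proj, "n_monomorphic_dropped"),
               attr(direct, "n_monomorphic_dropped"), tolerance = 1e-12)
})

test_that("projection weights follow the hypergeometric law", {
  # site with b = 2 of k = 4, projected to m = 2:
  # weights {0: 1/6, 1: 4/6, 2: 1/6}; ends dropped as monomorphic
  sfs <- project_msfs(tibble::tibble(b = 2, k = 4), m = 2)
  expect_equal(msfs_counts(sfs), 4 / 6, tolerance = 1e-12)
  expect_equal(attr(sfs, "n_monomorphic_dropped"), 2 / 6,
               tolerance = 1e-12)
  # identity cases
  expect_equal(msfs_counts(project_msfs(tibble::tibble(b = 2, k = 4),
                                        m = 4)),
               c(0, 1, 0))
  expect_equal(msfs_counts(project_msfs(tibble::tibble(b = 1, k = 2),
                                        m = 2)), 1)
  expect_error(project_msfs(tibble::tibble(b = 1, k = 3), m = 4),
               "below m")
})

test_that("projection equals brute-force subsample enumeration for k <= 6", {
  # enumerate every subsample of size m and average its spectrum
  for (k in 4:6) {
    for (m in 2:(k - 1)) {
      for (b in 0:k) {
        states <- c(rep("U", b), rep("M", k - b))
        subs <- utils::combn(k, m)
        brute <- numeric(m + 1)
        for (j in seq_len(ncol(subs))) {
          bu <- sum(states[subs[, j]] == "U")
          brute[bu + 1] <- brute[bu + 1] + 1 / ncol(subs)
        }
        proj <- project_msfs(tibble::tibble(b = b, k = k), m = m)
        expect_equal(msfs_counts(proj), brute[2:m], tolerance = 1e-12)
        expect_equal(attr(proj, "n_monomorphic_dropped"),
                     brute[1] + brute[m + 1], tolerance = 1e-12)
      }
    }
  }
})

test_that("projected total mass equals the input site count", {
  set.seed(6)
  sites <- tibble::tibble(k = sample(5:9, 200, TRUE))
  sites$b <- rbinom(200, sites$k, 0.4)
  proj <- project_msfs(sites, m = 5)
  expect_equal(sum(msfs_counts(proj)) + attr(proj, "n_monomorphic_dropped"),
               200, tolerance = 1e-9)
})

test_that("mSFS round-trips through its TSV serialization", {
  sfs <- msfs(c(3.5, 2, 0, 1), n = 5, n_monomorphic_dropped = 2.25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_msfs(sfs, path)
  back <- read_msfs(path)
  expect_equal(msfs_counts(back), msfs_counts(sfs))
  expect_equal(msfs_n(back), 5L)
  expect_equal(attr(back, "n_monomorphic_dropped"), 2.25)
})

test_that("annotation intersection uses half-open interval semantics", {
  # gene covering internal [50, 150): 1-based inclusive 51..150
  gff <- write_test_gff(
    withr::local_tempfile(fileext = ".gff3"),
    tibble::tibble(chrom = "chr1", start = 51, end = 150, id = "g1")
  )
  mat <- make_matrix(
    matrix(c("M", "U", "U", "M"), 2, 2,
           dimnames = list(NULL, c("a", "b"))),
    pos = c(99L, 150L)
  )
  out <- intersect_annotation(mat, gff)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 99L)
  empty_gff <- write_test_gff(
    withr::local_tempfile(fileext = ".gff3"),
    tibble::tibble(chrom = character(), start = integer(),
                   end = integer(), id = character())
  )
  expect_warning(res <- intersect_annotation(mat, empty_gff),
                 "no features|no sites")
  expect_equal(nrow(res), 0)
})

test_that("BED annotations are interpreted on their 0-based convention", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t50\t150\tg1", bed)
  mat <- make_matrix(
    matrix(c("M", "U", "U", "M", "M", "U"), 3, 2,
           dimnames = list(NULL, c("a", "b"))),
    pos = c(49L, 50L, 149L) # BED [50, 150) on the 0-based scale
  )
  out <- intersect_annotation(mat, bed)
  expect_equal(out$pos, c(50L, 149L))
})

test_that("gene methylation summaries and gbM classes follow thresholds", {
  gff <- write_test_gff(
    withr::local_tempfile(fileext = ".gff3"),
    tibble::tibble(chrom = "chr1", start = c(1, 1001),
                   end = c(1000, 2000), id = c("gBM", "gUM"))
  )
  mk_ctx <- function(base, ctx, frac_m, n = 10) {
    tibble::tibble(
      chrom = "chr1", pos = base + seq_len(n), strand = "+", context = ctx,
      meth_reads = 0L, total_reads = 10L, level = 0,
      state = c(rep("M", round(frac_m * n)),
                rep("U", n - round(frac_m * n)))
    )
  }
  calls <- dplyr::bind_rows(
    mk_ctx(0, "CG", 1.0), mk_ctx(100, "CHG", 0.0), mk_ctx(200, "CHH", 0.0),
    mk_ctx(1000, "CG", 0.0), mk_ctx(1100, "CHG", 0.0),
    mk_ctx(1200, "CHH", 0.0)
  )
  summ <- gene_methylation_summary(calls, gff)
  cls <- classify_gene_methylation(summ, min_sites_per_context = 5)
  expect_equal(cls$class[cls$gene_id == "gBM"], "BM")
  expect_equal(cls$class[cls$gene_id == "gUM"], "UM")
})

test_that("gbM classification thresholds match their definitions", {
  base <- tibble::tibble(
    gene_id = c("bm", "te", "um", "thin"),
    n_CG = c(20, 20, 20, 2), n_CHG = c(20, 20, 20, 20),
    n_CHH = c(20, 20, 20, 20),
    frac_mCG = c(0.95, 0.95, 0.02, 0.95),
    frac_mCHG = c(0.02, 0.10, 0.00, 0.02),
    frac_mCHH = c(0.01, 0.01, 0.00, 0.01)
  )
  out <- classify_gene_methylation(base, min_sites_per_context = 5)
  expect_equal(out$class, c("BM", "TE-like", "UM", "unclassified"))
})

test_that("windowed diversity averages the pairwise mismatch fraction", {
  mat <- make_matrix(
    matrix(c("M", "M", "U", "M"), 2, 2,
           dimnames = list(NULL, c("a", "b"))),
    pos = c(10L, 20L)
  )
  track <- windowed_diversity(mat, window = 100, step = 100, min_sites = 1)
  # site 1 is (M, U): diversity 1; site 2 monomorphic: 0
  expect_equal(track$diversity, 0.5)
  expect_equal(track$n_sites, 2L)
  # empty window flagged undefined
  mat2 <- make_matrix(
    matrix(c("M", "U"), 1, 2, dimnames = list(NULL, c("a", "b"))),
    pos = 250L
  )
  track2 <- windowed_diversity(mat2, window = 100, step = 100)
  expect_true(is.na(track2$diversity[1]))
  expect_true(all(track2$low_confidence))
})

test_that("diversity of diverged lines matches the analytic curve", {
  rates <- epimutation_rates(5e-3, 1e-2)
  t <- 30
  n_sites <- 4e4
  ped <- simulate_ma_pedigree(rates, n_sites = n_sites, n_lines = 2,
                              n_generations = t, seed = 9,
                              keep = "endpoint")
  states <- vapply(ped$lines, function(s) ifelse(s, "M", "U"),
                   character(n_sites))
  mat <- make_matrix(states, pos = seq_len(n_sites))
  track <- windowed_diversity(mat, window = n_sites + 1, step = n_sites + 1)
  d_expected <- divergence_curve(rates, t)
  mc_se <- sqrt(d_expected * (1 - d_expected) / n_sites)
  expect_lt(abs(track$diversity[1] - d_expected), 3 * mc_se)
})

test_that("gene windows diverge faster than TE windows at generation 30", {
  n_sites <- 2e4
  sim_div <- function(rates, seed) {
    ped <- simulate_ma_pedigree(rates, n_sites = n_sites, n_lines = 2,
                                n_generations = 30, seed = seed,
                                keep = "endpoint")
    mean(ped$lines[[1]] != ped$lines[[2]])
  }
  gene_div <- sim_div(athaliana_rates("gene"), 21)
  te_div <- sim_div(athaliana_rates("TE"), 22)
  expect_gt(gene_div, te_div)
  # and the analytic prediction agrees in direction
  expect_gt(divergence_curve(athaliana_rates("gene"), 30),
            divergence_curve(athaliana_rates("TE"), 30))
})

test_that("diversity tracks serialize to bedGraph", {
  track <- predict_regional_diversity(
    tibble::tibble(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5),
                   gene_density = c(0.9, 0.1), te_density = c(0.05, 0.8)),
    t = 30
  )
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(track, path)
  lines <- readLines(path)
  expect_match(lines[1], "type=bedGraph")
  expect_equal(length(lines), 3)
})
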