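#' Per-generation epimutation rates
#'
#' Per-site, per-haploid-genome, per-generation probabilities of a
#' methylation gain (`mu_UM`, a U site becoming M) and a loss (`mu_MU`).
#' These are the mutation-accumulation-line-scale quantities; the
#' population-scaled counterparts live in [pop_params()].
#'
#' @param mu_UM,mu_MU Gain and loss probabilities in `[0, 1]` with
#'   `mu_UM + mu_MU < 1`.
#' @param annotation_class Optional label (`"genome"`, `"gene"`, `"TE"`,
#'   ...).
#' @return An object of class `epi_rates`.
#' @seealso [athaliana_rates()] for published estimates.
#' @export
epimutation_rates <- function(mu_UM, mu_MU, annotation_class = NA_character_) {
  if (!is.numeric(mu_UM) || !is.numeric(mu_MU) ||
      mu_UM < 0 || mu_MU < 0 || mu_UM > 1 || mu_MU > 1) {
    abort("rates must lie in [0, 1].")
  }
  if (mu_UM + mu_MU >= 1) abort("mu_UM + mu_MU must be < 1.")
  structure(
    list(mu_UM = mu_UM, mu_MU = mu_MU,
         annotation_class = annotation_class),
    class = "epi_rates"
  )
}

#' @export
print.epi_rates <- function(x, ...) {
  cat(sprintf("<epi_rates%s> gain mu_UM = %g, loss mu_MU = %g\n",
              if (is.na(x$annotation_class)) ""
              else paste0(": ", x$annotation_class),
              x$mu_UM, x$mu_MU))
  invisible(x)
}

#' Published A. thaliana CG epimutation rate estimates
#'
#' Mutation-accumulation-line estimates of spontaneous CG epimutation
#' rates, per site per haploid genome per generation: genome-wide, gain
#' 2.56e-4 and loss 6.3e-4 (loss about 2.5 times as likely as gain, giving
#' roughly 30% of CG sites methylated at neutral equilibrium);
#' gene bodies, gain 3.48e-4 and loss 1.47e-3; transposable elements,
#' gain 3.24e-4 and loss 1.20e-5 (a strong bias toward gain, consistent
#' with constitutive TE silencing).
#'
#' @param class One of `"genome"`, `"gene"`, `"TE"`.
#' @return An [epimutation_rates()] object.
#' @examples
#' athaliana_rates("genome")
#' @export
athaliana_rates <- function(class = c("genome", "gene", "TE")) {
  class <- match.arg(class)
  switch(class,
    genome = epimutation_rates(2.56e-4, 6.3e-4, "genome"),
    gene = epimutation_rates(3.48e-4, 1.47e-3, "gene"),
    TE = epimutation_rates(3.24e-4, 1.20e-5, "TE")
  )
}

#' Stationary methylated fraction of the two-state epimutation chain
#'
#' At gain/loss balance the probability that a site is methylated is
#' `mu_UM / (mu_UM + mu_MU)`.
#'
#' @param rates An [epimutation_rates()] object.
#' @return A single probability.
#' @export
stationary_methylated_fraction <- function(rates) {
  stopifnot(inherits(rates, "epi_rates"))
  if (rates$mu_UM + rates$mu_MU == 0) {
    abort("both rates are zero; the stationary state is undefined.")
  }
  rates$mu_UM / (rates$mu_UM + rates$mu_MU)
}

#' Sample site states from the stationary distribution
#'
#' Independent draws with `P(M) = mu_UM / (mu_UM + mu_MU)`.
#'
#' @param rates An [epimutation_rates()] object.
#' @param n_sites Number of sites.
#' @param seed Optional RNG seed.
#' @return Logical vector (`TRUE` = methylated).
#' @export
stationary_state_sample <- function(rates, n_sites, seed = NULL) {
  local_seed(seed)
  runif(n_sites) < stationary_methylated_fraction(rates)
}

# One generation of per-site reversible epimutation on a logical
# methylation vector (TRUE = M).
step_epimutation <- function(state, rates) {
  u <- runif(length(state))
  (state & u >= rates$mu_MU) | (!state & u < rates$mu_UM)
}

#' Simulate a mutation-accumulation pedigree
#'
#' Independent selfing lines descend from a single shared founder; each
#' generation, every unmethylated site gains methylation with probability
#' `mu_UM` and every methylated site loses it with probability `mu_MU`,
#' independently across sites and lines (one haploid epihaplotype per
#' line, matching the per-haploid-genome definition of the rates).
#'
#' @param rates An [epimutation_rates()] object, or a list of them with a
#'   parallel `annotation` integer mask (`per-site rates`): see Details.
#' @param n_sites Number of sites.
#' @param n_lines Number of independent lines.
#' @param n_generations Number of generations to propagate.
#' @param founder `"stationary"`, `"all-M"`, `"all-U"`, or a logical
#'   vector of length `n_sites` (`TRUE` = M).
#' @param seed Optional RNG seed; recorded in the output.
#' @param keep `"trajectory"` stores every generation (sites x
#'   (generations + 1) logical matrix per line); `"endpoint"` stores only
#'   the final generation.
#' @details With a list of rates plus an integer `attr(rates, "mask")` of
#'   length `n_sites` indexing into the list, different annotation classes
#'   evolve under their own rates.
#' @return A list of class `ma_pedigree`: `founder`, `lines` (list of
#'   logical matrices or vectors), `rates`, `n_generations`, `seed`,
#'   `keep`.
#' @export
simulate_ma_pedigree <- function(rates, n_sites, n_lines = 2,
                                 n_generations = 30,
                                 founder = "stationary", seed = NULL,
                                 keep = c("trajectory", "endpoint")) {
  keep <- match.arg(keep)
  stopifnot(n_sites >= 1, n_lines >= 1, n_generations >= 1)
  rate_list <- if (inherits(rates, "epi_rates")) list(rates) else rates
  mask <- attr(rates, "mask") %||% rep(1L, n_sites)
  stopifnot(length(mask) == n_sites,
            all(vapply(rate_list, inherits, TRUE, "epi_rates")))
  local_seed(seed)

  if (is.logical(founder)) {
    stopifnot(length(founder) == n_sites)
    founder_state <- founder
  } else {
    founder_state <- switch(match.arg(founder,
                                      c("stationary", "all-M", "all-U")),
      stationary = {
        pm <- vapply(rate_list, stationary_methylated_fraction, 0)
        runif(n_sites) < pm[mask]
      },
      `all-M` = rep(TRUE, n_sites),
      `all-U` = rep(FALSE, n_sites)
    )
  }

  step_all <- function(state) {
    for (cls in seq_along(rate_list)) {
      idx <- which(mask == cls)
      if (length(idx)) {
        state[idx] <- step_epimutation(state[idx], rate_list[[cls]])
      }
    }
    state
  }

  lines <- vector("list", n_lines)
  for (l in seq_len(n_lines)) {
    if (keep == "trajectory") {
      traj <- matrix(FALSE, n_sites, n_generations + 1L)
      traj[, 1L] <- founder_state
      for (g in seq_len(n_generations)) {
        traj[, g + 1L] <- step_all(traj[, g])
      }
      lines[[l]] <- traj
    } else {
      state <- founder_state
      for (g in seq_len(n_generations)) state <- step_all(state)
      lines[[l]] <- state
    }
  }
  names(lines) <- paste0("line_", seq_len(n_lines))
  structure(
    list(founder = founder_state, lines = lines, rates = rates,
         n_generations = n_generations, seed = seed, keep = keep),
    class = "ma_pedigree"
  )
}

#' Estimate epimutation rates by transition counting in a pedigree
#'
#' The gain rate is estimated as the number of observed U-to-M transitions
#' divided by the number of U site-generations (opportunities), and the
#' loss rate analogously, pooling all lines and generation intervals.
#' Binomial standard errors and Clopper-Pearson 95% upper bounds are
#' attached; a direction with zero opportunities is returned as `NA` and
#' flagged.
#'
#' @param pedigree A `ma_pedigree` simulated with `keep = "trajectory"`.
#' @return A tibble with rows `gain` and `loss`: `direction`,
#'   `n_transitions`, `n_opportunities`, `rate`, `se`, `upper95`,
#'   `defined`.
#' @export
estimate_rates_from_pedigree <- function(pedigree) {
  stopifnot(inherits(pedigree, "ma_pedigree"))
  if (pedigree$keep != "trajectory") {
    abort("pedigree must be simulated with keep = 'trajectory'.")
  }
  gains <- losses <- u_opp <- m_opp <- 0
  for (traj in pedigree$lines) {
    g <- ncol(traj) - 1L
    if (g < 1) abort("need at least 2 consecutive generations.")
    from <- traj[, seq_len(g), drop = FALSE]
    to <- traj[, seq_len(g) + 1L, drop = FALSE]
    gains <- gains + sum(!from & to)
    losses <- losses + sum(from & !to)
    u_opp <- u_opp + sum(!from)
    m_opp <- m_opp + sum(from)
  }
  mk <- function(direction, k, n) {
    defined <- n > 0
    rate <- if (defined) k / n else NA_real_
    tibble::tibble(
      direction = direction,
      n_transitions = k, n_opportunities = n,
      rate = rate,
      se = if (defined) sqrt(rate * (1 - rate) / n) else NA_real_,
      upper95 = if (defined) qbeta(0.975, k + 1, n - k) else NA_real_,
      defined = defined
    )
  }
  out <- dplyr::bind_rows(mk("gain", gains, u_opp), mk("loss", losses, m_opp))
  if (any(!out$defined)) {
    warn("a transition direction had zero opportunities; rate undefined.")
  }
  out
}

#' Expected methylome divergence between two lines
#'
#' Closed form for the expected pairwise mismatch fraction between two
#' lineages that diverged `t` generations ago from a founder at the
#' stationary state:
#' `D(t) = 2 piM piU (1 - lambda^(2t))` with
#' `piM = mu_UM / (mu_UM + mu_MU)`, `piU = 1 - piM` and
#' `lambda = 1 - mu_UM - mu_MU`. Divergence saturates at `2 piM piU`
#' rather than growing linearly, because every site is simultaneously
#' subject to forward and backward epimutation.
#'
#' @param rates An [epimutation_rates()] object.
#' @param t Generations since the common founder (vectorized).
#' @return Expected mismatch fraction(s) in `[0, 1]`.
#' @export
divergence_curve <- function(rates, t) {
  stopifnot(inherits(rates, "epi_rates"))
  if (any(t < 0)) abort("`t` must be non-negative.")
  pm <- stationary_methylated_fraction(rates)
  lambda <- 1 - rates$mu_UM - rates$mu_MU
  2 * pm * (1 - pm) * (1 - lambda^(2 * t))
}

#' Predicted diversity track from annotation densities
#'
#' Combines annotation-specific divergence predictions into a windowed
#' track: each window's prediction is
#' `gene_density * D_gene(t) + te_density * D_TE(t) + residual * D_genome(t)`
#' where each `D` is a [divergence_curve()] value at `t` generations.
#'
#' @param profile A data frame with columns `chrom`, `start`, `end`,
#'   `gene_density`, `te_density` (densities in `[0, 1]`, summing to at
#'   most 1 per window).
#' @param gene_rates,te_rates,genome_rates [epimutation_rates()] objects;
#'   defaults are the published A. thaliana estimates.
#' @param t Generations since divergence.
#' @return A `diversity_track` tibble with a `diversity` column of
#'   predictions.
#' @export
predict_regional_diversity <- function(profile,
                                       gene_rates = athaliana_rates("gene"),
                                       te_rates = athaliana_rates("TE"),
                                       genome_rates = athaliana_rates("genome"),
                                       t = 30) {
  stopifnot(all(c("chrom", "start", "end", "gene_density",
                  "te_density") %in% names(profile)))
  if (any(profile$gene_density < 0 | profile$gene_density > 1 |
          profile$te_density < 0 | profile$te_density > 1 |
          profile$gene_density + profile$te_density > 1 + 1e-9)) {
    abort("densities must lie in [0, 1] and sum to at most 1 per window.")
  }
  resid <- pmax(1 - profile$gene_density - profile$te_density, 0)
  out <- tibble::tibble(
    chrom = profile$chrom, start = profile$start, end = profile$end,
    n_sites = NA_integer_,
    diversity = profile$gene_density * divergence_curve(gene_rates, t) +
      profile$te_density * divergence_curve(te_rates, t) +
      resid * divergence_curve(genome_rates, t),
    low_confidence = FALSE
  )
  class(out) <- c("diversity_track", class(out))
  out
}

#' Wright-Fisher simulation of epiallele frequencies with selection
#'
#' Each site evolves independently in a randomly mating diploid population
#' of constant size `N` (2N haploid copies). Per generation: (i) each U
#' copy becomes M with probability `mu_UM` and each M copy U with
#' probability `mu_MU`; (ii) the next generation is a binomial resample of
#' 2N copies with the U-copy sampling weight `1 + s` against 1 for M —
#' per-copy genic selection, which under random mating induces exactly the
#' diploid fitness scheme `1 + 2s` (U/U), `1 + s` (M/U), `1` (M/M).
#' After `burn_in` generations from a stationary-frequency start,
#' `n_sample` copies are drawn without replacement per site and the number
#' `b` carrying U is recorded.
#'
#' @param rates An [epimutation_rates()] object (per-copy per-generation).
#' @param N Diploid population size.
#' @param s Selection coefficient favouring U when positive.
#' @param n_sample Sampled copies per site (`<= 2N`).
#' @param n_sites Independent replicate sites.
#' @param burn_in Generations before sampling; default
#'   `ceiling(20 / (mu_UM + mu_MU + 1/(2N)))`, about twenty relaxation
#'   times of the combined epimutation-drift process.
#' @param init_freq_u Optional starting U-allele frequency (a single value
#'   in `[0, 1]`); by default sites start at a binomial draw around the
#'   stationary epimutation frequency.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `site` and `b` (sampled U-copy count),
#'   with the configuration in `attr(, "config")`.
#' @export
simulate_wright_fisher <- function(rates, N, s = 0, n_sample = 10,
                                   n_sites = 1000, burn_in = NULL,
                                   init_freq_u = NULL, seed = NULL) {
  stopifnot(inherits(rates, "epi_rates"), N >= 2,
            n_sample >= 1, n_sample <= 2 * N, n_sites >= 1)
  if (1 + s <= 0) abort("fitness 1 + s must be positive.")
  burn_in <- burn_in %||%
    ceiling(20 / (rates$mu_UM + rates$mu_MU + 1 / (2 * N)))
  local_seed(seed)
  two_n <- 2L * as.integer(N)
  # u = number of U copies per site
  u <- if (is.null(init_freq_u)) {
    rbinom(n_sites, two_n, 1 - stationary_methylated_fraction(rates))
  } else {
    stopifnot(init_freq_u >= 0, init_freq_u <= 1)
    rep(as.integer(round(init_freq_u * two_n)), n_sites)
  }
  for (g in seq_len(burn_in)) {
    # per-copy epimutation
    u <- rbinom(n_sites, u, 1 - rates$mu_UM) +
      rbinom(n_sites, two_n - u, rates$mu_MU)
    # selection-weighted resampling
    w <- u * (1 + s)
    u <- rbinom(n_sites, two_n, w / (w + (two_n - u)))
  }
  # sample n_sample copies without replacement: hypergeometric draw
  b <- stats::rhyper(n_sites, u, two_n - u, n_sample)
  out <- tibble::tibble(site = seq_len(n_sites), b = b)
  attr(out, "config") <- list(
    rates = rates, N = N, s = s, n_sample = n_sample,
    n_sites = n_sites, burn_in = burn_in, seed = seed
  )
  out
}

#' Draw an mSFS directly from the stationary sampling distribution
#'
#' Multinomial draw of segregating-site counts over the epiallelic classes
#' `1..n-1` with probabilities `q_{n,b}` from [conditional_msfs()]. This is
#' the fast generator for likelihood and recovery experiments.
#'
#' @param params A [pop_params()] object.
#' @param n Sample size.
#' @param n_sites Number of segregating sites to draw.
#' @param seed Optional RNG seed.
#' @return An [msfs()] object.
#' @export
simulate_msfs_counts <- function(params, n, n_sites, seed = NULL) {
  dist <- conditional_msfs(params, n)
  q <- dist$q[2:n]
  local_seed(seed)
  counts <- as.numeric(rmultinom(1, size = n_sites, prob = q))
  msfs(counts, n = n)
}

#' Simulate a full per-accession methylation call dataset
#'
#' End-to-end synthetic stand-in for a multi-accession WGBS panel: site
#' states for `n_accessions` are drawn from the stationary sampling
#' distribution (including monomorphic sites, at their model
#' probabilities), read coverage per site and accession follows a
#' negative-binomial model, methylated read counts are binomial around a
#' true level of `level_m` for M and `level_u` for U epialleles (a
#' bisulfite conversion-error proxy), and entries are made missing
#' (coverage 0) at rate `missing_rate`.
#'
#' @param params A [pop_params()] object.
#' @param n_accessions Sample size (default 92, a species-wide panel).
#' @param n_sites Total CG sites to simulate.
#' @param mean_coverage,coverage_dispersion Negative-binomial coverage
#'   model (mean 20x, size 5 by default).
#' @param missing_rate Fraction of entries with no coverage.
#' @param level_m,level_u True methylation levels of M and U epialleles.
#' @param seed Optional RNG seed.
#' @return A list of class `sim_call_data`: `calls` (named list of
#'   per-accession call tibbles, consumable by [binarize_calls()]),
#'   `truth` (the noiseless `meth_matrix`), and `config`.
#' @export
simulate_call_matrix <- function(params, n_accessions = 92,
                                 n_sites = 10000, mean_coverage = 20,
                                 coverage_dispersion = 5,
                                 missing_rate = 0.05, level_m = 0.95,
                                 level_u = 0.05, seed = NULL) {
  stopifnot(inherits(params, "pop_params"), n_accessions >= 2, n_sites >= 1)
  local_seed(seed)
  n <- n_accessions
  p <- sampling_probability(params, n)
  # per-site U-allele counts, monomorphic classes included
  b <- sample.int(n + 1L, n_sites, replace = TRUE, prob = p) - 1L
  # exchangeable accessions: random placement of the U states
  states <- matrix("M", n_sites, n)
  for (i in seq_len(n_sites)) {
    if (b[i] > 0) states[i, sample.int(n, b[i])] <- "U"
  }
  acc <- sprintf("acc%03d", seq_len(n))
  colnames(states) <- acc
  pos <- cumsum(rgeom(n_sites, 1 / 50) + 2L)
  sites <- tibble::tibble(
    chrom = "chr1", pos = as.integer(pos), strand = "both", context = "CG"
  )
  truth <- new_meth_matrix(dplyr::bind_cols(sites, tibble::as_tibble(states)),
                           acc)
  calls <- lapply(acc, function(a) {
    cov <- rnbinom(n_sites, mu = mean_coverage, size = coverage_dispersion)
    cov[runif(n_sites) < missing_rate] <- 0L
    true_level <- ifelse(states[, a] == "M", level_m, level_u)
    meth <- rbinom(n_sites, cov, true_level)
    dplyr::bind_cols(sites, tibble::tibble(
      meth_reads = as.integer(meth), total_reads = as.integer(cov),
      level = ifelse(cov > 0, meth / cov, NA_real_)
    ))
  })
  names(calls) <- acc
  structure(
    list(
      calls = calls, truth = truth,
      config = list(params = params, n_accessions = n_accessions,
                    n_sites = n_sites, mean_coverage = mean_coverage,
                    coverage_dispersion = coverage_dispersion,
                    missing_rate = missing_rate, level_m = level_m,
                    level_u = level_u, seed = seed)
    ),
    class = "sim_call_data"
  )
}
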