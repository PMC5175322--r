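PIPELINE_KEYS <- c("input", "binarize", "annotation", "msfs", "fit",
                   "simulate", "output_dir", "seed")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically read from YAML with
#' [read_pipeline_config()]) with sections `input` (named `files` list) or
#' `simulate` (arguments of [simulate_call_matrix()], with `alpha`, `r`,
#' `sigma` for the model), plus optional `binarize` (`min_coverage`,
#' `methylated_threshold`, `collapse_cg`), `annotation` (`path`,
#' `feature_type`), `msfs` (`policy`: `"intersection"` or `"projection"`;
#' `project_to`), `fit` (`enabled`, `sigma_free`, grid arguments for
#' [msfs_grid()]), and `output_dir`, `seed`. Unknown keys are rejected.
#'
#' @param config Named list.
#' @return The validated config, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$output_dir)) abort("config requires `output_dir`.")
  has_input <- !is.null(config$input$files)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    abort("config requires exactly one of `input$files` and `simulate`.")
  }
  if (has_input) {
    missing <- !file.exists(unlist(config$input$files))
    if (any(missing)) {
      abort(paste0("input file(s) not found: ",
                   paste(unlist(config$input$files)[missing],
                         collapse = ", ")))
    }
  }
  invisible(config)
}

#' @rdname validate_pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  validate_pipeline_config(yaml::read_yaml(path))
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full mSFS analysis pipeline
#'
#' Executes read (or simulate) -> strand-collapse -> binarize -> annotate
#' -> assemble -> GML -> mSFS -> model fit -> report, writing every
#' intermediate artifact to the output directory along with the effective
#' configuration and a machine-readable run report. Re-running with an
#' identical configuration and seed reproduces the outputs byte for byte.
#' A stage failure aborts with the failing stage named and leaves a
#' `FAILED` marker beside any partial outputs.
#'
#' @param config A config list or a YAML path (see
#'   [validate_pipeline_config()]).
#' @return A list of class `run_report`: per-stage provenance and the key
#'   outputs (GML table, mSFS, fit, report paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  stages <- list()
  bin <- config$binarize %||% list()
  min_cov <- bin$min_coverage %||% 3
  thr <- bin$methylated_threshold %||% 0.5
  collapse <- bin$collapse_cg %||% TRUE

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim <- run_stage("simulate", out_dir, {
      params <- pop_params(alpha = sim_cfg$alpha %||% 0.2,
                           r = sim_cfg$r %||% 3.43,
                           sigma = sim_cfg$sigma %||% 0)
      do.call(simulate_call_matrix, c(
        list(params = params, seed = config$seed),
        sim_cfg[setdiff(names(sim_cfg), c("alpha", "r", "sigma"))]
      ))
    })
    calls <- sim$calls
    stages$simulate <- list(config = sim_cfg, seed = config$seed,
                            n_accessions = length(calls))
  } else {
    files <- config$input$files
    if (is.null(names(files)) || any(names(files) == "")) {
      names(files) <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(unlist(files)))
    }
    calls <- run_stage("read", out_dir,
      purrr::map(files, read_cytosine_report,
                 permissive = config$input$permissive %||% FALSE)
    )
    stages$read <- list(files = files)
  }

  calls <- run_stage("binarize", out_dir, purrr::map(calls, function(df) {
    if (collapse) df <- collapse_cg_strands(df)
    binarize_calls(df, min_coverage = min_cov, methylated_threshold = thr)
  }))
  stages$binarize <- list(min_coverage = min_cov,
                          methylated_threshold = thr,
                          collapse_cg = collapse)

  policy <- config$msfs$policy %||% "intersection"
  mat <- run_stage("assemble", out_dir, assemble_call_matrix(
    calls, policy = if (policy == "projection") "union" else "intersection"
  ))

  if (!is.null(config$annotation$path)) {
    mat <- run_stage("annotate", out_dir, intersect_annotation(
      mat, config$annotation$path,
      feature_type = config$annotation$feature_type %||% "gene"
    ))
    stages$annotate <- config$annotation
  }
  matrix_path <- file.path(out_dir, "call_matrix.tsv")
  write_call_matrix(mat, matrix_path)
  stages$assemble <- list(policy = policy, n_sites = nrow(mat),
                          output = matrix_path)

  gml <- run_stage("gml", out_dir, compute_gml(mat))
  gml_path <- file.path(out_dir, "gml.tsv")
  readr::write_tsv(gml, gml_path)
  stages$gml <- list(output = gml_path)

  sfs <- run_stage("msfs", out_dir, {
    if (policy == "projection") {
      states <- meth_states(mat)
      k <- rowSums(!is.na(states))
      m <- config$msfs$project_to %||% min(k[k >= 2])
      project_msfs(mat[k >= m, , drop = FALSE], m = m)
    } else {
      build_msfs(mat)
    }
  })
  msfs_path <- file.path(out_dir, "msfs.tsv")
  write_msfs(sfs, msfs_path)
  stages$msfs <- list(policy = policy, output = msfs_path,
                      n = msfs_n(sfs),
                      n_segregating = sum(msfs_counts(sfs)))

  fit <- NULL
  fit_cfg <- config$fit %||% list()
  if (fit_cfg$enabled %||% TRUE) {
    fit <- run_stage("fit", out_dir, {
      grid_args <- fit_cfg[intersect(names(fit_cfg),
                                     names(formals(msfs_grid)))]
      fit_msfs(sfs, grid = do.call(msfs_grid, grid_args),
               sigma_free = fit_cfg$sigma_free %||% TRUE)
    })
    fit_path <- file.path(out_dir, "fit.json")
    jsonlite::write_json(
      list(
        best_params = unclass(fit$best_params),
        log_likelihood = fit$log_likelihood,
        neutral = list(params = unclass(fit$neutral$params),
                       log_likelihood = fit$neutral$log_likelihood),
        selected_model = fit$selected_model,
        delta_loglik = fit$delta_loglik,
        fitted_q = fit$fitted_q$q[2:fit$n]
      ),
      fit_path, auto_unbox = TRUE, digits = NA
    )
    report <- render_msfs_report(sfs, fit)
    report_path <- file.path(out_dir, "report.txt")
    writeLines(format(report), report_path)
    stages$fit <- list(output = fit_path, report = report_path,
                       selected_model = fit$selected_model)
  }

  yaml::write_yaml(config, file.path(out_dir, "config_effective.yaml"))
  report <- structure(
    list(stages = stages, config = config, seed = config$seed,
         version = as.character(packageVersion("epimsfs")),
         outputs = list(matrix = matrix_path, gml = gml_path,
                        msfs = msfs_path,
                        fit = stages$fit$output,
                        report = stages$fit$report),
         gml = gml, msfs = sfs, fit = fit),
    class = "run_report"
  )
  jsonlite::write_json(
    list(stages = stages, seed = config$seed, version = report$version),
    file.path(out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE
  )
  report
}

#' Tabulate an observed mSFS beside its model fit
#'
#' Builds the report table of observed class frequencies `d_b / sum(d)`
#' beside the fitted `q_{n,b}`, with the parameter estimates and the
#' neutral-versus-selection log-likelihood comparison.
#'
#' @param sfs The [msfs()] object the fit was computed on.
#' @param fit The corresponding [fit_msfs()] result.
#' @return An object of class `msfs_report` with elements `table` (tibble:
#'   `b`, `count`, `observed_freq`, `fitted_q`), `params`, `summary`;
#'   `format()` and `print()` render it as text.
#' @export
render_msfs_report <- function(sfs, fit) {
  stopifnot(inherits(fit, "msfs_fit"))
  n <- msfs_n(sfs)
  if (n != fit$n) {
    abort(sprintf("sample-size mismatch: mSFS has n = %d, fit has n = %d.",
                  n, fit$n))
  }
  counts <- msfs_counts(sfs)
  if (!isTRUE(all.equal(counts, msfs_counts(fit$msfs)))) {
    abort("the fit was not computed on this mSFS (counts differ).")
  }
  tab <- tibble::tibble(
    b = seq_len(n - 1L),
    count = counts,
    observed_freq = counts / sum(counts),
    fitted_q = fit$fitted_q$q[2:n]
  )
  structure(
    list(table = tab, params = fit$best_params, summary = glance(fit)),
    class = "msfs_report"
  )
}

#' @exportS3Method base::format
format.msfs_report <- function(x, ...) {
  p <- x$params
  s <- x$summary
  c(
    "Methylation site frequency spectrum: model fit",
    sprintf("  n = %d accessions, %s segregating sites",
            s$n, format(round(s$n_segregating, 2))),
    sprintf("  alpha = %.5g  beta = %.5g  r = %.5g  sigma = %.5g",
            p$alpha, p$beta, p$r, p$sigma),
    sprintf("  logLik = %.4f, selected model: %s (delta logLik = %s)",
            s$log_likelihood, s$selected_model,
            format(s$delta_loglik, digits = 4)),
    "",
    sprintf("  %3s %12s %14s %12s", "b", "count", "observed_freq",
            "fitted_q"),
    sprintf("  %3d %12s %14.6f %12.6f", x$table$b,
            format(round(x$table$count, 2), trim = TRUE),
            x$table$observed_freq, x$table$fitted_q)
  )
}

#' @export
print.msfs_report <- function(x, ...) {
  writeLines(format(x, ...))
  invisible(x)
}
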