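#' Configuration for a full pipeline run
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Root integer seed; every stochastic stage derives its own
#'   seed from it, so a run is fully reproducible.
#' @param samples Either a `diet_samples` object, a path to a long-format
#'   samples CSV, or `NULL` to run on generator output.
#' @param generator A [generator_config()] used when `samples` is `NULL`.
#' @param catalog A `taxon_catalog` or a path to a catalog CSV.
#' @param env Named list of [annual_series()], a path to an annual env CSV
#'   (columns `year` then one column per series), or `NULL` to generate.
#' @param otoliths Optional morphometrics input data frame or CSV path
#'   (`sample_id`, `species`, `otolith_mm`); `NULL` generates synthetic
#'   measurements, `FALSE` disables the morphometrics stage.
#' @param n_perm Permutations per annual comparison test.
#' @param alpha Significance level.
#' @param explanatory_window Admissible change-point window for
#'   explanatory series (default `c(1996, Inf)`: no shifts before 1997).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, samples = NULL,
                       generator = generator_config(), catalog = NULL,
                       env = NULL, otoliths = NULL, n_perm = 9999L,
                       alpha = 0.05, explanatory_window = c(1996, Inf)) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), samples = samples,
              generator = generator, catalog = catalog, env = env,
              otoliths = otoliths, n_perm = as.integer(n_perm),
              alpha = alpha, explanatory_window = explanatory_window)
  class(cfg) <- "run_config"
  cfg
}

pipeline_header <- function(seed) {
  sprintf("dietshift %s; seed=%d",
          as.character(utils::packageVersion("dietshift")), seed)
}

write_stage_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", pipeline_header(seed)), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full diet-indicator analysis pipeline
#'
#' Orchestrates every stage: load or generate samples; diet index table;
#' Arctic/Atlantic FO regime models; annual Arctic-vs-Atlantic permutation
#' comparisons; environmental correlations (raw and detrended);
#' Bray-Curtis/Ward/nMDS ordination of years with species scores; otolith
#' morphometrics. Writes one CSV per stage (plus a Newick dendrogram), a
#' MANIFEST of completed stages and a plain-text summary of headline
#' results. A stage failure aborts the run with the stage name; artifacts
#' of completed stages are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory results (`samples`,
#'   `indices`, `regimes`, `comparison`, `correlations`, `ordination`,
#'   `morphometrics`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- character(0)
  done <- function(stage, file) {
    manifest <<- c(manifest, paste0(stage, "\t", file))
    writeLines(c(paste0("# ", pipeline_header(seed)), manifest),
               file.path(config$out_dir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()

  catalog <- stage("catalog", {
    if (is.null(config$catalog)) default_catalog()
    else if (is.character(config$catalog)) read_catalog(config$catalog)
    else config$catalog
  })

  res$samples <- stage("load_samples", {
    if (is.null(config$samples)) {
      generate_samples(config$generator, seed = seed, catalog = catalog)
    } else if (is.character(config$samples)) {
      read_samples(config$samples, catalog = catalog)
    } else config$samples
  })
  samples_path <- file.path(config$out_dir, "samples.csv")
  write_samples(res$samples, samples_path, header = pipeline_header(seed))
  done("load_samples", "samples.csv")

  res$indices <- stage("indices", {
    rbind(index_table(res$samples, catalog = catalog),
          index_table(res$samples, by_year = TRUE, catalog = catalog))
  })
  write_stage_csv(res$indices, file.path(config$out_dir, "index_table.csv"),
                  seed)
  done("indices", "index_table.csv")

  res$env <- stage("load_env", {
    if (is.null(config$env) && is.null(config$samples)) {
      generate_env(config$generator, seed = seed)
    } else if (is.character(config$env)) {
      read_env_csv(config$env)
    } else config$env
  })

  res$regimes <- stage("regimes", {
    fits <- list(
      arctic = select_model(fo_series(res$samples, "arctic", catalog)),
      atlantic = select_model(fo_series(res$samples, "atlantic", catalog)))
    for (nm in names(res$env)) {
      fits[[nm]] <- select_model(res$env[[nm]],
                                 window = config$explanatory_window)
    }
    fits
  })
  regime_tab <- do.call(rbind, lapply(names(res$regimes), function(nm) {
    regime_report(res$regimes[[nm]], variable = nm)
  }))
  write_stage_csv(regime_tab, file.path(config$out_dir, "regimes.csv"), seed)
  done("regimes", "regimes.csv")

  res$comparison <- stage("comparison", {
    suppressWarnings(annual_group_comparison(
      res$samples, n_perm = config$n_perm, seed = seed + 100L,
      alpha = config$alpha, catalog = catalog))
  })
  write_stage_csv(res$comparison, file.path(config$out_dir, "comparison.csv"),
                  seed)
  done("comparison", "comparison.csv")

  if (!is.null(res$env)) {
    res$correlations <- stage("correlations", {
      diet <- list(
        fo_arctic = fo_series(res$samples, "arctic", catalog),
        fo_atlantic = fo_series(res$samples, "atlantic", catalog),
        fo_polar_cod = fo_series(res$samples, "polar_cod", catalog),
        ww_arctic = ww_series(res$samples, "arctic", catalog))
      correlation_table(diet, res$env[c("sea_ice_index", "temperature")])
    })
    write_stage_csv(res$correlations,
                    file.path(config$out_dir, "correlations.csv"), seed)
    done("correlations", "correlations.csv")
  }

  res$ordination <- stage("ordination", {
    pm <- presence_matrix(res$samples, level = "taxon", catalog = catalog)
    fo <- 100 * sweep(pm, 1L, attr(pm, "n_samples"), "/")
    fo <- fo[rowSums(fo) > 0, colSums(fo) > 0, drop = FALSE]
    d <- bray_curtis(fo)
    hc <- ward_cluster(d)
    ord <- nmds(d, k = 2L, seed = seed + 200L)
    sc <- suppressWarnings(species_scores(ord, fo))
    list(fo = fo, dissimilarity = d, dendrogram = hc, nmds = ord,
         species_scores = sc)
  })
  dm <- as.matrix(res$ordination$dissimilarity)
  write_stage_csv(data.frame(year = rownames(dm), dm, check.names = FALSE),
                  file.path(config$out_dir, "dissimilarity.csv"), seed)
  done("ordination", "dissimilarity.csv")
  write_dendrogram(res$ordination$dendrogram,
                   file.path(config$out_dir, "dendrogram.nwk"))
  done("ordination", "dendrogram.nwk")
  ordn <- res$ordination$nmds
  write_stage_csv(
    data.frame(year = rownames(ordn$points), ordn$points,
               stress = ordn$stress, check.names = FALSE),
    file.path(config$out_dir, "ordination.csv"), seed)
  done("ordination", "ordination.csv")
  write_stage_csv(
    data.frame(taxon = rownames(res$ordination$species_scores),
               res$ordination$species_scores, check.names = FALSE),
    file.path(config$out_dir, "species_scores.csv"), seed)
  done("ordination", "species_scores.csv")

  if (!isFALSE(config$otoliths)) {
    res$morphometrics <- stage("morphometrics", {
      meas <- if (is.null(config$otoliths)) {
        generate_otoliths(res$samples, seed = seed)
      } else if (is.character(config$otoliths)) {
        utils::read.csv(config$otoliths, stringsAsFactors = FALSE,
                        comment.char = "#")
      } else config$otoliths
      if (nrow(meas) > 0L) morphometrics_table(meas) else NULL
    })
    if (!is.null(res$morphometrics)) {
      write_stage_csv(res$morphometrics,
                      file.path(config$out_dir, "morphometrics.csv"), seed)
      done("morphometrics", "morphometrics.csv")
    } else {
      done("morphometrics", "(skipped: no otolith measurements)")
    }
  } else {
    done("morphometrics", "(skipped: disabled)")
  }

  summary_lines <- stage("summary", pipeline_summary(res, config))
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  done("summary", "summary.txt")

  res$manifest <- manifest
  invisible(res)
}

#' Read an annual environmental CSV
#'
#' Expects a `year` column plus one numeric column per series.
#'
#' @param path CSV path (lines starting with `#` skipped).
#' @return Named list of [annual_series()].
#' @export
read_env_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"year" %in% names(df)) stop("env CSV needs a year column")
  out <- list()
  for (nm in setdiff(names(df), "year")) {
    keep <- !is.na(df[[nm]])
    out[[nm]] <- annual_series(df$year[keep], df[[nm]][keep], name = nm)
  }
  out
}

pipeline_summary <- function(res, config) {
  lines <- c(pipeline_header(config$seed), "")
  lines <- c(lines, sprintf("Samples: %d over %d years (%d-%d)",
                            res$samples$n_samples, length(res$samples$years),
                            min(res$samples$years), max(res$samples$years)))
  for (nm in names(res$regimes)) {
    f <- res$regimes[[nm]]
    lines <- c(lines, if (form_has_changepoint(f$form)) {
      sprintf("Regime model [%s]: %s, change-point %d (regimes %d-%d / %d-%d)",
              nm, f$form, f$changepoint, min(f$years), f$changepoint,
              f$changepoint + 1L, max(f$years))
    } else {
      sprintf("Regime model [%s]: %s", nm, f$form)
    })
  }
  sig <- res$comparison[res$comparison$significant %in% TRUE, , drop = FALSE]
  lines <- c(lines, sprintf(
    "Years with significant Arctic-vs-Atlantic mass difference (alpha=%g): %s",
    config$alpha,
    if (nrow(sig) > 0L) paste0(sig$year, " (", sig$dominant, ")",
                               collapse = ", ") else "none"))
  if (!is.null(res$correlations)) {
    sigc <- res$correlations[res$correlations$significant, , drop = FALSE]
    lines <- c(lines, "Significant correlations:")
    lines <- c(lines, if (nrow(sigc) > 0L) {
      sprintf("  %s ~ %s%s: r = %.2f [%.2f, %.2f]", sigc$x, sigc$y,
              ifelse(sigc$detrended, " (detrended)", ""), sigc$r,
              sigc$ci_lo, sigc$ci_hi)
    } else "  none")
  }
  lines <- c(lines, sprintf("nMDS stress: %.4f",
                            res$ordination$nmds$stress))
  lines
}
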