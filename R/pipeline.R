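# End-to-end orchestration: run configuration, input validation, specimen
# measurement, and the comparative analysis pipeline.

#' Build a run configuration
#'
#' Collects the paths and switches of a pipeline run. The seed is mandatory
#' (auto-generated and reported if absent) and every output file records the
#' configuration hash so runs are traceable. Configurations can also be read
#' from / written to JSON.
#'
#' @param tree_file Newick tree path.
#' @param species_table path of the species-level CSV (column `species`,
#'   trait columns, `body_mass_kg`, optional `clade`).
#' @param specimen_table path of a specimen-level CSV (columns
#'   `specimen_id`, `species`, optionally `sex`) matching the landmark
#'   files.
#' @param landmark_dir directory with `<specimen_id>_spiral.csv` and
#'   optional `<specimen_id>_outline.csv` landmark files.
#' @param fossil_table path of a fossil CSV (columns `fossil`, `trait`,
#'   `value`, `body_mass_kg`).
#' @param out_dir output directory.
#' @param traits trait columns analysed in the comparative stages.
#' @param mass_column body-mass column name.
#' @param analyses character subset of `c("pca", "permutation", "signal",
#'   "allometry", "ancestral")`.
#' @param log_base log base for allometric fits (default 10).
#' @param lam_mode `"ML"` or fixed numeric lambda for PGLS/signal fits.
#' @param n_perm permutations for the pairwise tests.
#' @param chain [mcmc_config()] settings for the ancestral stage.
#' @param alpha_level significance level (default 0.05).
#' @param seed run seed; `NULL` draws one and reports it.
#' @return a `run_config` list.
#' @export
run_config <- function(tree_file = NULL, species_table = NULL,
                       specimen_table = NULL, landmark_dir = NULL,
                       fossil_table = NULL, out_dir = "cochlevol_out",
                       traits = c("RECL", "OWA"),
                       mass_column = "body_mass_kg",
                       analyses = c("pca", "permutation", "signal",
                                    "allometry", "ancestral"),
                       log_base = 10, lam_mode = "ML", n_perm = 10000L,
                       chain = mcmc_config(), alpha_level = 0.05,
                       seed = NULL) {
  if (is.null(seed)) {
    seed <- sample.int(1e6, 1L)
    message("no seed supplied; using seed = ", seed)
  }
  cfg <- list(tree_file = tree_file, species_table = species_table,
              specimen_table = specimen_table, landmark_dir = landmark_dir,
              fossil_table = fossil_table, out_dir = out_dir,
              traits = traits, mass_column = mass_column,
              analyses = analyses, log_base = log_base,
              lam_mode = lam_mode, n_perm = n_perm, chain = chain,
              alpha_level = alpha_level, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

# stable hash of the analytic configuration (md5 of its canonical JSON);
# the output directory does not change results and is excluded
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

.write_tsv <- function(df, file, config = NULL, units = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", .config_hash(config)), con)
  if (!is.null(units))
    writeLines(paste0("# units: ", paste(names(units), units, sep = "=",
                                         collapse = "; ")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Validate pipeline inputs without mutating them
#'
#' Checks tree/table alignment, positivity constraints and landmark file
#' shapes; collects all problems in a report instead of failing on the
#' first.
#'
#' @param config a [run_config()].
#' @return data frame with columns `input` and `problem` (zero rows = clean).
#' @export
validate_inputs <- function(config) {
  probs <- list()
  note <- function(input, problem)
    probs[[length(probs) + 1L]] <<- data.frame(input = input,
                                               problem = problem)
  tree <- NULL
  if (!is.null(config$tree_file)) {
    tree <- tryCatch(read_newick(config$tree_file), error = function(e) {
      note("tree", conditionMessage(e)); NULL
    })
  }
  if (!is.null(config$species_table)) {
    tab <- tryCatch(read.csv(config$species_table), error = function(e) {
      note("species_table", conditionMessage(e)); NULL
    })
    if (!is.null(tab)) {
      if (!"species" %in% names(tab))
        note("species_table", "missing 'species' column")
      if ("allometry" %in% config$analyses &&
          !config$mass_column %in% names(tab))
        note("species_table",
             sprintf("missing body-mass column '%s'", config$mass_column))
      else if (config$mass_column %in% names(tab) &&
               any(tab[[config$mass_column]] <= 0, na.rm = TRUE))
        note("species_table", "non-positive body mass")
      for (tr in intersect(config$traits, names(tab)))
        if (any(tab[[tr]] <= 0, na.rm = TRUE))
          note("species_table", sprintf("non-positive values in '%s'", tr))
      if (!is.null(tree) && "species" %in% names(tab)) {
        miss <- setdiff(tab$species, tree$tip.label)
        if (length(miss))
          note("species_table",
               sprintf("species absent from tree: %s",
                       paste(miss, collapse = ", ")))
      }
    }
  }
  if (!is.null(config$landmark_dir)) {
    files <- list.files(config$landmark_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (!length(files)) note("landmarks", "no CSV files in landmark_dir")
    for (f in files) {
      ok <- tryCatch({
        df <- read.csv(f, nrows = 5L)
        all(c("x", "y", "z") %in% names(df))
      }, error = function(e) FALSE)
      if (!isTRUE(ok))
        note("landmarks", sprintf("'%s' lacks x,y,z header", basename(f)))
    }
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(input = character(), problem = character())
}

#' Measure every specimen in a landmark directory
#'
#' Reads `<specimen_id>_spiral.csv` (and `<specimen_id>_outline.csv` when
#' present) for every specimen listed in the specimen table, runs
#' [measure_cochlea()], and writes a rounded TSV plus a full-precision twin,
#' followed by species means and combined-sex coefficients of variation.
#' Per-specimen failures are logged and do not abort the run.
#'
#' @param config a [run_config()] with `landmark_dir` and `specimen_table`
#'   set.
#' @return (invisibly) list with `measurements`, `species_summary`,
#'   `failures`.
#' @export
run_measure <- function(config) {
  spec <- read.csv(config$specimen_table)
  if (!all(c("specimen_id", "species") %in% names(spec)))
    .stop2("invalid_input",
           "specimen table needs 'specimen_id' and 'species' columns")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); failures <- list()
  for (i in seq_len(nrow(spec))) {
    id <- spec$specimen_id[i]
    sp_file <- file.path(config$landmark_dir, paste0(id, "_spiral.csv"))
    ow_file <- file.path(config$landmark_dir, paste0(id, "_outline.csv"))
    res <- tryCatch({
      spiral <- read_landmarks(sp_file, role = "spiral")
      outline <- if (file.exists(ow_file))
        read_landmarks(ow_file, role = "window") else NULL
      m <- measure_cochlea(spiral, outline)
      cbind(data.frame(specimen_id = id, species = spec$species[i],
                       stringsAsFactors = FALSE), as.data.frame(m))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(specimen_id = id, error = conditionMessage(res))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    .stop2("invalid_input", "no specimen could be measured")
  meas <- do.call(rbind, rows)
  fails <- if (length(failures)) do.call(rbind, failures)
    else data.frame(specimen_id = character(), error = character())
  if (nrow(fails))
    message(sprintf("%d specimen(s) failed: %s", nrow(fails),
                    paste(fails$specimen_id, collapse = ", ")))

  agg <- function(f) aggregate(meas[c("ECL", "TUR", "CUR", "RECL", "OWA")],
                               by = list(species = meas$species), FUN = f)
  means <- agg(function(x) mean(x, na.rm = TRUE))
  cvs <- agg(function(x) {
    x <- x[is.finite(x)]
    if (length(x) >= 2L && mean(x) != 0) sd(x) / mean(x) else NA_real_
  })
  names(cvs)[-1L] <- paste0("CV_", names(cvs)[-1L])
  species_summary <- merge(means, cvs, by = "species")

  units <- c(ECL = "mm", TUR = "turns", CUR = "ratio", RECL = "mm",
             OWA = "mm2")
  .write_tsv(cbind(meas[1:2], report_measurements(meas[-(1:2)])),
             file.path(config$out_dir, "measurements.tsv"), config, units)
  .write_tsv(meas, file.path(config$out_dir, "measurements_full.tsv"),
             config, units)
  .write_tsv(species_summary,
             file.path(config$out_dir, "species_summary.tsv"), config)
  if (nrow(fails))
    .write_tsv(fails, file.path(config$out_dir, "measure_failures.tsv"))
  invisible(list(measurements = meas, species_summary = species_summary,
                 failures = fails))
}

#' Run the comparative pipeline
#'
#' Executes, on a species table aligned to a tree, the stages enabled in
#' the configuration, in analysis order: PCA, pairwise permutation matrix,
#' phylogenetic-signal tests per trait, OLS/RMA/PGLS allometry with AIC
#' ranking and residual flags, MCMC ancestral states, and fossil Z-scores
#' with allometric expected values. Stage failures are isolated: later
#' independent stages still run and the returned object records each
#' stage's error, with the overall `status` reflecting any failure. One
#' TSV per stage plus a JSON run log are written to `out_dir`.
#'
#' @param config a [run_config()].
#' @param specimens optional specimen-level data frame (columns `species`
#'   and the configured traits) used for PCA and the permutation matrix;
#'   defaults to the species table itself.
#' @return (invisibly) a list of per-stage results, `errors`, and `status`
#'   (0 = all stages succeeded).
#' @export
run_comparative <- function(config, specimens = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- read_newick(config$tree_file)
  tab <- read.csv(config$species_table)
  ali <- align_table_to_tree(tab, tree)
  tree <- ali$tree; tab <- ali$table
  if (is.null(specimens)) specimens <- tab
  results <- list(); errors <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      errors[[name]] <<- conditionMessage(out)
      message(sprintf("stage '%s' failed: %s", name, errors[[name]]))
      NULL
    } else out
  }
  traits <- intersect(config$traits, names(tab))
  lb <- config$log_base

  if ("pca" %in% config$analyses)
    results$pca <- stage("pca", {
      cols <- intersect(c("ECL", "TUR", "CUR", "RECL", "OWA",
                          config$traits), names(specimens))
      M <- specimens[cols]
      M <- M[complete.cases(M), , drop = FALSE]
      p <- pca(M)
      .write_tsv(data.frame(component = seq_along(p$percent_variance),
                            percent_variance = p$percent_variance),
                 file.path(config$out_dir, "pca_variance.tsv"), config)
      .write_tsv(as.data.frame(p$factor_map),
                 file.path(config$out_dir, "pca_factor_map.tsv"), config)
      p
    })

  if ("permutation" %in% config$analyses && length(traits) >= 2L)
    results$permutation <- stage("permutation", {
      pm <- pairwise_permutation_matrix(specimens, "species", traits[1L],
                                        traits[2L], n_perm = config$n_perm,
                                        seed = config$seed)
      .write_tsv(as.data.frame(pm$p_matrix),
                 file.path(config$out_dir, "permutation_matrix.tsv"),
                 config)
      pm
    })

  if ("signal" %in% config$analyses)
    results$signal <- stage("signal", {
      rows <- lapply(traits, function(tr) {
        st <- lambda_signal_test(setNames(tab[[tr]], tab$species), tree)
        data.frame(trait = tr, lambda_ml = st$lambda_ml,
                   loglik_ml = st$loglik_ml,
                   loglik_lambda0 = st$loglik_lambda0,
                   loglik_lambda1 = st$loglik_lambda1,
                   p_vs_0 = st$p_vs_0, p_vs_1 = st$p_vs_1,
                   degenerate = st$degenerate)
      })
      out <- do.call(rbind, rows)
      .write_tsv(out, file.path(config$out_dir, "signal_tests.tsv"),
                 config)
      out
    })

  if ("allometry" %in% config$analyses)
    results$allometry <- stage("allometry", {
      if (!config$mass_column %in% names(tab))
        .stop2("invalid_input", "missing body-mass column '%s'",
               config$mass_column)
      lmass <- log(tab[[config$mass_column]], base = lb)
      fits <- list(); resid_rows <- list(); fit_rows <- list()
      for (tr in traits) {
        ly <- log(tab[[tr]], base = lb)
        f_ols <- ols_fit(ly, cbind(log_mass = lmass), response = tr,
                         species = tab$species, log_base = lb)
        f_rma <- rma_fit(ly, lmass, response = tr, species = tab$species,
                         log_base = lb)
        f_pgls <- pgls_fit(setNames(ly, tab$species),
                           cbind(log_mass = lmass), tree,
                           lam_mode = config$lam_mode, response = tr,
                           log_base = lb)
        fits[[tr]] <- list(OLS = f_ols, RMA = f_rma, PGLS = f_pgls,
                           ranked = model_select_aic(list(f_ols, f_pgls)))
        for (f in list(f_ols, f_rma, f_pgls))
          fit_rows[[length(fit_rows) + 1L]] <- data.frame(
            response = tr, method = f$method,
            intercept = f$coefficients[[1L]],
            slope = f$coefficients[[2L]],
            lambda = f$lambda, r_squared = f$r_squared, aic = f$aic,
            log_base = lb)
        sr <- standardized_residuals(f_pgls)
        sr$response <- tr; sr$method <- "PGLS"
        resid_rows[[length(resid_rows) + 1L]] <- sr
      }
      .write_tsv(do.call(rbind, fit_rows),
                 file.path(config$out_dir, "allometry_fits.tsv"), config)
      .write_tsv(do.call(rbind, resid_rows),
                 file.path(config$out_dir, "allometry_residuals.tsv"),
                 config)
      fits
    })

  if ("ancestral" %in% config$analyses)
    results$ancestral <- stage("ancestral", {
      chain <- config$chain
      chain$seed <- config$seed
      post <- lapply(traits, function(tr)
        mcmc_ancestral(setNames(log(tab[[tr]], base = lb), tab$species),
                       tree, config = chain))
      names(post) <- traits
      summ <- do.call(rbind, lapply(traits, function(tr)
        cbind(trait = tr, post[[tr]]$summary)))
      .write_tsv(summ, file.path(config$out_dir, "ancestral_states.tsv"),
                 config)
      fz <- NULL
      if (!is.null(config$fossil_table)) {
        fos <- read.csv(config$fossil_table)
        fz_rows <- list()
        for (i in seq_len(nrow(fos))) {
          tr <- fos$trait[i]
          if (!tr %in% traits) next
          p <- post[[tr]]
          for (j in seq_len(nrow(p$summary)))
            fz_rows[[length(fz_rows) + 1L]] <-
              zscore_fossil(log(fos$value[i], base = lb), p,
                            node = p$summary$node[j],
                            fossil = fos$fossil[i], trait = tr)
        }
        if (length(fz_rows)) {
          fz <- do.call(rbind, fz_rows)
          .write_tsv(fz, file.path(config$out_dir, "fossil_zscores.tsv"),
                     config)
        }
      }
      list(posteriors = post, summary = summ, fossil_zscores = fz)
    })

  log_file <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(list(config = unclass(config),
                            config_hash = .config_hash(config),
                            stages_run = names(results),
                            errors = errors,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       log_file, auto_unbox = TRUE, null = "null",
                       force = TRUE)
  invisible(list(results = results, errors = errors,
                 status = if (length(errors)) 1L else 0L))
}
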