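## CSV dialects ---------------------------------------------------------------

trait_units <- c(oil = "pct", protein = "pct", glucosinolate = "umol_g",
                 phytic_acid = "pct", palmitic = "pct", stearic = "pct",
                 oleic = "pct", linoleic = "pct", linolenic = "pct",
                 eicosenoic = "pct", erucic = "pct")

#' Spectra and reference CSV input/output
#'
#' Spectra CSV: one row per sample; first column `sample_id`, remaining
#' headers the wavenumbers as decimal cm^-1, strictly increasing.
#' Reference CSV: `sample_id` plus one column per trait with a unit
#' suffix (`oil_pct`, `glucosinolate_umol_g`, ...). Writing then reading
#' restores every numeric payload to within 1e-12.
#'
#' @param spectra A [spectra_set()].
#' @param reference A reference data.frame.
#' @param path File path.
#' @name study_csv
NULL

#' @rdname study_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(sample_id = spectra$sample_ids, spectra$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", format(as.numeric(unclass(spectra$grid)),
                                     trim = TRUE, digits = 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty spectra file")
  if (names(df)[1] != "sample_id")
    stop("first spectra column must be 'sample_id'")
  wn <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wn))
    stop(sprintf("non-numeric wavenumber header(s): %s",
                 paste(names(df)[-1][is.na(wn)][1:3], collapse = ", ")))
  if (any(diff(wn) <= 0))
    stop("wavenumber columns must be strictly increasing")
  spectra_set(as.matrix(df[, -1, drop = FALSE]),
              wavenumber_grid(values = wn),
              sample_ids = df$sample_id)
}

#' @rdname study_csv
#' @export
write_reference_csv <- function(reference, path) {
  traits <- reference_traits(reference)
  out <- reference
  suff <- ifelse(traits %in% names(trait_units), trait_units[traits], "value")
  names(out) <- c("sample_id", paste(traits, suff, sep = "_"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty reference file")
  if (names(df)[1] != "sample_id")
    stop("first reference column must be 'sample_id'")
  nm <- names(df)[-1]
  strip <- sub("_(pct|umol_g|value)$", "", nm)
  names(df) <- c("sample_id", strip)
  num <- vapply(df[-1], is.numeric, logical(1))
  if (!all(num))
    stop(sprintf("non-numeric trait column(s): %s",
                 paste(strip[!num], collapse = ", ")))
  df
}

#' Persist a fitted calibration model as JSON
#'
#' Stores every array of a `"pls_model"` (means, weights, loadings,
#' nested coefficients, scores, fitted values) together with its metadata
#' at full numeric precision, so a model survives a round trip through
#' disk bit-faithfully for prediction purposes.
#'
#' @param model A `"pls_model"`.
#' @param path Destination file (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  payload <- unclass(model)
  payload$.class <- "pls_model"
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$.class) || raw$.class != "pls_model")
    stop("file does not contain a serialized pls_model")
  raw$.class <- NULL
  for (nm in c("weights", "x_loadings", "scores", "coefficients"))
    raw[[nm]] <- as.matrix(raw[[nm]])
  structure(raw, class = "pls_model")
}

## Study configuration --------------------------------------------------------

#' Default end-to-end study configuration
#'
#' One nested list drives [run_study()]: the `simulate` block (sample
#' count, outlier fraction, moisture boost, water level), the `screen`
#' block (trait used for the chemical screen, score dimension, H and
#' residual thresholds), and the `calibrate` block (calibration fraction,
#' CV folds, maximum component count). All randomness derives from the
#' single `seed` through per-stage substreams, so changing one stage's
#' settings does not perturb another stage's draws.
#'
#' @param seed Master integer seed.
#' @param n Sample count.
#' @param traits Traits to calibrate (default: all eleven).
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(seed = 1, n = 100,
                         traits = default_trait_params()$trait) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_samples = n, outlier_fraction = 0.2, moisture_boost = 0.3,
                    water_level = 1, water_level_sd = 0.05),
    screen = list(trait = "oil", n_components = 5, h_max = 6, resid_sd = 3),
    calibrate = list(traits = traits, cal_fraction = 0.8, folds = NULL,
                     max_k = 12),
    pca = list(k = 3)
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Values present in the file override the [study_config()] defaults;
#' everything else is inherited. The file mirrors the config structure
#' (`seed:`, `simulate:`, `screen:`, `calibrate:`, `pca:` blocks).
#'
#' @param path YAML file path.
#' @return A `"study_config"`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- study_config(seed = if (!is.null(raw$seed)) raw$seed else 1)
  for (block in c("simulate", "screen", "calibrate", "pca")) {
    if (!is.null(raw[[block]]))
      cfg[[block]][names(raw[[block]])] <- raw[[block]]
  }
  if (is.null(raw$seed) && is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

## End-to-end study -----------------------------------------------------------

#' Run the full seed-quality calibration study
#'
#' The complete workflow on one synthetic panel: simulate spectra and
#' reference values with contaminant outliers; screen outliers in two
#' stages (Mahalanobis H on SNV-treated spectra, then calibration
#' y-residuals); preprocess the retained spectra per trait; split into
#' calibration/validation sets; choose the component count by k-fold
#' cross-validation and fit a NIPALS PLS model per trait; and compute the
#' evaluation statistics, spectra PCA, trait Pearson correlations and the
#' RCBD variability report. Identical configs give bit-identical results.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, every artifact is
#'   written there as CSV/JSON (spectra, reference, truth, outlier
#'   report, calibration reports, PCA scores/loadings/variance,
#'   correlation matrix, variability report, run manifest).
#' @return A list: `study`, `outlier_report`, `retained_ids`, `reports`
#'   (per-trait [build_report()] lists), `selections`, `pca`,
#'   `correlation`, `variability`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  if (is.null(config$seed)) stop("config must set a seed")
  set.seed(config$seed)
  sub <- sample.int(2^31 - 2, 4)
  sim <- config$simulate

  study <- simulate_study(
    n = sim$n_samples, seed = sub[1],
    scatter = scatter_params(),
    outlier_fraction = sim$outlier_fraction,
    moisture_boost = sim$moisture_boost,
    water_level = sim$water_level, water_level_sd = sim$water_level_sd)

  scr <- config$screen
  snv_spectra <- apply_pipeline(study$spectra, list(step_snv()))
  y_screen <- study$reference[[scr$trait]]
  report_out <- screen_outliers(snv_spectra, y_screen,
                                n_components = scr$n_components,
                                h_max = scr$h_max, resid_sd = scr$resid_sd)
  retained <- report_out$sample_id[!report_out$flagged]
  keep <- match(retained, study$spectra$sample_ids)

  spectra_kept <- study$spectra[keep]
  reference_kept <- study$reference[keep, , drop = FALSE]

  cal_cfg <- config$calibrate
  n_keep <- length(keep)
  set.seed(sub[2])
  cal_idx <- sort(sample.int(n_keep, round(cal_cfg$cal_fraction * n_keep)))
  val_idx <- setdiff(seq_len(n_keep), cal_idx)

  reports <- list()
  selections <- list()
  for (tr in cal_cfg$traits) {
    pre <- apply_pipeline(spectra_kept, default_preprocess(tr))
    y <- reference_kept[[tr]]
    cal_x <- pre[cal_idx]; val_x <- pre[val_idx]
    sel <- select_components(cal_x, y[cal_idx], max_k = cal_cfg$max_k,
                             folds = cal_cfg$folds, seed = sub[3])
    fit <- fit_pls(cal_x, y[cal_idx], ncomp = sel$chosen_k)
    reports[[tr]] <- build_report(fit, cal_x, y[cal_idx], val_x, y[val_idx],
                                  selection = sel, trait_name = tr)
    selections[[tr]] <- sel
  }

  pre_pca <- apply_pipeline(spectra_kept, list(step_snv()))
  pca_out <- pca(pre_pca, k = config$pca$k)
  corr <- pearson_matrix(reference_kept)
  rcbd <- rcbd_from_reference(reference_kept, seed = sub[4])
  variability <- variability_report(rcbd)

  result <- list(study = study, outlier_report = report_out,
                 retained_ids = retained, cal_ids = retained[cal_idx],
                 val_ids = retained[val_idx], reports = reports,
                 selections = selections, pca = pca_out,
                 correlation = corr, variability = variability,
                 config = config)
  if (!is.null(out_dir)) write_study_bundle(result, out_dir)
  result
}

report_row <- function(rep) {
  data.frame(trait = rep$trait_name, n_cal = rep$n_cal, n_val = rep$n_val,
             ncomp = rep$ncomp, r2_cal = rep$r2_cal, r2_val = rep$r2_val,
             rmsec = rep$rmsec, rmsep = rep$rmsep, mae_cal = rep$mae_cal,
             mae_val = rep$mae_val, bias = rep$bias, sec = rep$sec,
             secv = rep$secv, sep = rep$sep, rpd_cal = rep$rpd_cal,
             rpd_val = rep$rpd_val, stringsAsFactors = FALSE)
}

#' Write every artifact of a study run to a directory
#'
#' @param result A [run_study()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_spectra_csv(result$study$spectra, fp("spectra.csv"))
  write_reference_csv(result$study$reference, fp("reference.csv"))
  utils::write.csv(result$study$outlier_truth, fp("outlier_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(result$outlier_report, fp("outlier_report.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(result$reports, report_row)),
                   fp("calibration_reports.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(result$reports, unclass),
                       fp("calibration_reports.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(data.frame(component = seq_along(result$pca$explained_variance_pct),
                              explained_pct = result$pca$explained_variance_pct,
                              cumulative_pct = result$pca$cumulative_pct),
                   fp("pca_variance.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = result$retained_ids,
                              result$pca$scores),
                   fp("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$pca$loadings), fp("pca_loadings.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$correlation), fp("correlation.csv"),
                   row.names = TRUE)
  utils::write.csv(result$variability, fp("variability.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "nirseed",
    version = as.character(utils::packageVersion("nirseed")),
    r_version = as.character(getRversion()),
    seed = result$config$seed,
    config = unclass(result$config),
    n_samples = nrow(result$study$reference),
    n_retained = length(result$retained_ids)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
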