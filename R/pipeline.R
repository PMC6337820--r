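#' Analysis configuration for the full modelling pipeline
#'
#' Bundles every knob of the analysis grid: which imputation strategies and
#' longitudinal mean structures to run, the hazard covariates, and the
#' clinical thresholds used to dichotomize the raw biomarker snapshots
#' (month-3 value elevated above 100, month-12 value elevated above 64,
#' both in nmol BCE/mmol creatinine).
#'
#' @param imputations subset of `c("omit", "locf", "ocs")`.
#' @param bases subset of `c("rational", "exponential", "spline")`.
#' @param covariates baseline covariates entering every survival model.
#' @param ntx3_cut,ntx12_cut raw-scale thresholds for the month-3 and
#'   month-12 snapshot indicators.
#' @param clusters,fuzzifier fuzzy-clustering settings for the OCS
#'   imputation.
#' @param knots,boundary natural-cubic-spline settings (months).
#' @param n_pieces baseline-hazard intervals of the joint models.
#' @param schedule measurement schedule (months); `NULL` infers it from the
#'   longitudinal table.
#' @param seed integer seed echoed into the provenance record.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(imputations = c("omit", "locf", "ocs"),
                            bases = c("rational", "exponential", "spline"),
                            covariates = c("age", "sex", "extra_mets"),
                            ntx3_cut = 100, ntx12_cut = 64,
                            clusters = 6L, fuzzifier = 1.3,
                            knots = c(1, 6), boundary = c(0, 12),
                            n_pieces = 6L, schedule = NULL, seed = 1L) {
  imputations <- match.arg(imputations, c("omit", "locf", "ocs"),
                           several.ok = TRUE)
  bases <- match.arg(bases, c("rational", "exponential", "spline"),
                     several.ok = TRUE)
  if (ntx3_cut <= 0 || ntx12_cut <= 0) stop("thresholds must be positive")
  structure(list(imputations = imputations, bases = bases,
                 covariates = covariates, ntx3_cut = ntx3_cut,
                 ntx12_cut = ntx12_cut, clusters = as.integer(clusters),
                 fuzzifier = fuzzifier, knots = knots, boundary = boundary,
                 n_pieces = as.integer(n_pieces), schedule = schedule,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

## month-3 / month-12 biomarker snapshots, raw and log scale, plus the
## clinical elevation indicators (complete cases per feature)
snapshot_features <- function(baseline, longitudinal, config) {
  grab <- function(month) {
    rows <- longitudinal[abs(longitudinal$t - month) < 1e-9, c("id", "y")]
    rows[match(baseline$id, rows$id), "y"]
  }
  y3 <- grab(3); y12 <- grab(12)
  data.frame(id = baseline$id,
             ntx3 = exp(y3), log_ntx3 = y3,
             ntx3_high = as.integer(exp(y3) > config$ntx3_cut),
             ntx12 = exp(y12), log_ntx12 = y12,
             ntx12_high = as.integer(exp(y12) > config$ntx12_cut))
}

screen_one <- function(baseline, values, type) {
  ok <- !is.na(values)
  d <- baseline[ok, , drop = FALSE]
  v <- values[ok]
  if (length(unique(v)) < 2L) return(NULL)
  if (type == "categorical") {
    lr <- logrank_test(d, v)
    data.frame(test = "logrank", n = nrow(d), p = lr$p_value)
  } else {
    d$feature <- v
    cf <- fit_cox(d, "feature")
    data.frame(test = "wald", n = nrow(d), p = unname(cf$wald_p["feature"]))
  }
}

#' Univariate survival screen
#'
#' Log-rank tests for categorical features and univariate Cox Wald tests
#' for continuous features, over the baseline covariates and the biomarker
#' snapshot features (month-3 / month-12 values, their logs and the
#' clinical elevation indicators), each on its per-feature complete cases.
#'
#' @param data list with `baseline` and `longitudinal`.
#' @param config an [analysis_config()].
#' @return data frame with columns `feature`, `test`, `n`, `p`.
#' @export
run_univariate_screen <- function(data, config = analysis_config()) {
  baseline <- data$baseline
  snap <- snapshot_features(baseline, data$longitudinal, config)
  feats <- list(
    age = list(baseline$age, "continuous"),
    sex = list(baseline$sex, "categorical"),
    extra_mets = list(baseline$extra_mets, "categorical"),
    ntx3 = list(snap$ntx3, "continuous"),
    log_ntx3 = list(snap$log_ntx3, "continuous"),
    ntx3_high = list(snap$ntx3_high, "categorical"),
    ntx12 = list(snap$ntx12, "continuous"),
    log_ntx12 = list(snap$log_ntx12, "continuous"),
    ntx12_high = list(snap$ntx12_high, "categorical"))
  out <- list()
  for (nm in names(feats)) {
    row <- tryCatch(screen_one(baseline, feats[[nm]][[1]], feats[[nm]][[2]]),
                    error = function(e) NULL)
    if (is.null(row)) {
      message("feature '", nm, "' skipped (single level or test failure)")
      next
    }
    out[[nm]] <- cbind(feature = nm, row)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

impute_longitudinal <- function(data, method, config, schedule) {
  long <- data$longitudinal
  if (method == "omit") return(long)
  M <- long_to_trajectory(long, schedule)
  M2 <- switch(method,
               locf = locf_impute(M),
               ocs = ocs_impute(M, c = min(config$clusters, nrow(M$values)),
                                m_fuzz = config$fuzzifier,
                                seed = config$seed)$matrix)
  out <- trajectory_to_long(M2)
  ## imputed values past a patient's observed time are never used
  tmax <- data$baseline$time_obs[match(out$id, data$baseline$id)]
  out <- out[out$t < tmax, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full imputation-by-model analysis grid
#'
#' Orchestrates the complete analysis: the univariate screen, one
#' multivariate Cox model per biomarker snapshot variant, and then, for
#' each imputation strategy, an extended Cox model with the step-function
#' log-biomarker and one joint model per longitudinal mean structure
#' (tuning parameters of the parametric structures profiled per imputed
#' dataset).  With the default three imputations and three mean structures
#' this yields nine joint models and three extended Cox fits.  Failures are
#' isolated per grid cell.
#'
#' @param data list with `baseline` and `longitudinal` (log-scale `y`).
#' @param config an [analysis_config()].
#' @return an object of class `result_bundle`: `univariate`,
#'   `multivariate` (one Cox table per snapshot variant), `extended_cox`
#'   (per imputation), `jm` (fits, indexed imputation-major), `jm_table`
#'   (coefficient summary), `errors` and `provenance`.
#' @export
run_analysis_grid <- function(data, config = analysis_config()) {
  set.seed(config$seed)
  baseline <- data$baseline
  schedule <- config$schedule
  if (is.null(schedule)) schedule <- sort(unique(data$longitudinal$t))
  covs <- config$covariates
  univ <- tryCatch(run_univariate_screen(data, config),
                   error = function(e) NULL)
  ## multivariate Cox per snapshot variant (complete cases per variant)
  snap <- snapshot_features(baseline, data$longitudinal, config)
  multiv <- list()
  for (nm in c("ntx3", "log_ntx3", "ntx3_high",
               "ntx12", "log_ntx12", "ntx12_high")) {
    d <- cbind(baseline, feature = snap[[nm]])
    d <- d[!is.na(d$feature), , drop = FALSE]
    multiv[[nm]] <- tryCatch({
      cf <- fit_cox(d, c(covs, "feature"))
      list(fit = cf, n = nrow(d), n_events = sum(d$status))
    }, error = function(e) list(error = conditionMessage(e)))
  }
  errors <- list()
  ext <- list()
  jms <- list()
  jm_rows <- list()
  model_idx <- 0L
  for (imp in config$imputations) {
    long_imp <- tryCatch(impute_longitudinal(data, imp, config, schedule),
                         error = function(e) NULL)
    if (is.null(long_imp)) {
      errors[[paste0("impute_", imp)]] <- "imputation failed"
      next
    }
    ext[[imp]] <- tryCatch({
      cp <- to_counting_process(baseline, long_imp, value_name = "log_ntx")
      cf <- fit_extended_cox(cp, c(covs, "log_ntx"))
      list(fit = cf, n = length(unique(cp$id)), n_events = sum(cp$status))
    }, error = function(e) {
      errors[[paste0("extcox_", imp)]] <<- conditionMessage(e)
      NULL
    })
    for (bk in config$bases) {
      model_idx <- model_idx + 1L
      cell <- paste0(imp, "_", bk)
      jms[[cell]] <- tryCatch({
        basis <- if (bk == "spline") {
          basis_spec("spline", knots = config$knots,
                     boundary = config$boundary)
        } else {
          profile_tuning(long_imp, bk)$spec
        }
        jspec <- joint_model_spec(basis, n_pieces = config$n_pieces)
        fit <- fit_joint_model(list(baseline = baseline,
                                    longitudinal = long_imp),
                               jspec, covariates = covs)
        jm_rows[[cell]] <- data.frame(
          model = model_idx, imputation = imp, basis = bk,
          parameter = c(covs, "log_ntx"),
          estimate = c(unname(fit$gamma), fit$alpha),
          p = unname(fit$wald_p[c(covs, "alpha")]),
          n = fit$n_patients, n_events = fit$n_events)
        fit
      }, error = function(e) {
        errors[[paste0("jm_", cell)]] <<- conditionMessage(e)
        NULL
      })
    }
  }
  jm_table <- do.call(rbind, jm_rows)
  if (!is.null(jm_table)) rownames(jm_table) <- NULL
  structure(list(univariate = univ, multivariate = multiv,
                 extended_cox = ext, jm = jms, jm_table = jm_table,
                 errors = errors,
                 provenance = list(
                   config = config, hash = config_hash(config),
                   seed = config$seed,
                   n_patients = nrow(baseline),
                   n_events = sum(baseline$status),
                   package_version =
                     as.character(utils::packageVersion("bonejm")))),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>",
      length(Filter(Negate(is.null), x$jm)), "joint models,",
      length(Filter(Negate(is.null), x$extended_cox)),
      "extended Cox fits\n")
  if (length(x$errors))
    cat("  failed cells:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write a result bundle to disk
#'
#' One CSV per summary table plus a consolidated JSON bundle.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(bundle$univariate))
    utils::write.csv(bundle$univariate, file.path(dir, "univariate.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$jm_table))
    utils::write.csv(bundle$jm_table, file.path(dir, "jm_table.csv"),
                     row.names = FALSE)
  ext_rows <- do.call(rbind, lapply(names(bundle$extended_cox), function(im) {
    e <- bundle$extended_cox[[im]]
    if (is.null(e)) return(NULL)
    data.frame(imputation = im, parameter = names(e$fit$gamma),
               estimate = unname(e$fit$gamma), se = unname(e$fit$se),
               p = unname(e$fit$wald_p), n = e$n, n_events = e$n_events)
  }))
  if (!is.null(ext_rows))
    utils::write.csv(ext_rows, file.path(dir, "extended_cox.csv"),
                     row.names = FALSE)
  summ <- list(
    provenance = bundle$provenance[c("hash", "seed", "n_patients",
                                     "n_events", "package_version")],
    errors = bundle$errors,
    jm = lapply(bundle$jm, function(f) if (is.null(f)) NULL else
      list(basis = f$spec$basis$kind, loglik = f$loglik,
           alpha = f$alpha, alpha_p = unname(f$wald_p["alpha"]),
           gamma = as.list(f$gamma), converged = f$converged)))
  jsonlite::write_json(summ, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
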