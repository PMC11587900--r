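#' Build (and validate) a pipeline configuration
#'
#' Assembles the configuration driving [run_full_analysis()].  Model I is
#' the demographic adjustment (age, gender, race); Model II adds
#' socioeconomic and clinical covariates (education, PIR, diabetes,
#' dyslipidemia, WBC, energy) and must contain Model I.
#'
#' @param synthetic named list of [truth_params()] arguments, or `NULL`
#'   to read `input` instead.
#' @param input path to a cohort CSV (ignored when `synthetic` is given).
#' @param registry path to a YAML component registry, or `NULL` for the
#'   default [obs_registry()].
#' @param model1_covariates,model2_covariates covariate sets.
#' @param mediator list: `variable` (continuous mediator column),
#'   `n_knots`, `policy` (see [choose_cutoff()]).
#' @param subgroups subgroup columns for the mediation analysis.
#' @param imputation list: `enabled`, `m`.
#' @param exclusion_order order in which exclusion criteria are applied.
#' @param dop_draws Monte Carlo draws for the distribution-of-product CI.
#' @param obs_cutoff fixed OBS dichotomization cutoff, or `NULL` to
#'   recompute the first tertile from the analytic sample.
#' @param single_psu passed to all fits.
#' @param seed master seed for the whole run.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = list(),
                            input = NULL,
                            registry = NULL,
                            model1_covariates = c("age", "gender", "race"),
                            model2_covariates = c("age", "gender", "race",
                                                  "education", "pir_group",
                                                  "diabetes", "dyslipidemia",
                                                  "wbc", "energy"),
                            mediator = list(variable = "mma", n_knots = 4,
                                            policy = "nearest_quantile_median"),
                            subgroups = c("diabetes", "dyslipidemia"),
                            imputation = list(enabled = FALSE, m = 5),
                            exclusion_order = c("mma", "cvd", "obs"),
                            dop_draws = 1e6,
                            obs_cutoff = NULL,
                            single_psu = "fail",
                            seed = 1L) {
  cfg <- list(synthetic = synthetic, input = input, registry = registry,
              model1_covariates = model1_covariates,
              model2_covariates = model2_covariates,
              mediator = mediator, subgroups = subgroups,
              imputation = imputation, exclusion_order = exclusion_order,
              dop_draws = dop_draws, obs_cutoff = obs_cutoff,
              single_psu = single_psu, seed = as.integer(seed))
  if (!all(cfg$model1_covariates %in% cfg$model2_covariates))
    stop("Model I covariates must be a subset of Model II covariates",
         call. = FALSE)
  if (isTRUE(cfg$imputation$enabled) && cfg$imputation$m < 1)
    stop("imputation m must be >= 1", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()] (a `synthetic:` block mirrors [truth_params()]
#'   field-for-field).
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Apply the analytic exclusion criteria
#'
#' Drops rows missing the mediator (MMA), the outcome (CVD), or any OBS
#' component, in a fixed order, and records how many rows each criterion
#' removed.  A row failing several criteria is counted once, under the
#' first criterion in the order.
#'
#' @param cohort data frame.
#' @param registry component registry (for the OBS criterion).
#' @param order permutation of `c("mma", "cvd", "obs")`.
#' @return List with `cohort` (analytic rows), `log` (data frame
#'   `criterion`, `n_excluded`), `n_input`, `n_analytic`.
#' @export
apply_exclusions <- function(cohort, registry = obs_registry(),
                             order = c("mma", "cvd", "obs")) {
  if (!setequal(order, c("mma", "cvd", "obs")))
    stop("order must be a permutation of mma, cvd, obs", call. = FALSE)
  n_input <- nrow(cohort)
  bad <- list(
    mma = is.na(cohort$mma),
    cvd = is.na(cohort$cvd),
    obs = Reduce(`|`, lapply(registry$name,
                             function(nm) is.na(cohort[[nm]]))))
  keep <- rep(TRUE, n_input)
  log <- data.frame(criterion = order, n_excluded = 0L)
  for (i in seq_along(order)) {
    hit <- bad[[order[i]]] & keep
    log$n_excluded[i] <- sum(hit)
    keep <- keep & !hit
  }
  if (!any(keep)) stop("no rows remain after exclusions", call. = FALSE)
  list(cohort = cohort[keep, , drop = FALSE], log = log,
       n_input = n_input, n_analytic = sum(keep))
}

# OR table for one exposure under one covariate set, keeping only the
# exposure row (Tables 2/3 layout)
exposure_or_row <- function(outcome, exposure, covariates, design,
                            single_psu) {
  fit <- svy_logit(stats::reformulate(c(exposure, covariates),
                                      response = outcome),
                   design, single_psu = single_psu)
  ors <- odds_ratios(fit)
  row <- ors[startsWith(ors$term, exposure), , drop = FALSE]
  row$n <- fit$n
  row
}

#' Run the full OBS -> MMA -> CVD analysis
#'
#' Orchestrates the complete pipeline: load or generate the cohort, apply
#' exclusions, score the OBS and dichotomize it at the first tertile, fit
#' the restricted cubic spline of CVD on MMA to locate the inflection
#' point and choose the mediator cutoff, build the weighted descriptive
#' table, fit Models I/II for OBS->CVD, MMA->CVD and OBS->MMA, run the
#' mediation analysis (total and subgroups) and the exposure-by-mediator
#' interaction models, and optionally rerun the primary exposure model on
#' multiply imputed data with Rubin pooling.  The whole run is
#' reproducible from the configuration and its seed.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return An object of class `obs_report`; see [write_report()].
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load"
  result <- tryCatch({
    registry <- if (is.null(config$registry)) obs_registry()
                else obs_registry(config$registry)
    cohort <- if (length(config$synthetic) || is.null(config$input)) {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- config$seed
      generate_cohort(do.call(truth_params, args))
    } else {
      read_cohort(config$input)
    }

    stage <- "exclusions"
    excl <- apply_exclusions(cohort, registry,
                             order = config$exclusion_order)
    dat <- excl$cohort

    stage <- "obs_scoring"
    obs <- compute_obs(dat, registry)
    obs_group <- dichotomize_obs(obs$obs_total, cutoff = config$obs_cutoff)
    dat$obs_total <- obs$obs_total
    dat$obs_group <- obs_group
    design <- svy_design(dat, weights = "weight", strata = "stratum",
                         ids = "psu")

    stage <- "rcs_cutoff"
    med_var <- config$mediator$variable
    rcs <- fit_rcs_logistic(dat$cvd, dat[[med_var]],
                            covariates = config$model2_covariates,
                            design = design,
                            n_knots = config$mediator$n_knots,
                            single_psu = config$single_psu)
    inflection <- find_inflection(rcs)
    cutoff <- if (is.na(inflection)) {
      message("fitted dose-response is monotone; mediator cutoff set to ",
              "the sample median")
      stats::median(dat[[med_var]], na.rm = TRUE)
    } else {
      choose_cutoff(inflection, dat[[med_var]],
                    policy = config$mediator$policy)
    }
    dat$mma_group <- factor(ifelse(dat[[med_var]] >= cutoff, "high", "low"),
                            levels = c("low", "high"))
    design <- svy_design(dat, weights = "weight", strata = "stratum",
                         ids = "psu")

    stage <- "descriptives"
    descriptive <- descriptive_table(dat, design, config$single_psu)

    stage <- "models"
    m1 <- config$model1_covariates
    m2 <- config$model2_covariates
    or_tables <- list(
      obs_cvd = rbind(
        cbind(model = "I", exposure_or_row("cvd", "obs_group", m1,
                                           design, config$single_psu)),
        cbind(model = "II", exposure_or_row("cvd", "obs_group", m2,
                                            design, config$single_psu))),
      mma_cvd = rbind(
        cbind(model = "I", exposure_or_row("cvd", "mma_group", m1,
                                           design, config$single_psu)),
        cbind(model = "II", exposure_or_row("cvd", "mma_group", m2,
                                            design, config$single_psu))),
      obs_mma = rbind(
        cbind(model = "I", exposure_or_row("mma_group", "obs_group", m1,
                                           design, config$single_psu)),
        cbind(model = "II", exposure_or_row("mma_group", "obs_group", m2,
                                            design, config$single_psu))))

    stage <- "mediation"
    mediation <- list()
    for (sg in c(list(NULL), as.list(config$subgroups))) {
      res <- run_mediation("obs_group", "mma_group", "cvd",
                           covariates = m2, design = design,
                           subgroups = sg, draws = config$dop_draws,
                           seed = config$seed + 17L,
                           single_psu = config$single_psu)
      keep <- if (is.null(sg)) res else res[-1]   # total only once
      mediation <- c(mediation, keep)
    }
    mediation <- structure(mediation, class = "mediation_result",
                           exposure = "obs_group", mediator = "mma_group",
                           outcome = "cvd")

    stage <- "interaction"
    interaction_tab <- interaction_table(dat, design, m2,
                                         config$subgroups,
                                         config$single_psu)

    stage <- "imputation"
    mi <- NULL
    if (isTRUE(config$imputation$enabled)) {
      imps <- impute_missing(dat, m = config$imputation$m,
                             seed = config$seed + 31L)
      fits <- lapply(imps, function(di) {
        des_i <- svy_design(di, weights = "weight", strata = "stratum",
                            ids = "psu")
        svy_logit(stats::reformulate(c("obs_group", m2), response = "cvd"),
                  des_i, single_psu = config$single_psu)
      })
      pooled <- rubin_pool(fits)
      mi <- odds_ratios(pooled)
      mi <- mi[startsWith(mi$term, "obs_group"), , drop = FALSE]
      mi$m <- config$imputation$m
    }

    structure(list(
      provenance = list(
        seed = config$seed,
        n_input = excl$n_input,
        exclusions = excl$log,
        n_analytic = excl$n_analytic,
        obs_cutoff = as.numeric(attr(obs_group, "cutoff")),
        mma_inflection = as.numeric(inflection),
        mma_cutoff = as.numeric(cutoff),
        config = unclass(config)),
      descriptive = descriptive,
      or_tables = or_tables,
      rcs = list(knots = rcs$knots, p_overall = rcs$p_overall,
                 p_nonlinear = rcs$p_nonlinear),
      mediation = mediation,
      interaction = interaction_tab,
      mi_sensitivity = mi
    ), class = "obs_report")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

# weighted descriptive table by CVD status: weighted mean (SE) and
# design-based z test for continuous variables; counts, weighted % and
# Rao-Scott chi-square for categorical variables
descriptive_table <- function(dat, design, single_psu) {
  cont <- intersect(c("age", "wbc", "vitamin_b12", "energy", "mma",
                      "obs_total"), names(dat))
  cat_vars <- intersect(c("obs_group", "mma_group", "gender", "race",
                          "education", "pir_group", "diabetes",
                          "dyslipidemia"), names(dat))
  rows <- list()
  for (v in cont) {
    tot <- weighted_mean_se(dat[[v]], design, single_psu = single_psu)
    tst <- svy_mean_diff_test(dat[[v]], dat$cvd, design,
                              single_psu = single_psu)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      overall = tot[["mean"]], overall_se = tot[["se"]],
      statistic = tst$statistic, p = tst$p)
  }
  for (v in cat_vars) {
    tst <- rao_scott_chisq(dat[[v]], dat$cvd, design,
                           single_psu = single_psu)
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      overall = NA_real_, overall_se = NA_real_,
      statistic = tst$statistic, p = tst$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Table-5-style interaction rows: exposure, mediator, and their product
# term under the full covariate set, per population
interaction_table <- function(dat, design, covariates, subgroups,
                              single_psu) {
  pops <- list(total = rep(TRUE, nrow(dat)))
  for (sg in subgroups) {
    gv <- dat[[sg]]
    for (lv in sort(unique(gv[!is.na(gv)])))
      pops[[paste0(sg, "=", lv)]] <- !is.na(gv) & gv == lv
  }
  out <- list()
  for (nm in names(pops)) {
    des <- subset_design(design, pops[[nm]])
    covs <- setdiff(covariates, sub("=.*", "", nm))
    fit <- tryCatch(
      svy_logit(stats::reformulate(c("obs_group * mma_group", covs),
                                   response = "cvd"),
                des, single_psu = single_psu),
      error = function(e) NULL)
    if (is.null(fit)) next
    ors <- odds_ratios(fit)
    sel <- ors[grepl("obs_group|mma_group", ors$term), , drop = FALSE]
    sel$population <- nm
    out[[nm]] <- sel[, c("population", "term", "or", "lower", "upper", "p")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.obs_report <- function(x, ...) {
  p <- x$provenance
  cat("OBS -> MMA -> CVD analysis report\n")
  cat(sprintf("  input n = %d, analytic n = %d (exclusions: %s)\n",
              p$n_input, p$n_analytic,
              paste(sprintf("%s %d", p$exclusions$criterion,
                            p$exclusions$n_excluded), collapse = ", ")))
  cat(sprintf("  OBS cutoff %.4g; MMA inflection %.4g -> cutoff %.4g\n",
              p$obs_cutoff, p$mma_inflection, p$mma_cutoff))
  cat(sprintf("  RCS: p_overall = %.3g, p_nonlinear = %.3g\n",
              x$rcs$p_overall, x$rcs$p_nonlinear))
  cat("\nExposure odds ratios (Model I / II):\n")
  for (nm in names(x$or_tables)) {
    cat(" ", nm, "\n")
    print(format(x$or_tables[[nm]], digits = 3), row.names = FALSE)
  }
  cat("\nMediation:\n")
  print(x$mediation)
  invisible(x)
}

#' Write a report to disk as JSON plus per-table CSVs
#'
#' @param report an `obs_report`.
#' @param dir output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "obs_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  med_df <- as.data.frame(report$mediation)
  json <- jsonlite::toJSON(list(
    provenance = report$provenance,
    descriptive = report$descriptive,
    or_tables = report$or_tables,
    rcs = report$rcs,
    mediation = med_df,
    interaction = report$interaction,
    mi_sensitivity = report$mi_sensitivity
  ), auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  json_path <- file.path(dir, "report.json")
  writeLines(json, json_path)
  utils::write.csv(med_df, file.path(dir, "mediation.csv"),
                   row.names = FALSE)
  utils::write.csv(report$descriptive, file.path(dir, "descriptive.csv"),
                   row.names = FALSE)
  for (nm in names(report$or_tables))
    utils::write.csv(report$or_tables[[nm]],
                     file.path(dir, paste0("or_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(report$interaction, file.path(dir, "interaction.csv"),
                   row.names = FALSE)
  invisible(json_path)
}

#' Read a cohort table from CSV
#'
#' Restores the factor codings expected by the pipeline (gender, race,
#' education, PIR group, OBS/MMA groups when present).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("gender" %in% names(dat))
    dat$gender <- factor(dat$gender, levels = c("male", "female"))
  if ("race" %in% names(dat))
    dat$race <- factor(dat$race, levels = race_levels())
  if ("education" %in% names(dat))
    dat$education <- factor(dat$education, levels = education_levels())
  if ("pir_group" %in% names(dat))
    dat$pir_group <- factor(dat$pir_group, levels = pir_levels())
  dat
}

#' Write a cohort table with its data dictionary
#'
#' Writes the cohort as CSV and emits a companion data-dictionary file
#' describing every column (name, type, units).
#'
#' @param cohort data frame following [cohort_schema()].
#' @param path output CSV path; the dictionary is written alongside with
#'   suffix `_dictionary.csv`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  dict <- data.frame(
    column = names(cohort),
    type = vapply(cohort, function(x) class(x)[1], character(1)),
    description = cohort_column_docs()[names(cohort)])
  utils::write.csv(dict,
                   sub("\\.csv$", "_dictionary.csv", path),
                   row.names = FALSE)
  invisible(path)
}

cohort_column_docs <- function() {
  docs <- c(
    id = "participant identifier",
    age = "age in years",
    gender = "male/female",
    race = "5-level race/ethnicity category",
    education = "3-level education category",
    pir_group = "poverty-income ratio group (<1, >=1, unknown)",
    diabetes = "diabetes (0/1)",
    dyslipidemia = "dyslipidemia (0/1)",
    wbc = "white blood cells, 1000 cells/uL",
    vitamin_b12 = "serum vitamin B12, pmol/L",
    energy = "energy intake, kcal/day",
    weight = "sampling weight",
    stratum = "sampling stratum",
    psu = "primary sampling unit within stratum",
    met_score = "physical activity, MET score",
    cotinine = "serum cotinine, ng/mL",
    alcohol_g_day = "alcohol consumption, g/day",
    bmi = "body mass index, kg/m2",
    mma = "serum methylmalonic acid, nmol/L",
    cvd = "self-reported cardiovascular disease (0/1)",
    low_obs_true = "latent truth: low-OBS exposure indicator",
    mma_high_true = "latent truth: high-MMA indicator")
  diet <- c(
    d_fiber = "dietary fiber, g/day",
    d_carotene = "carotene, ug/day",
    d_riboflavin = "riboflavin, mg/day",
    d_niacin = "niacin, mg/day",
    d_vitamin_b6 = "vitamin B6, mg/day",
    d_total_folate = "total folate, ug/day",
    d_vitamin_b12 = "dietary vitamin B12, ug/day",
    d_vitamin_c = "vitamin C, mg/day",
    d_vitamin_e = "vitamin E, mg/day",
    d_calcium = "calcium, mg/day",
    d_magnesium = "magnesium, mg/day",
    d_zinc = "zinc, mg/day",
    d_copper = "copper, mg/day",
    d_selenium = "selenium, ug/day",
    d_total_fat = "total fat, g/day",
    d_iron = "total iron intake, mg/day")
  c(docs, diet)
}
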