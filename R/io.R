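# Reading and writing the parameter tables, config bundles, traces and
# reports. Tables travel as plain CSV (age_lower, age_upper, sex, outcome,
# value), scalar settings as YAML, reports as CSV + JSON with a config echo
# and a run manifest for provenance.

#' Write / read a baseline participation table as long CSV
#'
#' Columns: `age_lower`, `age_upper`, `sex`, `outcome`, `value`.
#'
#' @param bp A [baseline_participation()] table.
#' @param path CSV file path.
#' @return `write_baseline_csv` returns `path` invisibly;
#'   `read_baseline_csv` returns the validated table.
#' @export
write_baseline_csv <- function(bp, path) {
  df <- as.data.frame(bp)
  long <- do.call(rbind, lapply(.outcomes, function(o)
    data.frame(age_lower = df$age_lower, age_upper = df$age_upper,
               sex = df$sex, outcome = o, value = df[[o]])))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_baseline_csv
#' @export
read_baseline_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_lower", "age_upper", "sex", "outcome", "value")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!long$outcome %in% .outcomes)
  if (length(bad))
    stop(sprintf("%s: line %d: unknown outcome '%s'", path, bad[1] + 1,
                 long$outcome[bad[1]]), call. = FALSE)
  bad <- which(!is.na(long$value) & (long$value < 0 | long$value > 1))
  if (length(bad))
    stop(sprintf("%s: line %d: value %s outside [0, 1]", path, bad[1] + 1,
                 format(long$value[bad[1]])), call. = FALSE)
  wide <- unique(long[c("sex", "age_lower", "age_upper")])
  for (o in .outcomes) {
    sub <- long[long$outcome == o, ]
    wide[[o]] <- sub$value[match(
      paste(wide$sex, wide$age_lower),
      paste(sub$sex, sub$age_lower))]
  }
  baseline_participation(wide)
}

#' Write / read a full input bundle as a directory
#'
#' Materialises `baseline.csv`, `lifetable.csv`, `effects.csv`,
#' `schedule.yaml`, `healthcare.yaml` (and reads them back into a bundle
#' for [run_model()]).
#'
#' @param inputs A model input bundle.
#' @param dir Directory (created if needed).
#' @return `write_inputs` returns `dir` invisibly; `read_inputs` returns
#'   the bundle.
#' @export
write_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_baseline_csv(inputs$baseline, file.path(dir, "baseline.csv"))
  write.csv(as.data.frame(inputs$lifetable),
            file.path(dir, "lifetable.csv"), row.names = FALSE)
  eff <- do.call(rbind, lapply(c("moderate", "severe"), function(sev) {
    es <- inputs$effects[[sev]]
    if (is.null(es)) return(NULL)
    do.call(rbind, lapply(es$effects, function(e)
      data.frame(severity = sev, outcome = e$outcome, measure = e$measure,
                 point = e$point, ci_low = e$ci_low, ci_high = e$ci_high,
                 age_lower = e$age_lower %||% NA,
                 age_upper = e$age_upper %||% NA)))
  }))
  write.csv(eff, file.path(dir, "effects.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(inputs$schedule)[setdiff(
    names(unclass(inputs$schedule)), "labour_tax")],
    file.path(dir, "schedule.yaml"))
  write.csv(inputs$schedule$labour_tax, file.path(dir, "labour_tax.csv"),
            row.names = FALSE)
  hc <- unclass(inputs$healthcare)
  yaml::write_yaml(hc[setdiff(names(hc), c("primary", "revision"))],
                   file.path(dir, "healthcare.yaml"))
  write.csv(rbind(cbind(kind = "primary", inputs$healthcare$primary),
                  cbind(kind = "revision", inputs$healthcare$revision)),
            file.path(dir, "surgery.csv"), row.names = FALSE)
  yaml::write_yaml(list(oa_excess_hr = inputs$mortality$oa_excess_hr,
                        oa_excess_ci = inputs$mortality$oa_excess_ci,
                        womac_hr_per_10 = inputs$mortality$womac_hr_per_10,
                        womac_ci = inputs$mortality$womac_ci),
                   file.path(dir, "mortality.yaml"))
  invisible(dir)
}

#' @rdname write_inputs
#' @export
read_inputs <- function(dir) {
  need <- c("baseline.csv", "lifetable.csv", "effects.csv",
            "schedule.yaml", "labour_tax.csv", "healthcare.yaml",
            "surgery.csv", "mortality.yaml")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("input directory is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  eff_df <- read.csv(file.path(dir, "effects.csv"),
                     stringsAsFactors = FALSE)
  effects <- lapply(setNames(c("moderate", "severe"),
                             c("moderate", "severe")), function(sev) {
    sub <- eff_df[eff_df$severity == sev, ]
    if (!nrow(sub)) return(NULL)
    relative_effect_set(sev, lapply(seq_len(nrow(sub)), function(i)
      relative_effect(sub$outcome[i], sub$measure[i], sub$point[i],
                      sub$ci_low[i], sub$ci_high[i],
                      if (is.na(sub$age_lower[i])) NULL else
                        sub$age_lower[i],
                      if (is.na(sub$age_upper[i])) NULL else
                        sub$age_upper[i])))
  })
  sched <- yaml::read_yaml(file.path(dir, "schedule.yaml"))
  sched$labour_tax <- read.csv(file.path(dir, "labour_tax.csv"))
  hc <- yaml::read_yaml(file.path(dir, "healthcare.yaml"))
  surg <- read.csv(file.path(dir, "surgery.csv"))
  hc$primary <- surg[surg$kind == "primary", c("name", "prob", "cost")]
  hc$revision <- surg[surg$kind == "revision", c("name", "prob", "cost")]
  mort <- yaml::read_yaml(file.path(dir, "mortality.yaml"))
  list(baseline = read_baseline_csv(file.path(dir, "baseline.csv")),
       effects = effects,
       lifetable = lifetable(read.csv(file.path(dir, "lifetable.csv"))),
       mortality = mortality_adjustment(mort$oa_excess_hr,
                                        unlist(mort$oa_excess_ci),
                                        mort$womac_hr_per_10,
                                        unlist(mort$womac_ci)),
       schedule = do.call(fiscal_schedule, sched),
       healthcare = do.call(healthcare_costs, hc))
}

#' Write / read a model configuration as YAML
#'
#' @param config A [model_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   validated config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(unclass(model_config()))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(path, ": unknown config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  validate_model_config(modifyList(unclass(model_config()),
                                   vals[setdiff(names(vals),
                                                "cycle_length")]))
}

#' Write cohort traces as tidy CSV
#'
#' @param result An `oafiscal_result` produced with `keep_traces = TRUE`.
#' @param path CSV path; columns `cycle`, `age`, `state`, `occupancy`,
#'   `arm`, `sex`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  rows <- list()
  for (arm in c("controlled", "moderate", "severe")) {
    traces <- attr(result[[arm]], "traces")
    if (is.null(traces))
      stop("result has no traces; rerun with keep_traces = TRUE",
           call. = FALSE)
    for (tr in traces) rows[[length(rows) + 1]] <- as.data.frame(tr)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record for a set of outputs: config hash, package version,
#' seed, timestamp and the warnings emitted during the run.
#'
#' @param config A [model_config()].
#' @param warnings Character vector of warnings emitted.
#' @return A list (class `run_manifest`).
#' @export
run_manifest <- function(config, warnings = character()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       null = "null")
  structure(list(config_hash = unname(tools::md5sum(tmp)),
                 package_version = as.character(packageVersion("oafiscal")),
                 seed = config$seed,
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"),
                 warnings = warnings),
            class = "run_manifest")
}

#' Write the disaggregated report
#'
#' Writes `report.csv` (the [disaggregate()] table), `report.json` (the
#' same values plus INT, healthcare shares, a config echo, currency field
#' and manifest) and, when traces were kept, `trace.csv`.
#'
#' @param result An `oafiscal_result`.
#' @param dir Output directory (created if needed).
#' @param warnings Warnings to record in the manifest.
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir, warnings = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- disaggregate(result)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 2)
  write.csv(tab, file.path(dir, "report.csv"), row.names = FALSE)
  manifest <- run_manifest(result$config, warnings)
  payload <- list(
    currency = "GBP",
    int = as.list(result$int),
    healthcare_share = list(
      moderate = healthcare_share(result, "moderate"),
      severe = healthcare_share(result, "severe")),
    table = tab,
    config = unclass(result$config),
    manifest = unclass(manifest))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 2, null = "null",
                       dataframe = "rows")
  if (!is.null(attr(result$controlled, "traces")))
    write_trace_csv(result, file.path(dir, "trace.csv"))
  invisible(dir)
}
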