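#' @name tidy-format
#' @title The canonical tidy time-series format
#' @description
#' Datasets move through the package as data frames with seven columns:
#' `experiment_id`, `channel_id`, `time_h`, `variable`, `compartment`,
#' `value`, `unit`.  Keys `(experiment_id, channel_id, time_h, variable,
#' compartment)` must be unique; units must be consistent within a
#' variable; rows are kept in (experiment, channel, variable,
#' compartment, time) order.  Times are hours with t = 0 at inoculation.
NULL

.tidy_cols <- c("experiment_id", "channel_id", "time_h", "variable",
                "compartment", "value", "unit")

.tidy_order <- function(df)
  df[order(df$experiment_id, df$channel_id, df$variable, df$compartment, df$time_h), ]

.tidy_check <- function(df) {
  miss <- setdiff(.tidy_cols, names(df))
  if (length(miss)) stop("missing tidy columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(df$value) || any(!is.finite(df$value))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
    stop("non-numeric value cell(s) at row(s): ", paste(utils::head(bad, 10), collapse = ", "))
  }
  key <- do.call(paste, c(df[c("experiment_id", "channel_id", "time_h",
                               "variable", "compartment")], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate keys:\n", paste(utils::head(gsub("\r", " / ", key[dup]), 10), collapse = "\n"))
  for (v in unique(df$variable))
    if (length(unique(df$unit[df$variable == v])) > 1)
      stop("inconsistent units within variable '", v, "'")
  invisible(df)
}

#' Convert a generated dataset to / from the tidy format
#'
#' @param dataset List of `series_data` (e.g. from
#'   [generate_dataset()]).
#' @return `as_tidy()`: a tidy data frame; `tidy_to_series()`: a list of
#'   `series_data`, one per (experiment, channel, variable, compartment)
#'   combination, in tidy order.
#' @export
as_tidy <- function(dataset) {
  if (inherits(dataset, "series_data")) dataset <- list(dataset)
  out <- do.call(rbind, lapply(dataset, function(s)
    data.frame(experiment_id = s$experiment_id, channel_id = s$channel_id,
               time_h = s$times, variable = s$variable, compartment = s$compartment,
               value = s$values, unit = s$unit)))
  rownames(out) <- NULL
  .tidy_order(out)
}

#' @param df A tidy data frame.
#' @rdname as_tidy
#' @export
tidy_to_series <- function(df) {
  .tidy_check(df)
  df <- .tidy_order(df)
  key <- interaction(df$experiment_id, df$channel_id, df$variable, df$compartment,
                     drop = TRUE, lex.order = TRUE)
  lapply(split(df, key), function(d)
    series_data(d$time_h, d$value, experiment_id = d$experiment_id[1],
                channel_id = d$channel_id[1], variable = d$variable[1],
                compartment = d$compartment[1], unit = d$unit[1]))
}

#' Read / write tidy time-series CSV
#'
#' Lossless round trip of the seven-column tidy format (see
#' [tidy-format]); rows are written in canonical order; duplicate keys
#' and non-numeric values raise errors naming the offenders.
#'
#' @param path CSV path.
#' @return `read_tidy()`: validated tidy data frame.
#' @export
read_tidy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .tidy_check(df)
  .tidy_order(df)
}

#' @param df Tidy data frame to write.
#' @rdname read_tidy
#' @export
write_tidy <- function(df, path) {
  .tidy_check(df)
  utils::write.csv(.tidy_order(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read COMSTAT text exports into the tidy format
#'
#' COMSTAT writes one delimited text table per image stack (header row;
#' tab- or whitespace-separated) and encodes no timestamps or channel
#' identity, so a manifest maps each file to its metadata.  The
#' requested feature column is located by name (dialect-tolerant
#' matching ignores case and punctuation; common synonyms are known) and
#' summarised by its mean when a file holds several image positions.
#'
#' @param paths Character vector of COMSTAT file paths.
#' @param feature One of `"biomass"`, `"avg_thickness"`,
#'   `"max_thickness"`, `"area"`, `"colony_volume"`.
#' @param mapping Data frame manifest with columns `file` (matched
#'   against `basename(paths)`), `experiment_id`, `channel_id`,
#'   `time_h`, `compartment`.
#' @param feature_column Optional explicit column name overriding the
#'   synonym search.
#' @return Tidy data frame (one row per file) with default units:
#'   biomass um^3/um^2, thicknesses um, area um^2, colony volume um^3.
#' @export
read_comstat <- function(paths,
                         feature = c("biomass", "avg_thickness", "max_thickness",
                                     "area", "colony_volume"),
                         mapping, feature_column = NULL) {
  feature <- match.arg(feature)
  need <- c("file", "experiment_id", "channel_id", "time_h", "compartment")
  if (!is.data.frame(mapping) || !all(need %in% names(mapping)))
    stop("mapping must be a data frame with columns: ", paste(need, collapse = ", "))
  syn <- list(
    biomass = c("biomass", "biovolume", "totalbiomass"),
    avg_thickness = c("avgthickness", "averagethickness", "meanthickness"),
    max_thickness = c("maxthickness", "maximumthickness"),
    area = c("area", "substratumcoverage", "areaoccupied"),
    colony_volume = c("colonyvolume", "microcolonyvolume", "colonyvolumesatsubstratum"))
  unit <- switch(feature, biomass = "um^3/um^2", avg_thickness = "um",
                 max_thickness = "um", area = "um^2", colony_volume = "um^3")
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  rows <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    first <- readLines(p, n = 1L)
    sep <- if (length(first) && grepl("\t", first)) "\t" else ""
    tab <- tryCatch(utils::read.table(p, header = TRUE, sep = sep, check.names = TRUE),
                    error = function(e) stop("cannot parse '", p, "': ", conditionMessage(e)))
    if (!nrow(tab)) stop("empty COMSTAT file: ", p)
    cn <- if (!is.null(feature_column)) {
      hit <- which(norm(names(tab)) == norm(feature_column))
      if (!length(hit)) stop("column '", feature_column, "' not in ", p,
                             "; available: ", paste(names(tab), collapse = ", "))
      hit[1]
    } else {
      hit <- which(norm(names(tab)) %in% syn[[feature]])
      if (!length(hit))
        stop("no column for feature '", feature, "' in ", p,
             "; available: ", paste(names(tab), collapse = ", "))
      hit[1]
    }
    m <- mapping[mapping$file == basename(p), , drop = FALSE]
    if (!nrow(m)) stop("file not in mapping manifest: ", basename(p))
    data.frame(experiment_id = m$experiment_id[1], channel_id = m$channel_id[1],
               time_h = m$time_h[1], variable = feature, compartment = m$compartment[1],
               value = mean(as.numeric(tab[[cn]])), unit = unit)
  })
  out <- .tidy_order(do.call(rbind, rows))
  rownames(out) <- NULL
  .tidy_check(out)
}

#' Read / write measured concentration-time profiles
#'
#' PK CSV format: columns `time_h`, `conc`, `agent`.  Reading returns
#' one interpolated-mode [pk_profile()] per agent.
#'
#' @param path CSV path.
#' @param unit Concentration unit label attached to the profiles.
#' @return `read_pk_csv()`: named list of [pk_profile()]s.
#' @export
read_pk_csv <- function(path, unit = "mg/L") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "conc", "agent") %in% names(df)))
    stop("PK CSV needs columns time_h, conc, agent")
  lapply(split(df, df$agent), function(d) {
    d <- d[order(d$time_h), ]
    pk_profile(d$agent[1], "interpolated",
               points = data.frame(time = d$time_h, conc = d$conc), unit = unit)
  })
}

# ---- config-file plumbing ---------------------------------------------

#' Build a model specification from a config list
#'
#' Interprets the structured document used by the command-line entry
#' point (YAML; see the methods vignette for the schema): a `growth`
#' block, optional `agent_effect` (the two-agent models are recognised
#' by name), `effect_sign`, a `pk` list (bolus/infusion events or
#' interpolated points), `dead_model` and `post_plateau`.
#'
#' @param cfg Named list, typically `yaml::read_yaml(path)$model`.
#' @return A [model_spec()].
#' @export
spec_from_config <- function(cfg) {
  if (is.null(cfg$growth)) stop("config needs a growth block")
  growth <- do.call(growth_params, cfg$growth)
  ae <- NULL
  if (!is.null(cfg$agent_effect)) {
    two <- cfg$agent_effect$model %in% c("additive_linear", "linear_interaction",
                                         "competitive_interaction", "competitive_antagonism")
    ae <- do.call(if (two) two_agent_params else agent_params, cfg$agent_effect)
  }
  pk <- lapply(cfg$pk, function(p) {
    if (!is.null(p$events))
      p$events <- do.call(rbind, lapply(p$events, as.data.frame))
    if (!is.null(p$points))
      p$points <- do.call(rbind, lapply(p$points, as.data.frame))
    do.call(pk_profile, p)
  })
  model_spec(growth, agent_effect = ae,
             effect_sign = cfg$effect_sign %||% "inhibit",
             pk = pk, dead_model = cfg$dead_model %||% "none",
             post_plateau = cfg$post_plateau)
}

.cli_usage <- "usage: biofilmkin <simulate|generate|fit|compare|residuals> [options]
  simulate  --config cfg.yaml --out traj.csv [--tmax H --dt H]
  generate  --preset NAME --seed N --out DIR
  fit       --data data.csv --config cfg.yaml --method single|two-stage|mixed
            [--random p1,p2] [--seed N] --out report.json
  compare   REPORT.json [REPORT2.json ...] [--criterion aic|hq|hq-as-printed]
  residuals --report report.json --data data.csv --config cfg.yaml --out res.csv
"

.cli_opts <- function(args) {
  opts <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[i + 1L], "--"))
        stop("flag ", a, " needs a value")
      opts[[substring(a, 3)]] <- args[i + 1L]; i <- i + 2L
    } else { opts$positional <- c(opts$positional, a); i <- i + 1L }
  }
  opts
}

#' Command-line entry point
#'
#' Thin shell binding of the package functions; a wrapper script
#' suitable for `Rscript` ships in `inst/cli/biofilmkin.R`.  Subcommands:
#' `simulate` (config to trajectory CSV), `generate` (preset to tidy
#' dataset + JSON truth sidecar), `fit` (data + model config to a JSON
#' report; `--method single|two-stage|mixed`), `compare` (fit reports to
#' an AIC/HQ table on stdout), `residuals` (report + data to a
#' weighted-residual CSV).  All randomness flows through `--seed`.
#' Structured progress goes to stderr.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly=TRUE)`.
#' @return Exit code, invisibly: 0 success, 2 configuration/usage error,
#'   3 convergence failure.
#' @export
biofilm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  say <- function(...) message("[biofilmkin] ", sprintf(...))
  fail <- function(code, msg) { message(.cli_usage); message("error: ", msg); invisible(code) }
  if (!length(args)) return(fail(2L, "no subcommand"))
  cmd <- args[1]
  op <- tryCatch(.cli_opts(args[-1]), error = function(e) conditionMessage(e))
  if (is.character(op)) return(fail(2L, op))
  seed <- as.integer(op$seed %||% 1)

  res <- tryCatch(switch(cmd,
    simulate = {
      cfg <- yaml::read_yaml(op$config)
      spec <- spec_from_config(cfg$model)
      tmax <- as.numeric(op$tmax %||% cfg$simulate$t_max %||% 168)
      dt <- as.numeric(op$dt %||% cfg$simulate$dt %||% 1)
      traj <- simulate_trajectory(spec, seq(0, tmax, by = dt))
      utils::write.csv(as.data.frame(traj), op$out, row.names = FALSE, quote = FALSE)
      say("trajectory written to %s", op$out); 0L
    },
    generate = {
      d <- design_preset(op$preset)
      dat <- generate_dataset(d, seed = seed)
      dir.create(op$out, showWarnings = FALSE, recursive = TRUE)
      write_tidy(as_tidy(dat), file.path(op$out, "dataset.csv"))
      jsonlite::write_json(attr(dat, "truth"), file.path(op$out, "truth.json"),
                           dataframe = "rows", digits = NA)
      say("dataset + truth sidecar written to %s", op$out); 0L
    },
    fit = {
      cfg <- yaml::read_yaml(op$config)
      spec <- spec_from_config(cfg$model)
      series <- tidy_to_series(read_tidy(op$data))
      method <- op$method %||% "single"
      report <- switch(method,
        single = {
          f <- fit_single(series, spec, estimate = unlist(cfg$fit$estimate),
                          multistart = as.integer(cfg$fit$multistart %||% 8), seed = seed)
          if (!isTRUE(f$convergence$converged)) stop("convergence failure", call. = FALSE)
          list(method = "single", estimates = as.list(f$estimates), se = as.list(f$se),
               objective = f$objective, n_obs = f$n_obs, n_params = f$n_params,
               aic = f$aic, hq = f$hq, converged = f$convergence$converged, seed = seed)
        },
        `two-stage` = {
          f <- fit_two_stage(series, spec, estimate = unlist(cfg$fit$estimate), seed = seed)
          list(method = "two-stage", summary = f$summary, failed = f$failed, seed = seed)
        },
        mixed = {
          rnd <- strsplit(op$random %||% "Bmax", ",")[[1]]
          f <- fit_mixed_effects(series, spec, random = rnd,
                                 estimate = unlist(cfg$fit$estimate), seed = seed)
          list(method = "mixed", fixed_effects = as.list(f$fixed_effects),
               cv_percent = as.list(f$cv_percent), sigma = f$sigma,
               objective = f$objective, n_obs = f$n_obs, n_params = f$n_params,
               aic = f$aic, hq = f$hq, seed = seed)
        },
        stop("unknown method: ", method, call. = FALSE))
      report$config <- cfg
      jsonlite::write_json(report, op$out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      say("fit report written to %s", op$out); 0L
    },
    compare = {
      reps <- lapply(op$positional, jsonlite::read_json, simplifyVector = TRUE)
      crit <- gsub("-", "_", op$criterion %||% "aic")
      n <- vapply(reps, function(r) as.numeric(r$n_obs), numeric(1))
      obj <- vapply(reps, function(r) as.numeric(r$objective), numeric(1))
      p <- vapply(reps, function(r) as.numeric(r$n_params), numeric(1))
      val <- switch(crit, aic = obj + 2 * p, hq = obj + 2 * p * log(log(n)),
                    hq_as_printed = obj + 2 * p * log(n),
                    stop("unknown criterion", call. = FALSE))
      tab <- data.frame(report = basename(op$positional), objective = obj,
                        n_params = p, value = val)
      names(tab)[4] <- crit
      tab <- tab[order(val, p), ]; tab$rank <- seq_len(nrow(tab))
      utils::write.table(tab, stdout(), row.names = FALSE, quote = FALSE, sep = "\t")
      0L
    },
    residuals = {
      cfg <- yaml::read_yaml(op$config)
      rep <- jsonlite::read_json(op$report, simplifyVector = TRUE)
      spec <- spec_from_config(cfg$model)
      est <- unlist(rep$estimates)
      spec <- .update_spec(spec, as.list(est[setdiff(names(est), "sigma")]))
      series <- tidy_to_series(read_tidy(op$data))
      preds <- lapply(series, function(s) .predict_series(spec, s$times, s$compartment))
      out <- do.call(rbind, lapply(seq_along(series), function(i) {
        s <- series[[i]]
        data.frame(experiment_id = s$experiment_id, channel_id = s$channel_id,
                   time_h = s$times, observed = s$values, predicted = preds[[i]],
                   wres = (s$values - preds[[i]]) / est[["sigma"]])
      }))
      utils::write.csv(out, op$out, row.names = FALSE, quote = FALSE)
      say("weighted residuals written to %s", op$out); 0L
    },
    fail(2L, paste("unknown subcommand:", cmd))),
    error = function(e) {
      msg <- conditionMessage(e)
      message("error: ", msg)
      if (grepl("convergence", msg, ignore.case = TRUE)) 3L else 2L
    })
  invisible(if (is.numeric(res)) as.integer(res) else 0L)
}
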