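#' Read a per-spine record table from CSV
#'
#' Expects the canonical header
#' `id,sample_id,condition,volume_um3,psd_area_um2,psd_core_volume_um3,
#' has_ser,has_spine_apparatus,perforated,n_synapses` and validates every
#' row: positive measurements, known condition, and the structural
#' invariant that a spine apparatus implies SER.  Errors name the offending
#' column or row.
#'
#' @param path CSV file path.
#' @return A validated record data.frame.
#' @seealso [write_records()]
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(record_columns(), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("has_ser", "has_spine_apparatus", "perforated")) {
    v <- df[[col]]
    if (is.character(v)) v <- tolower(v) %in% c("true", "t", "1", "yes")
    df[[col]] <- as.logical(v)
  }
  df$n_synapses <- as.integer(df$n_synapses)
  if (any(!is.finite(df$n_synapses)) || any(df$n_synapses < 1L)) {
    stop("'n_synapses' must be an integer >= 1 in every row",
         call. = FALSE)
  }
  check_records(df)
  df
}

#' Write a per-spine record table to CSV
#'
#' @param records validated record data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  check_records(records)
  write.csv(records[, record_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs.  Exactly one input source
#' must be given: a synthetic-population configuration (`synth`), a record
#' table (`records`, data.frame or CSV path), or a list of annotated trace
#' stacks (`traces`) to be measured first.
#'
#' @param synth a [synth_config()]; the default when no other source is
#'   given.
#' @param records a record data.frame or CSV path.
#' @param traces list of entries `list(stack = <trace_stack>, sample_id,
#'   condition, has_ser, has_spine_apparatus, perforated)`; volume and PSD
#'   area are measured from the stack.
#' @param local_corr a [local_corr_params()].
#' @param brick a [brick_spec()] for the density census.
#' @param density_intensity expected synapse density (um^-3) used when the
#'   brick scenes are simulated (synthetic input only).
#' @param n_bricks_per_sample bricks counted per sample.
#' @param section_thickness section thickness (um) used when measuring
#'   trace input.
#' @param outdir optional output directory; when set, [run_pipeline()]
#'   writes the CSV/JSON report files there.
#' @param seed global seed; every stochastic stage derives its seed from
#'   it, so a fixed seed reproduces the full report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, records = NULL, traces = NULL,
                            local_corr = local_corr_params(),
                            brick = brick_spec(),
                            density_intensity = 1.2,
                            n_bricks_per_sample = 4L,
                            section_thickness = 0.06,
                            outdir = NULL, seed = 1L) {
  sources <- c(synth = !is.null(synth), records = !is.null(records),
               traces = !is.null(traces))
  if (sum(sources) == 0L) {
    synth <- synth_config()
    sources["synth"] <- TRUE
  }
  if (sum(sources) > 1L) {
    stop("exactly one input source allowed, got: ",
         paste(names(sources)[sources], collapse = " + "), call. = FALSE)
  }
  if (!is.null(synth) && !inherits(synth, "synth_config")) {
    stop("'synth' must be a synth_config", call. = FALSE)
  }
  if (!inherits(local_corr, "local_corr_params")) {
    stop("'local_corr' must be a local_corr_params object", call. = FALSE)
  }
  if (!inherits(brick, "brick_spec")) {
    stop("'brick' must be a brick_spec", call. = FALSE)
  }
  check_scalar(density_intensity, "density_intensity", positive = TRUE)
  check_scalar(n_bricks_per_sample, "n_bricks_per_sample",
               positive = TRUE, integer = TRUE)
  check_scalar(section_thickness, "section_thickness", positive = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(input = names(sources)[sources],
                 synth = synth, records = records, traces = traces,
                 local_corr = local_corr, brick = brick,
                 density_intensity = density_intensity,
                 n_bricks_per_sample = as.integer(n_bricks_per_sample),
                 section_thickness = section_thickness,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# measure trace input into a record table
measure_trace_input <- function(traces, thickness) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (is.null(tr$stack) || !inherits(tr$stack, "trace_stack")) {
      stop("traces[[", i, "]] has no trace_stack under $stack",
           call. = FALSE)
    }
    grab <- function(field, default) {
      if (is.null(tr[[field]])) default else tr[[field]]
    }
    data.frame(
      id = tr$stack$object_id,
      sample_id = grab("sample_id", "sample_1"),
      condition = grab("condition", "control"),
      volume_um3 = measure_volume(tr$stack, "spine"),
      psd_area_um2 = measure_psd_area(tr$stack),
      psd_core_volume_um3 = grab(
        "psd_core_volume_um3",
        tryCatch(measure_volume(tr$stack, "psd_core"),
                 error = function(e) NA_real_)),
      has_ser = grab("has_ser", FALSE),
      has_spine_apparatus = grab("has_spine_apparatus", FALSE),
      perforated = grab("perforated", FALSE),
      n_synapses = grab("n_synapses", 1L),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full spine/PSD coupling analysis
#'
#' Orchestrates the analysis end to end: obtain records (generate, read or
#' measure), estimate per-sample spine densities with unbiased bricks,
#' compute local Spearman profiles for the three parameter pairs (PSD area
#' vs volume, PSD-core volume vs volume, PSD area vs PSD-core volume) in
#' each condition with decoupling-band summaries and a between-condition
#' chi-square on decoupled counts, run the group statistics (Mann-Whitney
#' on sizes and ratios, log-log regressions with ANCOVA, Kruskal-Wallis +
#' Dunn across condition x SER strata, SER-stratified relative changes),
#' tabulate perforation against SER, and bin the volume histogram.  The
#' whole report is deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `spine_report`; when `config$outdir` is set the
#'   tables are also written as CSV and the summary as JSON.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be a pipeline_config", call. = FALSE)
  }
  seed <- config$seed
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  say("seed: %d", seed)
  say("input source: %s", config$input)

  ## records
  records <- stage("records", switch(config$input,
    synth = {
      cfg <- config$synth
      cfg$seed <- seed + 1L
      generate_population(cfg)
    },
    records = {
      if (is.character(config$records)) read_records(config$records)
      else check_records(config$records)
    },
    traces = measure_trace_input(config$traces,
                                 config$section_thickness)))
  say("records: %d spines (%s)", nrow(records),
      paste(sprintf("%s: %d", names(table(records$condition)),
                    table(records$condition)), collapse = ", "))

  conds <- intersect(c("control", "cltp"), unique(records$condition))
  both_conditions <- length(conds) == 2L

  ## density census (synthetic scenes; skipped for measured input)
  density <- NULL
  if (config$input == "synth") {
    density <- stage("density", {
      samples <- unique(records$sample_id)
      per_sample <- do.call(rbind, lapply(seq_along(samples), function(k) {
        sid <- samples[k]
        cond <- records$condition[match(sid, records$sample_id)]
        counts <- vapply(seq_len(config$n_bricks_per_sample),
                         function(b) {
          scene <- generate_brick_scene(
            config$density_intensity, config$brick$dims,
            config$brick$origin,
            seed = seed + 100L + 10L * k + b)
          brick_count(scene, config$brick)
        }, numeric(1))
        data.frame(sample_id = sid, condition = cond,
                   n_bricks = config$n_bricks_per_sample,
                   density_per_um3 = spine_density(counts,
                                                   config$brick$volume_um3),
                   stringsAsFactors = FALSE)
      }))
      res <- list(per_sample = per_sample)
      if (both_conditions) {
        res$t_test <- t_test_unpaired(
          per_sample$density_per_um3[per_sample$condition == "control"],
          per_sample$density_per_um3[per_sample$condition == "cltp"])
      }
      res
    })
    say("density: %d samples, brick %g um^3", nrow(density$per_sample),
        config$brick$volume_um3)
  }

  ## local correlation profiles
  pars <- c("psd_area", "psd_core_volume", "psd_area_vs_core")
  need <- max(config$local_corr$window_sizes)
  profiled_conds <- conds[vapply(conds, function(cc) {
    sum(records$condition == cc) >= need
  }, logical(1))]
  for (cc in setdiff(conds, profiled_conds)) {
    say("profiles skipped for '%s': fewer than %d spines", cc, need)
  }
  profiles <- stage("local_correlation", {
    out <- list()
    if (length(profiled_conds)) {
      for (pp in pars) {
        entry <- list()
        for (ci in seq_along(profiled_conds)) {
          cc <- profiled_conds[ci]
          lp <- config$local_corr
          lp$seed <- seed + 200L + 10L * match(pp, pars) + ci
          prof <- local_profile(records[records$condition == cc, ,
                                        drop = FALSE],
                                parameter = pp, params = lp)
          entry[[cc]] <- prof
          entry[[paste0("bands_", cc)]] <- nonsignificant_regions(prof)
        }
        if (length(profiled_conds) == 2L) {
          entry$chi_square <- tryCatch(
            compare_decoupled_counts(entry$control, entry$cltp,
                                     labels = c("control", "cltp")),
            error = function(e) list(note = conditionMessage(e)))
        }
        out[[pp]] <- entry
      }
    }
    out
  })
  for (pp in names(profiles)) {
    for (cc in profiled_conds) {
      b <- profiles[[pp]][[paste0("bands_", cc)]]
      say("profile %s/%s: %d/%d decoupled (%.1f%%)", pp, cc,
          b$n_decoupled, b$n_total, 100 * b$fraction)
    }
  }

  ## group statistics
  group_stats <- stage("group_statistics", {
    gs <- list()
    vars <- c("volume_um3", "psd_area_um2", "psd_core_volume_um3")
    gs$summaries <- lapply(setNames(vars, vars), function(v) {
      lapply(setNames(conds, conds), function(cc) {
        summarize_group(records[[v]][records$condition == cc])
      })
    })
    gs$ratios <- ratio_metrics(records)
    if (both_conditions) {
      ctl <- records$condition == "control"
      gs$mann_whitney <- lapply(setNames(vars, vars), function(v) {
        mann_whitney(records[[v]][ctl], records[[v]][!ctl])
      })
      gs$ancova <- list(
        area_vs_volume = ancova_compare(
          records$volume_um3[ctl], records$psd_area_um2[ctl],
          records$volume_um3[!ctl], records$psd_area_um2[!ctl]),
        core_vs_volume = ancova_compare(
          records$volume_um3[ctl], records$psd_core_volume_um3[ctl],
          records$volume_um3[!ctl], records$psd_core_volume_um3[!ctl]),
        area_vs_core = ancova_compare(
          records$psd_core_volume_um3[ctl], records$psd_area_um2[ctl],
          records$psd_core_volume_um3[!ctl], records$psd_area_um2[!ctl]))
      strata <- factor(
        paste0(records$condition,
               ifelse(records$has_ser, "_ser", "_noser")),
        levels = c("control_noser", "cltp_noser", "control_ser",
                   "cltp_ser"))
      if (!anyNA(strata) && all(table(strata) > 0)) {
        gs$kruskal_dunn <- lapply(setNames(vars, vars), function(v) {
          kruskal_dunn(split(records[[v]], strata))
        })
        gs$relative_change <- lapply(setNames(vars, vars), function(v) {
          relative_change(records, parameter = v)
        })
      }
      gs$spearman <- list(
        area_vs_volume = lapply(setNames(conds, conds), function(cc) {
          sel <- records$condition == cc
          spearman_global(records$volume_um3[sel],
                          records$psd_area_um2[sel])
        }),
        core_vs_volume = lapply(setNames(conds, conds), function(cc) {
          sel <- records$condition == cc
          spearman_global(records$volume_um3[sel],
                          records$psd_core_volume_um3[sel])
        }))
    }
    gs
  })

  ## perforation x SER cross-tabulation
  perforation <- stage("perforation", {
    lapply(setNames(conds, conds), function(cc) {
      sel <- records$condition == cc
      tab <- table(perforated = records$perforated[sel],
                   has_ser = records$has_ser[sel])
      list(table = tab,
           perforated_without_ser = sum(records$perforated[sel] &
                                          !records$has_ser[sel]))
    })
  })

  histogram <- stage("histogram", {
    lapply(setNames(conds, conds), function(cc) {
      volume_histogram(records$volume_um3[records$condition == cc])
    })
  })

  report <- list(records = records, density = density,
                 profiles = profiles, group_stats = group_stats,
                 perforation = perforation, histogram = histogram,
                 seed = seed, config = config, log = log_lines)
  class(report) <- "spine_report"
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.spine_report <- function(x, ...) {
  cat("Spine/PSD coupling report\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

# serialisable summary of the report (profiles exported as CSV separately)
report_summary <- function(report) {
  strip <- function(x) {
    # drop lm objects and other non-serialisable payloads
    if (inherits(x, "lm")) return(NULL)
    if (is.list(x) && !is.data.frame(x)) {
      x <- lapply(x, strip)
      return(x[!vapply(x, is.null, logical(1))])
    }
    if (is.table(x)) return(as.data.frame(x))
    x
  }
  bands <- lapply(report$profiles, function(entry) {
    entry[grep("^bands_|^chi_square$", names(entry))]
  })
  list(seed = report$seed,
       n_records = nrow(report$records),
       n_by_condition = as.list(table(report$records$condition)),
       density = strip(report$density),
       bands = strip(bands),
       group_stats = strip(report$group_stats),
       perforation = strip(report$perforation),
       log = report$log)
}

# write the report bundle: CSV tables + JSON summary + run log
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_records(report$records, file.path(outdir, "records.csv"))
  if (!is.null(report$density)) {
    write.csv(report$density$per_sample,
              file.path(outdir, "density.csv"), row.names = FALSE)
  }
  for (pp in names(report$profiles)) {
    entry <- report$profiles[[pp]]
    for (nm in names(entry)) {
      if (inherits(entry[[nm]], "local_corr_profile")) {
        write.csv(as.data.frame(entry[[nm]]),
                  file.path(outdir, sprintf("profile_%s_%s.csv", pp, nm)),
                  row.names = FALSE)
      }
    }
  }
  for (cc in names(report$histogram)) {
    write.csv(report$histogram[[cc]],
              file.path(outdir, sprintf("volume_histogram_%s.csv", cc)),
              row.names = FALSE)
  }
  jsonlite::write_json(report_summary(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(report$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Validate a report summary against the expected schema
#'
#' Checks the structural contract of the JSON report: required top-level
#' keys and the band-summary layout.  The reference schema ships at
#' `inst/extdata/report-schema.json`.
#'
#' @param summary a list as produced by the report writer (or parsed back
#'   from `report.json`).
#' @return `TRUE` invisibly; errors name what is missing.
#' @export
validate_report_summary <- function(summary) {
  schema_path <- system.file("extdata", "report-schema.json",
                             package = "spinecorr")
  schema <- jsonlite::read_json(schema_path)
  missing <- setdiff(unlist(schema$required), names(summary))
  if (length(missing)) {
    stop("report summary is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
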