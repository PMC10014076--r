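#' Load a run configuration
#'
#' A run configuration is a flat key/value document (YAML) with sections
#' `input` (either `simulate` entries or `events_csv` + `sample_sheet`
#' paths), `transform`, `capacity`, `noise`, `dose_response`,
#' `comparisons`, plus a top-level `seed` and `outdir`.
#'
#' @param path path to a YAML config file.
#' @return the config as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# Stable hash of a config: md5 of its canonical deparse.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = c("keepNA", "keepInteger",
                                         "niceNames", "showAttributes")),
             tmp)
  unname(tools::md5sum(tmp))
}

# Tidy CSV writer: 6 significant digits, fixed column order, LF endings, so
# repeated runs under one seed are byte-identical.
write_tidy_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA_character_,
           formatC(signif(v, 6), format = "g", digits = 6))
  })
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n", na = "NA")
  invisible(path)
}

condition_label <- function(ds) {
  paste0(ds$condition$receptor, "/", ds$condition$ligand)
}

selector_matches <- function(selector, ds) {
  for (field in names(selector)) {
    if (!field %in% c("receptor", "ligand", "replicate")) {
      stop("unknown selector field: ", field)
    }
    if (!identical(as.character(ds$condition[[field]]),
                   as.character(selector[[field]]))) {
      return(FALSE)
    }
  }
  TRUE
}

build_input_datasets <- function(config) {
  input <- config$input
  if (is.null(input)) stop("config error: missing input section")
  datasets <- list()
  if (!is.null(input$simulate)) {
    seed0 <- config$seed
    if (is.null(seed0)) stop("config error: seed required for simulation")
    counter <- 0L
    for (entry in input$simulate) {
      reps <- entry$replicates %||% 1L
      for (r in seq_len(reps)) {
        counter <- counter + 1L
        seed_r <- (as.integer(seed0) + 7919L * counter) %% .Machine$integer.max
        gen <- entry$generator %||% "mixture"
        ds <- if (gen == "mixture") {
          args <- entry[intersect(names(entry),
                                  names(formals(mixture_reporter_config)))]
          args$seed <- seed_r
          if (!is.null(args$doses)) args$doses <- as.numeric(args$doses)
          simulate_mixture_reporter(do.call(mixture_reporter_config, args),
                                    receptor = entry$receptor %||% "synthetic",
                                    ligand = entry$ligand %||% "synthetic",
                                    replicate = r)
        } else if (gen == "known_channel") {
          cfg <- known_channel_config(
            conditional = do.call(rbind, entry$conditional),
            n_cells_per_dose = entry$n_cells_per_dose %||% 5000L,
            output_centers = entry$output_centers %||% NULL,
            output_jitter_sd = entry$output_jitter_sd %||% 0.02,
            seed = seed_r)
          simulate_known_channel(cfg,
                                 receptor = entry$receptor %||% "known_channel",
                                 ligand = entry$ligand %||% "known_channel",
                                 replicate = r)
        } else stop("config error: unknown generator '", gen, "'")
        datasets[[paste0(condition_label(ds), "/rep", r)]] <- ds
      }
    }
  } else if (!is.null(input$events_csv) && !is.null(input$sample_sheet)) {
    sheet <- utils::read.csv(input$sample_sheet, stringsAsFactors = FALSE)
    sheet <- validate_sample_sheet(sheet)
    tables <- list()
    for (sid in unique(sheet$sample_id)) {
      path <- file.path(dirname(input$sample_sheet), sid)
      if (!file.exists(path)) path <- sid
      ch <- unique(sheet$output_channel[sheet$sample_id == sid])
      tables[[sid]] <- if (grepl("\\.fcs$", sid, ignore.case = TRUE)) {
        read_fcs(path)
      } else {
        read_events_csv(path, ch)
      }
    }
    transform <- config$transform %||% list(method = "log10_floor")
    datasets <- assemble_dataset(sheet, tables, transform = transform)
  } else {
    stop("config error: input needs either simulate entries or ",
         "events_csv + sample_sheet")
  }
  datasets
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — build or load dose-indexed datasets,
#' estimate channel capacity per replicate, decompose signal and noise
#' power, fit dose-response curves, and run the configured group
#' comparisons — writing one tidy CSV per stage, a JSON manifest (package
#' version, seed, config hash, outputs) and a plain-text log into the
#' output directory. Re-running with the same config and seed reproduces
#' the CSVs byte for byte. A stage failure aborts the run, names the stage,
#' and leaves a FAILED marker in the manifest alongside any tables already
#' written.
#'
#' @param config a config list (see [read_run_config()]) or a path to a
#'   YAML config file.
#' @param outdir output directory; overrides `config$outdir`.
#' @return (invisibly) a list with `datasets`, `capacity`, `noise`,
#'   `dose_response`, `comparisons` tables and the `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("config error: no output directory")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  manifest <- list(package = "lectincap",
                   version = as.character(utils::packageVersion("lectincap")),
                   seed = config$seed, config_hash = config_hash(config),
                   status = "RUNNING", outputs = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  fail <- function(stage, err) {
    manifest$status <<- "FAILED"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(err)
    write_manifest()
    writeLines(c(log_lines, paste0("FAILED at stage ", stage, ": ",
                                   conditionMessage(err))), log_path)
    stop("stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  datasets <- tryCatch(build_input_datasets(config),
                       error = function(e) fail("input", e))
  say("input: ", length(datasets), " dataset(s)")

  # validate comparison selectors before any compute
  comparisons <- config$comparisons %||% list()
  for (cmp in comparisons) {
    for (side in c("group_a", "group_b")) {
      hits <- Filter(function(d) selector_matches(cmp[[side]], d), datasets)
      if (length(hits) == 0) {
        fail("comparisons",
             simpleError(paste0("config error: selector ", side,
                                " matches no replicate estimate")))
      }
    }
  }

  results <- list(datasets = datasets)
  cap_opts <- config$capacity %||% list()
  cap_enabled <- cap_opts$enabled %||% TRUE
  cap_tab <- NULL
  if (isTRUE(cap_enabled)) {
    cap_tab <- tryCatch({
      rows <- lapply(names(datasets), function(nm) {
        ds <- datasets[[nm]]
        est <- estimate_capacity(
          ds,
          n_bins = cap_opts$bins %||% "auto",
          bias_correction = cap_opts$bias_correction %||% TRUE,
          n_bootstrap = cap_opts$n_bootstrap %||% 0L,
          seed = config$seed %||% 1L,
          min_cells = cap_opts$min_cells %||% 50L)
        data.frame(condition = condition_label(ds),
                   replicate = ds$condition$replicate,
                   n_bins = est$n_bins, bits = est$bits,
                   ci_low = est$ci_low, ci_high = est$ci_high)
      })
      do.call(rbind, rows)
    }, error = function(e) fail("capacity", e))
    write_tidy_csv(cap_tab, file.path(outdir, "capacity.csv"))
    manifest$outputs <- c(manifest$outputs, "capacity.csv")
    say("capacity: ", nrow(cap_tab), " estimate(s)")
    results$capacity <- cap_tab
  }

  noise_enabled <- (config$noise %||% list())$enabled %||% TRUE
  noise_tab <- NULL
  if (isTRUE(noise_enabled)) {
    noise_tab <- tryCatch({
      rows <- lapply(names(datasets), function(nm) {
        ds <- datasets[[nm]]
        d <- decompose(ds)
        data.frame(condition = condition_label(ds),
                   replicate = ds$condition$replicate,
                   signal_power = d$signal_power,
                   noise_power = d$noise_power, snr = d$snr)
      })
      do.call(rbind, rows)
    }, error = function(e) fail("noise", e))
    write_tidy_csv(noise_tab, file.path(outdir, "noise.csv"))
    manifest$outputs <- c(manifest$outputs, "noise.csv")
    say("noise: ", nrow(noise_tab), " decomposition(s)")
    results$noise <- noise_tab
  }

  dr_enabled <- (config$dose_response %||% list())$enabled %||% TRUE
  dr_tab <- NULL
  if (isTRUE(dr_enabled)) {
    dr_tab <- tryCatch({
      rows <- lapply(names(datasets), function(nm) {
        ds <- datasets[[nm]]
        if (length(unique(ds$doses[ds$doses > 0])) < 4L) return(NULL)
        sm <- dose_response_summary(ds)
        fit <- fit_4pl(sm$dose, sm$response)
        data.frame(condition = condition_label(ds),
                   replicate = ds$condition$replicate,
                   bottom = fit$bottom, top = fit$top, ec50 = fit$ec50,
                   hill = fit$hill, rss = fit$rss,
                   converged = fit$converged)
      })
      do.call(rbind, Filter(Negate(is.null), rows))
    }, error = function(e) fail("dose_response", e))
    if (!is.null(dr_tab)) {
      write_tidy_csv(dr_tab, file.path(outdir, "dose_response.csv"))
      manifest$outputs <- c(manifest$outputs, "dose_response.csv")
      say("dose_response: ", nrow(dr_tab), " fit(s)")
    }
    results$dose_response <- dr_tab
  }

  if (length(comparisons) > 0) {
    cmp_tab <- tryCatch({
      rows <- lapply(comparisons, function(cmp) {
        metric <- cmp$metric %||% "capacity_bits"
        pull <- function(selector) {
          hit <- vapply(datasets, function(d) selector_matches(selector, d),
                        logical(1))
          keys <- names(datasets)[hit]
          switch(metric,
            capacity_bits = cap_tab$bits[match(keys, paste0(
              cap_tab$condition, "/rep", cap_tab$replicate))],
            snr = noise_tab$snr[match(keys, paste0(
              noise_tab$condition, "/rep", noise_tab$replicate))],
            ec50 = dr_tab$ec50[match(keys, paste0(
              dr_tab$condition, "/rep", dr_tab$replicate))],
            stop("config error: unknown comparison metric '", metric, "'"))
        }
        va <- pull(cmp$group_a); vb <- pull(cmp$group_b)
        if (anyNA(va) || anyNA(vb)) {
          stop("comparison metric '", metric,
               "' unavailable for a selected replicate")
        }
        test <- cmp$test %||% "wilcoxon"
        res <- if (test == "wilcoxon") {
          w <- wilcoxon_rank_sum(va, vb)
          list(statistic = w$statistic, p = w$p_value,
               name = paste0("wilcoxon_rank_sum_", w$method))
        } else {
          t <- students_t_test(va, vb)
          list(statistic = t$statistic, p = t$p_value, name = "students_t")
        }
        data.frame(metric = metric,
                   group_a = paste(unlist(cmp$group_a), collapse = "/"),
                   group_b = paste(unlist(cmp$group_b), collapse = "/"),
                   n_a = length(va), n_b = length(vb),
                   statistic = res$statistic, p_value = res$p,
                   test = res$name)
      })
      do.call(rbind, rows)
    }, error = function(e) fail("comparisons", e))
    write_tidy_csv(cmp_tab, file.path(outdir, "comparisons.csv"))
    manifest$outputs <- c(manifest$outputs, "comparisons.csv")
    say("comparisons: ", nrow(cmp_tab), " test(s)")
    results$comparisons <- cmp_tab
  }

  manifest$status <- "OK"
  write_manifest()
  writeLines(c(log_lines, "OK"), log_path)
  results$manifest <- manifest
  invisible(results)
}
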