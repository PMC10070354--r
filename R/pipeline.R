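#' Write / read trial events as BIDS-style TSV
#'
#' @param trials Tibble with at least `subject`, `trial`, `onset`,
#'   `valence`, `instruction`, `response`.
#' @param path TSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_events <- function(trials, path) {
  out <- data.frame(
    onset = trials$onset, duration = 22,
    trial_type = paste(trials$valence, trials$instruction, sep = "_"),
    subject = trials$subject, trial = trials$trial,
    response = trials$response,
    response_rank = if ("response_rank" %in% names(trials))
      trials$response_rank else 1L
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  parts <- strsplit(d$trial_type, "_", fixed = TRUE)
  tibble::tibble(
    subject = d$subject, trial = d$trial, onset = d$onset,
    valence = vapply(parts, `[`, character(1), 1),
    instruction = vapply(parts, `[`, character(1), 2),
    response = d$response, response_rank = d$response_rank
  )
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a [synthetic_config()]
#' (simulate mode) or file paths to BOLD/NIfTI, events and subject tables
#' (load mode), plus the filter variants, pFDR and MLR settings. In load
#' mode every referenced file must exist at configuration time; in
#' particular missing events with MLR enabled fail here, before any
#' computation.
#'
#' @param synthetic A [synthetic_config()], or `NULL` in load mode.
#' @param paths `NULL`, or a list with `bold` (named character vector of 4D
#'   NIfTI paths, names = subject ids), `subjects` (CSV with `subject`,
#'   `group`, `hamd`), `events` (TSV from [write_events()]), and optionally
#'   `gm_mask` (3D NIfTI).
#' @param layers Self-layer definitions.
#' @param bands Named list of `c(low, high)` cutoffs; `NA` high = high-pass
#'   only. Defaults to the infra-slow band-pass (0.01-0.1 Hz) and the
#'   high-pass-only control.
#' @param n_discard Initial volumes to discard.
#' @param run_mlr Fit the per-condition multinomial models.
#' @param mlr_k,mlr_repeats Cross-validation folds and repeats.
#' @param tr TR override for load mode (seconds), or `NULL`.
#' @param seed Integer seed for every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), paths = NULL,
                            layers = default_self_layers(),
                            bands = list(bandpass = c(0.01, 0.1),
                                         highpass = c(0.01, NA)),
                            n_discard = 2L, run_mlr = TRUE,
                            mlr_k = 10L, mlr_repeats = 5L,
                            tr = NULL, seed = 1L) {
  if (is.null(synthetic) && is.null(paths))
    stop("either `synthetic` or `paths` must be given")
  if (!is.null(paths)) {
    needed <- c("bold", "subjects")
    if (run_mlr || TRUE) needed <- c(needed, "events")
    missing_entries <- setdiff(needed, names(paths))
    if (length(missing_entries))
      stop("paths must name: ", paste(missing_entries, collapse = ", "))
    files <- c(paths$bold, paths$subjects, paths$events, paths$gm_mask)
    absent <- files[!file.exists(files)]
    if (length(absent))
      stop("configured file(s) not found: ", paste(absent, collapse = ", "))
  }
  structure(list(synthetic = synthetic, paths = paths, layers = layers,
                 bands = bands, n_discard = as.integer(n_discard),
                 run_mlr = isTRUE(run_mlr), mlr_k = as.integer(mlr_k),
                 mlr_repeats = as.integer(mlr_repeats), tr = tr,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a synthetic configuration from a YAML or JSON file
#'
#' Reads a flat mapping of [synthetic_config()] arguments (counts, TR, band
#' edges, loadings, seed, ...) from file; unknown keys are an error so typos
#' fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [synthetic_config()].
#' @export
synthetic_config_from_file <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$layer_loadings))
    vals$layer_loadings <- lapply(vals$layer_loadings, unlist)
  do.call(synthetic_config, vals)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

subject_region_series <- function(bold, layers, n_discard) {
  bold <- discard_initial_volumes(bold, n_discard)
  masks <- assert_disjoint_layers(layers, dim(bold$data)[1:3], bold$affine)
  m <- voxel_matrix(bold)
  series <- vapply(masks, function(msk)
    colMeans(m[as.vector(msk), , drop = FALSE]), numeric(n_volumes(bold)))
  list(gs = extract_global_signal(bold), layers = series)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> GSCORR -> group statistics -> behavioural
#' statistics -> multinomial link for each dataset variant (band-pass and
#' high-pass, each with and without global signal regression — the four
#' datasets of the study design), writing all tables plus a run manifest
#' (package version, seed, configuration hash) to `out_dir`.
#'
#' Because masked averaging, filtering and regression are linear, region
#' series are extracted once and filtered/residualized at the series level;
#' this is numerically identical to filtering every voxel first.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the GSCORR table, per-variant group
#'   statistics, behavioural tests, MLR reports and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$paths)) {
    cohort <- generate_cohort(config$synthetic)
    subjects <- cohort$subjects
    trials <- cohort$trials
    bold_list <- cohort$bold
    tr <- config$synthetic$tr
  } else {
    subjects <- tibble::as_tibble(read.csv(config$paths$subjects,
                                           stringsAsFactors = FALSE))
    trials <- read_events(config$paths$events)
    trials$group <- subjects$group[match(trials$subject, subjects$subject)]
    gm <- NULL
    if (!is.null(config$paths$gm_mask))
      gm <- array(as.numeric(RNifti::readNifti(config$paths$gm_mask)) > 0,
                  dim(RNifti::readNifti(config$paths$gm_mask)))
    bold_list <- lapply(config$paths$bold, load_bold, tr = config$tr,
                        mask = gm)
    names(bold_list) <- names(config$paths$bold)
    tr <- bold_list[[1]]$tr
  }

  extracted <- lapply(bold_list, subject_region_series,
                      layers = config$layers, n_discard = config$n_discard)

  variants <- list()
  for (band_name in names(config$bands)) {
    band <- config$bands[[band_name]]
    spec <- filter_spec(band[1], if (is.na(band[2])) NULL else band[2], tr)
    for (gsr in c(FALSE, TRUE)) {
      vn <- paste0(band_name, if (gsr) "_gsr" else "_gs")
      rows <- lapply(names(extracted), function(id) {
        ex <- extracted[[id]]
        gs_f <- temporal_filter(ex$gs, spec)
        lay_f <- temporal_filter(ex$layers, spec)
        if (gsr)
          lay_f <- apply(lay_f, 2L, nuisance_regress,
                         regressors = matrix(gs_f, ncol = 1))
        g <- lapply(colnames(lay_f), function(nm) {
          gg <- compute_gscorr(lay_f[, nm], gs_f)
          tibble::tibble(subject = id,
                         group = subjects$group[subjects$subject == id],
                         variant = vn, layer = nm, rho = gg$rho, z = gg$z)
        })
        do.call(rbind, g)
      })
      variants[[vn]] <- do.call(rbind, rows)
    }
  }
  gscorr_tab <- do.call(rbind, variants)

  hamd <- setNames(subjects$hamd, subjects$subject)
  group_stats <- lapply(variants, layer_group_comparison, covariate = hamd)
  within_stats <- lapply(variants, function(v)
    rbind(within_group_layer_comparison(v, "mdd"),
          within_group_layer_comparison(v, "ctrl")))

  cleaned <- clean_responses(trials)
  conditions <- unique(paste(cleaned$valence, cleaned$instruction, sep = "_"))
  behavior <- lapply(setNames(conditions, conditions), function(cc) {
    vi <- strsplit(cc, "_", fixed = TRUE)[[1]]
    tab <- contingency_table(cleaned, vi[1], vi[2])
    c(list(table = tab), chi_square_test(tab))
  })

  mlr <- NULL
  if (config$run_mlr) {
    main <- variants[[1]]
    zwide <- do.call(rbind, lapply(split(main, main$subject), function(d)
      tibble::tibble(subject = d$subject[1],
                     interoceptive = d$z[d$layer == "interoceptive"],
                     exteroceptive = d$z[d$layer == "exteroceptive"],
                     mental = d$z[d$layer == "mental"])))
    mlr <- lapply(setNames(conditions, conditions), function(cc) {
      vi <- strsplit(cc, "_", fixed = TRUE)[[1]]
      d <- cleaned[cleaned$valence == vi[1] & cleaned$instruction == vi[2], ]
      idx <- match(d$subject, zwide$subject)
      feats <- cbind(interoceptive = zwide$interoceptive[idx],
                     exteroceptive = zwide$exteroceptive[idx],
                     mental = zwide$mental[idx],
                     group = as.numeric(d$group == "mdd"))
      ref <- if (vi[1] == "negative") "2" else "1"
      out <- tryCatch({
        outcomes <- factor(d$response, levels = sort(unique(d$response)))
        if (!ref %in% levels(outcomes))
          ref <- names(which.max(table(outcomes)))
        cv <- cross_validate(feats, outcomes, ref, k = config$mlr_k,
                             repeats = config$mlr_repeats,
                             seed = config$seed)
        cv$rrr <- relative_risk_ratios(cv$model)
        cv
      }, error = function(e) {
        message("MLR skipped for ", cc, ": ", conditionMessage(e))
        NULL
      })
      out
    })
  }

  hash <- config_hash(config)
  write_tsv <- function(d, name) {
    write.table(as.data.frame(d), file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
    name
  }
  files <- c(
    write_tsv(cbind(gscorr_tab, config_hash = hash), "gscorr.tsv"),
    vapply(names(group_stats), function(vn)
      write_tsv(cbind(group_stats[[vn]], variant = vn, config_hash = hash),
                paste0("group_", vn, ".tsv")), character(1)),
    vapply(names(within_stats), function(vn)
      write_tsv(cbind(within_stats[[vn]], variant = vn, config_hash = hash),
                paste0("within_group_", vn, ".tsv")), character(1)),
    vapply(names(behavior), function(cc) {
      write_tsv(as.data.frame(behavior[[cc]]$table),
                paste0("contingency_", cc, ".tsv"))
      write_tsv(as.data.frame(behavior[[cc]]$std_residuals),
                paste0("std_residuals_", cc, ".tsv"))
    }, character(1))
  )
  if (!is.null(mlr)) {
    for (cc in names(mlr)) {
      if (is.null(mlr[[cc]])) next
      rep_i <- mlr[[cc]]
      jsonlite::write_json(
        list(condition = cc, config_hash = hash,
             coefficients = rep_i$model$coefficients,
             reference = rep_i$model$reference,
             rrr = rep_i$rrr,
             mean_cv_accuracy = rep_i$mean_accuracy,
             whole_data_accuracy = rep_i$whole_data_accuracy,
             no_information_rate = rep_i$no_information_rate,
             binomial_p = rep_i$binomial_p,
             confusion = rep_i$confusion),
        file.path(out_dir, paste0("mlr_", cc, ".json")),
        auto_unbox = TRUE, digits = NA)
      files <- c(files, paste0("mlr_", cc, ".json"))
    }
  }
  manifest <- list(package = "gstopo",
                   version = as.character(utils::packageVersion("gstopo")),
                   seed = config$seed, config_hash = hash,
                   variants = names(variants), outputs = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(gscorr = gscorr_tab, group_stats = group_stats,
                 within_stats = within_stats, behavior = behavior,
                 mlr = mlr, manifest = manifest))
}
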