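#' Compute daily exposure records from gas-log files
#'
#' Workflow entry point wrapping the parsing and aggregation stages:
#' reads every gas-log CSV, aggregates to one record per person-day,
#' optionally joins logbook metadata, and writes `daily_exposure.csv`
#' plus a machine-readable `provenance.json` (inputs, constants,
#' peak-count mode, package version) to the output directory.
#' Deterministic: rerunning on the same inputs reproduces the CSV.
#'
#' @param gaslog_files character vector of gas-log CSV paths.
#' @param out_dir output directory (created if needed).
#' @param logbook optional logbook-day data frame ([logbook_days()]).
#' @param constants an [h2s_constants()] bundle.
#' @param mode peak-count convention.
#' @return the daily-exposure data frame, invisibly.
#' @export
run_index <- function(gaslog_files, out_dir, logbook = NULL,
                      constants = h2s_constants(),
                      mode = c("cumulative", "max_band")) {
  mode <- match.arg(mode)
  if (length(gaslog_files) == 0 || !any(file.exists(gaslog_files)))
    stop("no parsable gas-log input found")
  logs <- unlist(lapply(gaslog_files, parse_gas_log_multi),
                 recursive = FALSE)
  if (length(logs) == 0) stop("no parsable gas-log input found")
  key <- vapply(logs, function(g) {
    ts <- c(g$readings$timestamp, g$alarm_points$timestamp)
    paste(g$person_id, format(min(ts), "%Y-%m-%d"))
  }, "")
  rows <- lapply(split(logs, key), function(gs) {
    pid <- gs[[1]]$person_id
    date <- format(min(c(gs[[1]]$readings$timestamp,
                         gs[[1]]$alarm_points$timestamp)), "%Y-%m-%d")
    meta <- NULL
    if (!is.null(logbook)) {
      hit <- logbook[logbook$person_id == pid &
                       as.character(logbook$date) == date, , drop = FALSE]
      if (nrow(hit)) meta <- hit[1, , drop = FALSE]
    }
    aggregate_person_day(gs, meta = meta, constants = constants, mode = mode)
  })
  daily <- do.call(rbind, rows)
  daily <- daily[order(daily$person_id, daily$date), ]
  rownames(daily) <- NULL

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(daily, file.path(out_dir, "daily_exposure.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, list(
    command = "index", inputs = gaslog_files, mode = mode,
    constants = unclass(constants)))
  invisible(daily)
}

#' Compare study datasets: summary table, histograms, index-TWA export
#'
#' Side-by-side descriptive comparison of two or more study datasets:
#' one summary row per dataset ([summarize_dataset()]), the binned
#' distribution of daily maxima above the common 1.6-ppm floor
#' ([histogram_bins()]) as counts and as fractions of detects, and the
#' index-versus-TWA table with log-log fits per ceiling-exceedance
#' stratum. All outputs are written as CSV; plots, when `ggplot2` is
#' available and `plots = TRUE`, are best-effort renderings of the
#' same CSVs.
#'
#' @param datasets named list of [study_dataset()] objects.
#' @param out_dir output directory.
#' @param plots also render PDF figures (needs `ggplot2`).
#' @return list with `summary`, `histograms`, `index_twa`, invisibly.
#' @export
run_compare <- function(datasets, out_dir, plots = FALSE) {
  stopifnot(length(datasets) >= 2,
            all(vapply(datasets, inherits, TRUE, "study_dataset")))
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, `[[`, "", "label")

  summary <- do.call(rbind, lapply(datasets, summarize_dataset))
  rownames(summary) <- NULL

  hists <- do.call(rbind, lapply(names(datasets), function(nm) {
    m <- datasets[[nm]]$days
    m <- m[m$status == "measured", , drop = FALSE]
    h <- histogram_bins(m$max_ppm[!is.na(m$max_ppm)])
    n_binned <- sum(h$counts) + h$overload
    data.frame(dataset = nm,
               bin = c(h$labels, ">100"),
               count = c(h$counts, h$overload),
               fraction_of_detects = if (n_binned > 0)
                 c(h$counts, h$overload) / n_binned else NA_real_)
  }))

  it <- do.call(rbind, lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    if (!"index_model" %in% names(ds$days)) ds <- impute_censored(ds)
    m <- ds$days[ds$days$status == "measured", , drop = FALSE]
    res <- index_twa_table(m)
    cbind(dataset = nm, res$table)
  }))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(hists, file.path(out_dir, "histograms.csv"), row.names = FALSE)
  utils::write.csv(it, file.path(out_dir, "index_twa.csv"), row.names = FALSE)
  write_provenance(out_dir, list(command = "compare",
                                 datasets = names(datasets)))
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(hists[hists$count > 0, ],
                          ggplot2::aes(x = bin, y = fraction_of_detects,
                                       group = dataset, colour = dataset)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "daily maximum H2S (ppm)", y = "fraction of detects") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
    ggplot2::ggsave(file.path(out_dir, "histograms.pdf"), gg,
                    width = 8, height = 5)
  }
  invisible(list(summary = summary, histograms = hists, index_twa = it))
}

#' Fit and report the variance-components model for one dataset
#'
#' Imputes censored days, fits the mixed model (fixed: similar-exposure
#' group and season; random: worker), writes the coefficient and
#' variance-component tables, predicted cell means with 95% CIs for
#' every observed group-by-season cell, and (optionally) the split-half
#' robustness check with per-half fits.
#'
#' @param dataset a [study_dataset()].
#' @param out_dir output directory.
#' @param fixed fixed-effect factors (default `c("seg", "season")`).
#' @param split run the split-half robustness procedure.
#' @param seed integer seed (mandatory when `split = TRUE`).
#' @param mode peak-count convention for imputation.
#' @return list with `fit`, `cells`, and (if requested) `split`,
#'   `fit_half1`, `fit_half2`, invisibly.
#' @export
run_model <- function(dataset, out_dir, fixed = c("seg", "season"),
                      split = FALSE, seed = NULL,
                      mode = c("cumulative", "max_band")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "study_dataset"))
  ds <- impute_censored(dataset, mode = mode)
  fit <- fit_varcomp(ds, fixed = fixed)

  frame <- ds$days[ds$days$in_model, , drop = FALSE]
  if (length(fixed)) {
    cells <- unique(frame[, fixed, drop = FALSE])
    cell_rows <- lapply(seq_len(nrow(cells)), function(i)
      predict_cell_mean(fit, as.list(lapply(cells[i, , drop = FALSE],
                                            as.character))))
    cells_out <- do.call(rbind, cell_rows)
  } else {
    cells_out <- predict_cell_mean(fit)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$fixed_effects, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(component = c("between_person", "within_person"),
               variance = c(fit$var_between_person, fit$var_within_person),
               fraction = c(1 - fit$within_fraction, fit$within_fraction)),
    file.path(out_dir, "varcomp.csv"), row.names = FALSE)
  utils::write.csv(cells_out, file.path(out_dir, "cell_means.csv"),
                   row.names = FALSE)

  out <- list(fit = fit, cells = cells_out)
  if (split) {
    if (is.null(seed)) stop("the split-half procedure is random: give a seed")
    sp <- robustness_split(ds, seed = seed)
    d <- ds$days
    keep <- d$status == "measured" & !d$censored
    if ("has_logbook" %in% names(d)) keep <- keep & d$has_logbook
    d <- d[keep, , drop = FALSE]
    for (f in fixed) if (is.factor(d[[f]])) d[[f]] <- droplevels(d[[f]])
    out$split <- sp
    out$fit_half1 <- fit_varcomp(droplevels(d[sp$part1, , drop = FALSE]),
                                 fixed = fixed)
    out$fit_half2 <- fit_varcomp(droplevels(d[sp$part2, , drop = FALSE]),
                                 fixed = fixed)
  }
  write_provenance(out_dir, list(
    command = "model", dataset = dataset$label, fixed = fixed,
    mode = mode, seed = seed,
    imputation_constant = attr(ds, "imputation_constant"),
    neg2_loglik = fit$neg2_loglik))
  invisible(out)
}

#' Write a provenance record for an output directory
#'
#' Every workflow output directory carries `provenance.json`: the
#' command, its configuration, any seed, and the package version, so
#' results can be traced and reruns verified.
#'
#' @param out_dir output directory.
#' @param info named list of command-specific fields.
#' @return the file path, invisibly.
#' @export
write_provenance <- function(out_dir, info) {
  info$package <- "h2sindex"
  info$version <- as.character(utils::packageVersion("h2sindex"))
  info$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(info, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
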