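# Plain-text interchange: long-format TAC CSV, ground-truth/config JSON and
# deterministic result files.

SCHEMA_VERSION <- "1"

#' Write time-activity curves to CSV
#'
#' Long format with header `time_min, series, value`; tissue series are
#' named after their regions, whole blood is `CWB` and blood-mixed traces
#' `CPET:<region>`.
#'
#' @param path output file.
#' @param schedule a [measurement_schedule()].
#' @param ct_matrix n x T tissue matrix with region rownames.
#' @param cwb optional whole-blood samples at `schedule$s`.
#' @param cpet_matrix optional n x T blood-mixed matrix.
#' @return the path, invisibly.
#' @export
write_tac_csv <- function(path, schedule, ct_matrix, cwb = NULL,
                          cpet_matrix = NULL) {
  regions <- rownames(ct_matrix) %||% paste0("region", seq_len(nrow(ct_matrix)))
  rows <- do.call(rbind, lapply(seq_len(nrow(ct_matrix)), function(i) {
    data.frame(time_min = schedule$t, series = regions[i],
               value = ct_matrix[i, ], stringsAsFactors = FALSE)
  }))
  if (!is.null(cwb)) {
    rows <- rbind(rows, data.frame(time_min = schedule$s, series = "CWB",
                                   value = cwb, stringsAsFactors = FALSE))
  }
  if (!is.null(cpet_matrix)) {
    rows <- rbind(rows, do.call(rbind, lapply(seq_len(nrow(cpet_matrix)),
      function(i) {
        data.frame(time_min = schedule$t,
                   series = paste0("CPET:", regions[i]),
                   value = cpet_matrix[i, ], stringsAsFactors = FALSE)
      })))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read time-activity curves from CSV
#'
#' Parses the long TAC format of [write_tac_csv()]. Times are sorted (with a
#' warning when the file was unsorted); duplicate `(time, series)` rows and
#' non-numeric values are rejected with the offending row named.
#'
#' @param path CSV file with header `time_min, series, value`.
#' @param require_cwb error when no `CWB` series is present (needed by the
#'   full estimation modes).
#' @return list with `schedule`, `ct_matrix` (region rows), `regions`,
#'   `cwb` (or `NULL`) and `cpet_matrix` (or `NULL`).
#' @export
read_tac_csv <- function(path, require_cwb = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "series", "value") %in% names(df))) {
    stop("TAC CSV must have columns time_min, series, value", call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))) |
                 !is.finite(suppressWarnings(as.numeric(df$time_min))))
  if (length(bad) > 0) {
    stop(sprintf("non-numeric value in TAC CSV at data row %d", bad[1]),
         call. = FALSE)
  }
  df$value <- as.numeric(df$value)
  df$time_min <- as.numeric(df$time_min)
  dup <- duplicated(df[, c("time_min", "series")])
  if (any(dup)) {
    stop(sprintf("duplicate (time, series) pair at data row %d", which(dup)[1]),
         call. = FALSE)
  }
  if (is.unsorted(df$time_min[df$series == df$series[1]])) {
    warning("TAC CSV times were unsorted; sorting", call. = FALSE)
  }
  series <- unique(df$series)  # keep the file's series order
  df <- df[order(match(df$series, series), df$time_min), ]
  tissue <- setdiff(series[!startsWith(series, "CPET:")], "CWB")
  if (length(tissue) == 0) stop("no tissue series in TAC CSV", call. = FALSE)
  t <- sort(unique(df$time_min[df$series == tissue[1]]))
  ct <- t(vapply(tissue, function(r) {
    sub <- df[df$series == r, ]
    if (!identical(sub$time_min, t)) {
      stop(sprintf("series '%s' is not on the common time grid", r),
           call. = FALSE)
    }
    sub$value
  }, numeric(length(t))))
  rownames(ct) <- tissue
  cwb <- NULL; s <- t
  if ("CWB" %in% series) {
    sub <- df[df$series == "CWB", ]
    s <- sub$time_min
    cwb <- sub$value
  } else if (require_cwb) {
    stop("TAC CSV has no CWB series (required in full mode)", call. = FALSE)
  }
  cpet_names <- series[startsWith(series, "CPET:")]
  cpet <- NULL
  if (length(cpet_names) > 0) {
    cpet <- t(vapply(cpet_names, function(r) {
      df$value[df$series == r]
    }, numeric(length(t))))
    rownames(cpet) <- sub("^CPET:", "", cpet_names)
  }
  list(schedule = measurement_schedule(t, s), ct_matrix = ct,
       regions = tissue, cwb = cwb, cpet_matrix = cpet)
}

params_to_list <- function(pv) {
  list(lambdas = pv$polyexp$lambdas, mus = pv$polyexp$mus,
       fraction = list(A = pv$fraction$A, xi1 = pv$fraction$xi1,
                       xi2 = pv$fraction$xi2),
       regions = lapply(pv$regions, function(r) {
         list(K1 = r$K1, k2 = r$k2, k3 = r$k3)
       }))
}

params_from_list <- function(x) {
  regions <- lapply(x$regions, function(r) {
    structure(list(K1 = r$K1, k2 = r$k2, k3 = r$k3),
              class = "petkin_kinetics")
  })
  param_vector(polyexp(unlist(x$lambdas), unlist(x$mus)),
               plasma_fraction(x$fraction$A, x$fraction$xi1, x$fraction$xi2),
               regions)
}

#' Write a ground-truth/parameter JSON document
#'
#' @param pv a [param_vector()].
#' @param path output file.
#' @param vb fractional blood volume to record.
#' @param schedule optional [measurement_schedule()] to record.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(pv, path, vb = NULL, schedule = NULL) {
  doc <- c(list(schema_version = SCHEMA_VERSION), params_to_list(pv))
  if (!is.null(vb)) doc$vb <- vb
  if (!is.null(schedule)) doc$schedule <- list(t = schedule$t, s = schedule$s)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth/parameter JSON document
#'
#' @param path JSON file written by [write_truth_json()].
#' @return list with `params` (a [param_vector()]), `vb` and `schedule`
#'   (either may be `NULL`).
#' @export
read_truth_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sched <- if (!is.null(doc$schedule)) {
    measurement_schedule(doc$schedule$t, doc$schedule$s)
  }
  list(params = params_from_list(doc), vb = doc$vb, schedule = sched)
}

#' Write fit or experiment results to a directory
#'
#' JSON with a schema version plus, for experiments, Table-style CSV
#' summaries (one row per region and kinetic parameter, plus a divergence
#' count file). Field ordering is deterministic, so re-running an identical
#' configuration and seed reproduces the files byte for byte.
#'
#' @param result a `petkin_fit` or `petkin_experiment`.
#' @param dir output directory (created if needed).
#' @param thin keep every `thin`-th iterate in fit JSON output (1 = all).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(result, dir, thin = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (inherits(result, "petkin_fit")) {
    keep <- unique(c(seq(1, length(result$iterates), by = thin),
                     length(result$iterates)))
    doc <- list(schema_version = SCHEMA_VERSION,
                stopped_by = result$stopped_by,
                stop_iteration = result$stop_iteration,
                residual_norms = result$residual_norms,
                final = params_to_list(result$params),
                iterates = lapply(result$iterates[keep], as.numeric),
                iterate_index = keep - 1)
    f <- file.path(dir, "fit.json")
    jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    written <- c(written, f)
  } else if (inherits(result, "petkin_experiment")) {
    doc <- list(schema_version = SCHEMA_VERSION, setup = result$setup,
                count = result$setting$name, delta_y = result$setting$delta_y,
                delta_x = result$delta_x, n_reps = result$n_reps,
                master_seed = result$master_seed,
                n_divergent = result$n_divergent,
                median_representative = result$median_representative,
                rho_opt = vapply(result$replicates, `[[`, 0, "rho_opt"),
                rho_d = vapply(result$replicates, function(x) {
                  if (is.na(x$rho_d)) NA_real_ else x$rho_d
                }, 0))
    f <- file.path(dir, "experiment.json")
    jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    written <- c(written, f)
    if (!is.null(result$summary)) {
      f <- file.path(dir, "summary.csv")
      utils::write.csv(result$summary, f, row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }
    f <- file.path(dir, "divergence.csv")
    utils::write.csv(data.frame(setup = result$setup,
                                count = result$setting$name,
                                delta_x = result$delta_x,
                                n_divergent = result$n_divergent,
                                n_reps = result$n_reps),
                     f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    errs <- lapply(result$replicates, `[[`, "relative_errors")
    len <- max(vapply(errs, length, 0L))
    mat <- vapply(errs, function(e) c(e, rep(NA_real_, len - length(e))),
                  numeric(len))
    f <- file.path(dir, "relative_errors.csv")
    utils::write.csv(data.frame(iteration = seq_len(len) - 1, mat),
                     f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  invisible(written)
}
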