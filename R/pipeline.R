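#' Configuration for an end-to-end pipeline run
#'
#' Exactly one coarse-mask source must be configured: `coarse_masks` (a list
#' of [binary_mask()]s / `NULL`s aligned with the slices, e.g. read from a
#' detector's output directory), `corruption` (a [corruption_spec()] applied
#' to each slice's ground truth, emulating a detector on phantom data), or
#' `coarse_fn` (a plugin `function(slice, gt)` returning a `binary_mask` or
#' `NULL`).
#'
#' @param slices list of [ct_slice()]s (nonempty).
#' @param gt_masks optional list aligned with `slices`: ground-truth
#'   [binary_mask()] or `NULL` per slice (`NULL` = no lung / no truth).
#' @param gate a trained [train_gate()] object, or `NULL` with
#'   `skip_classify = TRUE` to bypass phase 1.
#' @param skip_classify bypass the gate and treat every slice as lung.
#' @param coarse_masks,corruption,coarse_fn the coarse-mask source (exactly
#'   one non-`NULL`).
#' @param parzen a [parzen_config()].
#' @param output_dir optional directory for refined masks (PNG) and the JSON
#'   run report.
#' @param seed run seed (propagated into the refinement subsampling).
#' @return an object of class `run_config`.
#' @export
run_config <- function(slices, gt_masks = NULL, gate = NULL,
                       skip_classify = FALSE, coarse_masks = NULL,
                       corruption = NULL, coarse_fn = NULL,
                       parzen = parzen_config(), output_dir = NULL,
                       seed = 0L) {
  if (length(slices) == 0) stop("empty input set", call. = FALSE)
  sources <- c(!is.null(coarse_masks), !is.null(corruption), !is.null(coarse_fn))
  if (sum(sources) != 1L)
    stop("exactly one coarse-mask source must be configured", call. = FALSE)
  if (!skip_classify && is.null(gate))
    stop("either supply a trained gate or set skip_classify = TRUE",
         call. = FALSE)
  structure(list(slices = slices, gt_masks = gt_masks, gate = gate,
                 skip_classify = isTRUE(skip_classify),
                 coarse_masks = coarse_masks, corruption = corruption,
                 coarse_fn = coarse_fn, parzen = parzen,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

.coarse_for_slice <- function(config, i, slice, gt) {
  if (!is.null(config$coarse_masks)) return(config$coarse_masks[[i]])
  if (!is.null(config$corruption)) {
    if (is.null(gt)) return(NULL)
    return(corrupt_mask(gt, config$corruption))
  }
  config$coarse_fn(slice, gt)
}

#' Run the two-phase pipeline over a set of slices
#'
#' Phase 1: unless `skip_classify`, each slice is classified by the gate and
#' non-lung slices short-circuit with `skipped = TRUE` (no mask is emitted;
#' when ground truth exists the slice is scored against an empty prediction,
#' so fabricated detections on non-lung slices are what gating protects
#' against). Phase 2: lung slices get a coarse mask from the configured
#' source and are refined by [refine_boundary()]; metrics are computed where
#' ground truth exists. Per-slice failures (e.g. a missing coarse mask) are
#' recorded in the slice report, and the run continues.
#'
#' With a fixed seed the whole run, including the JSON report, is
#' reproducible bit for bit.
#'
#' @param config a [run_config()].
#' @return an object of class `pipeline_report`: list with `slices` (one
#'   report per slice), `aggregate` (mean +/- sd metric table over scored
#'   slices) and `n_failed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pz <- config$parzen
  pz$seed <- derive_seed(config$seed, 13L)
  reports <- vector("list", length(config$slices))
  metric_rows <- list()

  for (i in seq_along(config$slices)) {
    slice <- config$slices[[i]]
    gt <- if (!is.null(config$gt_masks)) config$gt_masks[[i]] else NULL
    rep_i <- list(source_id = slice$source_id, index = i,
                  lung_detected = NA, skipped = FALSE, error = NULL,
                  iterations_run = NA_integer_, converged = NA,
                  mask_path = NA_character_, metrics = NULL)

    detected <- if (config$skip_classify) TRUE
                else predict_gate(config$gate, slice) == "lung"
    rep_i$lung_detected <- detected

    if (!detected) {
      rep_i$skipped <- TRUE
      if (!is.null(gt) || !is.null(config$gt_masks)) {
        # score the (empty) non-emission against truth when truth is known
        empty <- binary_mask(matrix(0L, slice$height, slice$width))
        gtm <- gt %||% empty
        rep_i$metrics <- suppressWarnings(segmentation_metrics(empty, gtm))
      }
    } else {
      res <- tryCatch({
        coarse <- .coarse_for_slice(config, i, slice, gt)
        if (is.null(coarse))
          stop("no coarse mask available for detected-lung slice ", i,
               call. = FALSE)
        norm <- normalize_intensity(slice, "minmax")
        refine_boundary(norm, coarse, pz)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rep_i$error <- conditionMessage(res)
      } else {
        rep_i$iterations_run <- res$iterations_run
        rep_i$converged <- res$converged
        if (!is.null(out_dir)) {
          mp <- file.path(out_dir, sprintf("mask_%03d.png", i))
          write_mask(res$mask, mp)
          rep_i$mask_path <- mp
        }
        if (!is.null(gt))
          rep_i$metrics <- suppressWarnings(segmentation_metrics(res$mask, gt))
        else if (!is.null(config$gt_masks)) {
          empty <- binary_mask(matrix(0L, slice$height, slice$width))
          rep_i$metrics <- suppressWarnings(segmentation_metrics(res$mask, empty))
        }
      }
    }
    if (!is.null(rep_i$metrics)) metric_rows[[length(metric_rows) + 1L]] <- rep_i$metrics
    reports[[i]] <- rep_i
  }

  agg <- if (length(metric_rows) > 0)
    aggregate_metrics(do.call(rbind, metric_rows)) else NULL
  n_failed <- sum(vapply(reports, function(r) !is.null(r$error), logical(1)))

  report <- structure(list(slices = reports, aggregate = agg,
                           n_failed = n_failed, seed = config$seed),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    json <- jsonlite::toJSON(.report_as_list(report), auto_unbox = TRUE,
                             digits = NA, null = "null", pretty = TRUE)
    writeLines(json, file.path(out_dir, "run_report.json"))
  }
  report
}

.report_as_list <- function(report) {
  list(schema = "pulmoseg-run-report/1", seed = report$seed,
       n_failed = report$n_failed,
       aggregate = report$aggregate,
       slices = lapply(report$slices, function(r) {
         r$metrics <- if (!is.null(r$metrics)) as.list(r$metrics) else NULL
         r
       }))
}

#' @export
print.pipeline_report <- function(x, ...) {
  n <- length(x$slices)
  nskip <- sum(vapply(x$slices, function(r) isTRUE(r$skipped), logical(1)))
  cat(sprintf("<pipeline_report> %d slice(s): %d segmented, %d skipped, %d failed\n",
              n, n - nskip - x$n_failed, nskip, x$n_failed))
  if (!is.null(x$aggregate)) {
    cat("aggregate metrics (mean \u00b1 sd):\n")
    for (i in seq_len(nrow(x$aggregate)))
      cat(sprintf("  %-8s %s\n", x$aggregate$metric[i], x$aggregate$report[i]))
  }
  invisible(x)
}
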