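# End-to-end experiment orchestration: simulate (or load) casts, split,
# train both stages, predict on the held-out test split, and evaluate.

#' Run a full simulate-train-evaluate experiment
#'
#' Generates `n_casts` synthetic maxillary casts, fits the two-stage model
#' on the train/validation splits, predicts the 12 landmarks on the test
#' split (both the full pipeline and, for comparison, the coarse cluster
#' centroids alone), and reports the evaluation statistics. With `out_dir`
#' set, writes the report CSVs, per-cast predictions (.pp + JSON), training
#' histories, and a run log with seed and config, enough to reproduce the
#' run.
#'
#' @param n_casts number of synthetic casts to simulate.
#' @param config a [pm_config()].
#' @param seed root seed for simulation, split, and training.
#' @param out_dir optional output directory.
#' @param base_params [cast_shape_params()] for the simulator.
#' @param verbose print per-epoch losses.
#' @return List: `model` (the fitted `palatemark`), `report`
#'   (`evaluation_report`, full pipeline), `coarse_report` (coarse-only),
#'   `axis` (per-axis MAE), `errors` (test matrix, mm), `predictions`,
#'   `truths`.
#' @export
run_experiment <- function(n_casts = 60, config = pm_config(), seed = 0L,
                           out_dir = NULL,
                           base_params = cast_shape_params(),
                           verbose = FALSE) {
  casts <- generate_dataset(n_casts, base_params, seed = seed + 7L)
  model <- fit_palatemark(casts, config, seed = seed, verbose = verbose)
  test_casts <- casts[model$split$test]
  preds <- lapply(test_casts, function(c) predict(model, c$mesh))
  coarse_preds <- lapply(test_casts, function(c)
    predict(model, c$mesh, stage = "coarse"))
  truths <- lapply(test_casts, function(c) c$landmarks)
  errs <- t(mapply(euclidean_errors, preds, truths))
  coarse_errs <- t(mapply(euclidean_errors, coarse_preds, truths))
  ids <- vapply(test_casts, function(c) c$mesh$cast_id, "")
  report <- summarize_errors(errs, config$sdr_thresholds, cast_ids = ids)
  coarse_report <- summarize_errors(coarse_errs, config$sdr_thresholds,
                                    cast_ids = ids)
  ax <- axis_mae(preds, truths)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_csv(report, file.path(out_dir, "report.csv"))
    write_report_csv(coarse_report, file.path(out_dir, "report_coarse.csv"))
    utils::write.csv(data.frame(axis = ax$axis,
                                mae = sprintf("%.6f", ax$mae),
                                sd = sprintf("%.6f", ax$sd)),
                     file.path(out_dir, "axis_mae.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(model$coarse_net$history,
                     file.path(out_dir, "history_coarse.csv"),
                     row.names = FALSE)
    utils::write.csv(model$refine_net$history,
                     file.path(out_dir, "history_refine.csv"),
                     row.names = FALSE)
    for (i in seq_along(preds)) {
      write_pickpoints(preds[[i]],
                       file.path(out_dir, paste0(ids[i], "_pred.pp")))
      write_landmarks_json(preds[[i]],
                           file.path(out_dir, paste0(ids[i], "_pred.json")),
                           cast_id = ids[i])
    }
    writeLines(c(sprintf("palatemark %s",
                         as.character(utils::packageVersion("palatemark"))),
                 sprintf("seed: %d", seed),
                 sprintf("n_casts: %d", n_casts),
                 sprintf("profile: %s", config$profile),
                 sprintf("n_points: %d", config$n_points),
                 sprintf("epochs: %d + %d", config$coarse_epochs,
                         config$refine_epochs)),
               file.path(out_dir, "run_log.txt"))
  }
  list(model = model, report = report, coarse_report = coarse_report,
       axis = ax, errors = errs, coarse_errors = coarse_errs,
       predictions = preds, truths = truths)
}
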