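# Accuracy and reliability statistics: per-landmark Euclidean errors,
# per-axis MAE, success detection rates, pooled summary reports, repeat
# annotation distances, and the intraclass correlation coefficient. Errors
# are always computed in cast-frame millimetres.

#' Per-landmark Euclidean errors between prediction and ground truth
#'
#' Label-aligned (16 with 16, etc.), never nearest-match. Both sets must be
#' in the cast-frame (mm).
#'
#' @param pred,truth [landmark_set()] objects in the `cast_mm` frame.
#' @return Named numeric vector of 12 distances (mm).
#' @export
euclidean_errors <- function(pred, truth) {
  stopifnot(inherits(pred, "landmark_set"), inherits(truth, "landmark_set"))
  if (pred$frame != "cast_mm" || truth$frame != "cast_mm")
    stop("errors are computed in cast-frame mm; got normalized-frame input",
         call. = FALSE)
  if (!identical(pred$labels, truth$labels))
    stop("pairing error: label mismatch", call. = FALSE)
  d <- sqrt(rowSums((pred$points - truth$points)^2))
  names(d) <- pred$labels
  d
}

#' Per-axis mean absolute localization error
#'
#' Pools |dx|, |dy|, |dz| over all casts and landmarks and reports mean and
#' SD per axis.
#'
#' @param preds,truths lists of paired [landmark_set()] objects.
#' @return data.frame with `axis`, `mae`, `sd` (mm).
#' @export
axis_mae <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  devs <- do.call(rbind, Map(function(p, t) {
    euclidean_errors(p, t)   # validates frames + labels
    abs(p$points - t$points)
  }, preds, truths))
  data.frame(axis = c("x", "y", "z"),
             mae = colMeans(devs),
             sd = apply(devs, 2, stats::sd))
}

#' Success detection rate at distance thresholds
#'
#' Percentage of errors within each threshold, inclusive comparison
#' (error <= t). Default thresholds 0.5, 1, 1.5, 2 mm.
#'
#' @param errors numeric vector of errors (mm).
#' @param thresholds positive ascending thresholds (mm).
#' @return Named numeric vector of percentages in [0, 100].
#' @export
sdr <- function(errors, thresholds = c(0.5, 1, 1.5, 2)) {
  if (!length(errors)) stop("undefined statistic: no errors given",
                            call. = FALSE)
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  out <- vapply(thresholds, function(t) 100 * mean(errors <= t), 1)
  names(out) <- paste0("sdr", thresholds)
  out
}

#' Summarize per-cast per-landmark errors into an evaluation report
#'
#' One row per landmark (mean, SD, SDR at each threshold) plus a pooled
#' overall row; outliers are flagged at error > mean + 3 SD within each
#' landmark (an 1.5 IQR boxplot rule is available via `outlier_rule`).
#'
#' @param errors n_casts x 12 matrix of errors (mm), columns in FDI order;
#'   a vector is treated as one cast.
#' @param thresholds SDR thresholds (mm).
#' @param cast_ids optional identifiers for the outlier list.
#' @param outlier_rule `"mean3sd"` or `"iqr"`.
#' @return An `evaluation_report`: `table` (13 rows), `axis` slot unset,
#'   `outliers`, `n_casts`.
#' @export
summarize_errors <- function(errors, thresholds = c(0.5, 1, 1.5, 2),
                             cast_ids = NULL,
                             outlier_rule = c("mean3sd", "iqr")) {
  outlier_rule <- match.arg(outlier_rule)
  if (is.null(dim(errors))) errors <- matrix(errors, nrow = 1)
  stopifnot(ncol(errors) == 12, nrow(errors) >= 1)
  if (is.null(cast_ids)) cast_ids <- sprintf("cast%03d", seq_len(nrow(errors)))
  rows <- lapply(1:12, function(k) {
    e <- errors[, k]
    c(mean = mean(e), sd = if (length(e) > 1) stats::sd(e) else 0, sdr(e, thresholds))
  })
  flat <- as.vector(errors)
  overall <- c(mean = mean(flat), sd = if (length(flat) > 1) stats::sd(flat) else 0,
               sdr(flat, thresholds))
  tab <- as.data.frame(do.call(rbind, c(rows, list(overall))))
  tab <- cbind(landmark = c(FDI_LABELS, "Overall"), tab)
  rownames(tab) <- NULL
  out_list <- do.call(rbind, lapply(1:12, function(k) {
    e <- errors[, k]
    lim <- if (outlier_rule == "mean3sd") mean(e) + 3 * stats::sd(e)
    else stats::quantile(e, 0.75, names = FALSE) + 1.5 * stats::IQR(e)
    hit <- which(e > lim & is.finite(lim))
    if (!length(hit)) return(NULL)
    data.frame(cast_id = cast_ids[hit], landmark = FDI_LABELS[k],
               error = e[hit])
  }))
  structure(list(table = tab, outliers = out_list, n_casts = nrow(errors),
                 thresholds = thresholds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Landmark localization over %d casts (mm):\n", x$n_casts))
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$outliers))
    cat(sprintf("%d outlier observations (error > mean + 3 SD)\n",
                nrow(x$outliers)))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' Columns: landmark, mean, sd, then one SDR column per threshold. Numeric
#' cells are fixed-format (`%.6f`) so identical runs are byte-identical.
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  tab <- report$table
  out <- data.frame(landmark = tab$landmark,
                    lapply(tab[, -1, drop = FALSE],
                           function(col) sprintf("%.6f", col)),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Distances between two repeat annotation sessions
#'
#' Label-aligned per-landmark distances, e.g. between two manual annotation
#' passes, used for intraexaminer repeatability.
#'
#' @param rep1,rep2 [landmark_set()] objects (`cast_mm`).
#' @return Named numeric vector of 12 distances (mm).
#' @export
repeat_distances <- function(rep1, rep2) euclidean_errors(rep1, rep2)

#' Intraclass correlation coefficient ICC(A,1)
#'
#' Two-way absolute-agreement single-measures ICC from the session x subject
#' mean squares: `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with
#' `MSR` the between-subjects, `MSC` the between-sessions, and `MSE` the
#' residual mean square. A consistency form ICC(C,1),
#' `(MSR - MSE) / (MSR + (k-1) MSE)`, is available via `type`.
#'
#' @param session1,session2 numeric vectors: one measurement per subject and
#'   session (n subjects, 2 sessions).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return Scalar ICC (<= 1).
#' @export
icc <- function(session1, session2, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(length(session1) == length(session2))
  n <- length(session1)
  if (n < 3) stop("need at least 3 subjects per ICC cell", call. = FALSE)
  x <- cbind(session1, session2)
  k <- 2
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-24)
    stop("undefined statistic: zero total variance", call. = FALSE)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Coordinate-wise ICC between two landmark annotation sessions
#'
#' Computes [icc()] for each coordinate axis of each landmark across casts.
#'
#' @param sessions1,sessions2 lists of [landmark_set()] objects (one per
#'   cast, paired).
#' @param type passed to [icc()].
#' @return 12 x 3 matrix of ICC values (rows FDI labels, columns x/y/z).
#' @export
icc_landmarks <- function(sessions1, sessions2, type = "agreement") {
  stopifnot(length(sessions1) == length(sessions2), length(sessions1) >= 3)
  out <- matrix(NA_real_, 12, 3,
                dimnames = list(FDI_LABELS, c("x", "y", "z")))
  for (k in 1:12) for (a in 1:3) {
    s1 <- vapply(sessions1, function(s) s$points[k, a], 1)
    s2 <- vapply(sessions2, function(s) s$points[k, a], 1)
    out[k, a] <- icc(s1, s2, type = type)
  }
  out
}
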