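#' Normalised root-mean-square error between two series
#'
#' `NRMSE = sqrt(mean((p - o)^2)) / (max(o) - min(o))`: the RMSE of the
#' predicted series against the observed one, normalised by the observed
#' range.  Values below the 30% acceptance threshold flag an acceptable
#' match.  The statistic is invariant to scaling both series by a positive
#' constant and to adding a common constant.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @param accept_threshold acceptance threshold as a fraction (default 0.30).
#' @return object of class `nrmse_result`: list with `nrmse` (fraction),
#'   `percent`, `accepted`, `n`, `observed_range`.
#' @export
#' @examples
#' nrmse(c(0, 1, 2), c(1, 1, 1))$percent   # 40.82
nrmse <- function(observed, predicted, accept_threshold = 0.30) {
  if (length(observed) != length(predicted))
    stop("nrmse: series must have equal length")
  if (length(observed) < 2) stop("nrmse: need at least 2 observations")
  r <- max(observed) - min(observed)
  if (r <= 0) stop("nrmse: observed range is zero; normalisation undefined")
  v <- sqrt(mean((predicted - observed)^2)) / r
  structure(list(nrmse = v, percent = 100 * v,
                 accepted = v < accept_threshold,
                 n = length(observed), observed_range = r),
            class = "nrmse_result")
}

#' @export
print.nrmse_result <- function(x, ...) {
  cat(sprintf("NRMSE %.1f%% over n=%d (observed range %.2f): %s\n",
              x$percent, x$n, x$observed_range,
              if (x$accepted) "acceptable (< 30%)" else "not acceptable"))
  invisible(x)
}

#' Extrema and range of a motion series
#'
#' @param series non-empty numeric vector.
#' @return named numeric: `min`, `max`, `range` (`max - min`).
#' @export
motion_range <- function(series) {
  if (!length(series)) stop("motion_range: empty series")
  c(min = min(series), max = max(series), range = max(series) - min(series))
}

#' Mean and sample standard deviation of a set of motion ranges
#'
#' @param ranges numeric vector of ranges (n >= 2 for the SD).
#' @return named numeric: `mean`, `sd` (sample, n-1 denominator).
#' @export
summarize_ranges <- function(ranges) {
  if (length(ranges) < 2)
    stop("summarize_ranges: need at least 2 ranges for a sample SD")
  c(mean = mean(ranges), sd = stats::sd(ranges))
}

#' Rotation envelope of passive knee motion
#'
#' The band between the internal-rotation curve under internal-rotation
#' torque (upper limit) and under external-rotation torque (lower limit)
#' across the flexion grid.
#'
#' @param result_ir,result_er [run_flexion_sweep()] results for the same
#'   state under IR and ER torque.
#' @return data.frame `flexion_deg`, `upper_deg`, `lower_deg`, `width_deg`.
#' @export
rotation_envelope <- function(result_ir, result_er) {
  if (!identical(result_ir$kinematics$flexion_deg,
                 result_er$kinematics$flexion_deg))
    stop("rotation_envelope: flexion grids differ")
  if (!identical(result_ir$label, result_er$label))
    stop("rotation_envelope: results are for different knee states")
  data.frame(flexion_deg = result_ir$kinematics$flexion_deg,
             upper_deg = result_ir$kinematics$ir_deg,
             lower_deg = result_er$kinematics$ir_deg,
             width_deg = result_ir$kinematics$ir_deg -
               result_er$kinematics$ir_deg)
}

#' Inter-state comparison report
#'
#' Summarises per-state, per-DoF extrema and ranges, internal-rotation ranges
#' under IR torque with their mean and sample SD, and ranks the
#' reconstructed states by the NRMSE of their internal-rotation curve against
#' the intact curve (smaller = closer to intact).
#'
#' @param results named list of [run_flexion_sweep()] results under IR
#'   torque, keyed by state label.
#' @param intact_key name of the intact entry.
#' @return object of class `comparison_report`: list with `dof_table`
#'   (long data.frame state/dof/min/max/range), `ir_ranges`,
#'   `ir_range_summary` (mean, sd), `ranking` (data.frame state/nrmse_vs_
#'   intact_pct, best first), `missing` (states absent from `results`).
#' @export
compare_states <- function(results, intact_key = "INTACT") {
  if (is.null(results[[intact_key]]))
    stop("compare_states: no intact result under key `", intact_key, "`")
  missing <- setdiff(knee_state_labels(), names(results))
  dofs <- c("ir_deg", "add_deg", "ant_mm", "prox_mm", "lat_mm")
  dof_table <- do.call(rbind, lapply(names(results), function(st) {
    kin <- results[[st]]$kinematics
    do.call(rbind, lapply(dofs, function(d) {
      mr <- motion_range(kin[[d]])
      data.frame(state = st, dof = d, min = mr[["min"]], max = mr[["max"]],
                 range = mr[["range"]], stringsAsFactors = FALSE)
    }))
  }))
  ir_ranges <- vapply(results,
                      function(r) motion_range(r$kinematics$ir_deg)[["range"]],
                      0)
  summ <- if (length(ir_ranges) >= 2) summarize_ranges(ir_ranges)
  else c(mean = unname(ir_ranges), sd = NA_real_)
  recon <- setdiff(names(results), c(intact_key, "ACL_SECTIONED"))
  intact_ir <- results[[intact_key]]$kinematics$ir_deg
  ranking <- data.frame(state = recon,
                        nrmse_vs_intact_pct = vapply(recon, function(st) {
                          nrmse(intact_ir, results[[st]]$kinematics$ir_deg)$percent
                        }, 0),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$nrmse_vs_intact_pct), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(dof_table = dof_table, ir_ranges = ir_ranges,
                 ir_range_summary = summ, ranking = ranking,
                 missing = missing),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n  IR ranges (deg):\n")
  for (nm in names(x$ir_ranges))
    cat(sprintf("    %-14s %.1f\n", nm, x$ir_ranges[[nm]]))
  cat(sprintf("  mean +/- SD of IR range: %.1f +/- %.1f\n",
              x$ir_range_summary[["mean"]], x$ir_range_summary[["sd"]]))
  cat("  ranking vs intact (NRMSE %):\n")
  for (i in seq_len(nrow(x$ranking)))
    cat(sprintf("    %d. %-12s %.1f\n", i, x$ranking$state[i],
                x$ranking$nrmse_vs_intact_pct[i]))
  if (length(x$missing))
    cat("  missing states:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Write a comparison report to JSON and Markdown
#'
#' @param report a [compare_states()] report.
#' @param json_path,md_path output paths (NULL to skip either).
#' @export
write_comparison_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(dof_table = report$dof_table,
           ir_ranges = as.list(report$ir_ranges),
           ir_range_summary = as.list(report$ir_range_summary),
           ranking = report$ranking, missing = report$missing),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(md_path)) {
    lines <- c("# Knee state comparison", "",
               "## Internal-rotation ranges under IR torque", "",
               "| state | min (deg) | max (deg) | range (deg) |",
               "|---|---|---|---|")
    ir <- report$dof_table[report$dof_table$dof == "ir_deg", ]
    for (i in seq_len(nrow(ir)))
      lines <- c(lines, sprintf("| %s | %.1f | %.1f | %.1f |", ir$state[i],
                                ir$min[i], ir$max[i], ir$range[i]))
    lines <- c(lines, "",
               sprintf("Mean +/- SD of IR range: %.1f +/- %.1f deg",
                       report$ir_range_summary[["mean"]],
                       report$ir_range_summary[["sd"]]),
               "", "## Ranking of reconstructions vs intact (IR NRMSE)", "",
               "| rank | state | NRMSE (%) |", "|---|---|---|")
    for (i in seq_len(nrow(report$ranking)))
      lines <- c(lines, sprintf("| %d | %s | %.1f |", i,
                                report$ranking$state[i],
                                report$ranking$nrmse_vs_intact_pct[i]))
    writeLines(lines, md_path)
  }
  invisible(report)
}
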