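# Orchestration: per-frame decomposition + collision analysis over a
# trajectory, and early/late stage comparison.

#' Analyze a trajectory
#'
#' Runs the five-component decomposition (for replication intermediates),
#' the radius of gyration over all nucleotides, and collision detection +
#' tally on every frame, returning one row per frame.
#'
#' @param frames a list of [trajectory_frame()]s (or a single conformation).
#' @param cutoff,exclusion_bp,step,braid_window collision parameters, see
#'   [detect_collisions()].
#' @param keep_events also return the per-event table as attribute
#'   `"events"`.
#' @return A tibble of class `topo_timeseries`: columns `time`, `c1`..`c5`,
#'   `q_unrep`, `q_wrap`, `q_rep`, `delta_lk_total`, `rg_nm`, and the eight
#'   `n_type<k>_<chirality>` collision counts.
#' @export
analyze_trajectory <- function(frames, cutoff = 10, exclusion_bp = 147,
                               step = 10, braid_window = 100,
                               keep_events = FALSE) {
  if (inherits(frames, c("duplex_conformation",
                         "replication_intermediate")))
    frames <- list(trajectory_frame(0, frames))
  if (inherits(frames, "trajectory_frame")) frames <- list(frames)
  if (length(frames) < 1) stop("need at least one frame")
  sizes <- vapply(frames, function(f) nrow(all_points(f)), 0)
  if (length(unique(sizes)) > 1)
    stop("mixed molecule sizes across frames")

  ev_all <- list()
  rows <- lapply(frames, function(f) {
    conf <- f$conformation
    dec <- if (inherits(conf, "replication_intermediate"))
      glance(decompose_ri(conf)) else
      tibble::tibble(q_unrep = NA_real_, q_wrap = NA_real_,
                     q_rep = NA_real_, c1 = NA_real_, c2 = NA_real_,
                     c3 = NA_real_, c4 = NA_real_, c5 = NA_real_,
                     delta_lk_total = NA_real_, baseline_unrep = NA_real_,
                     n_unrep = NA_integer_, n_rep = NA_integer_)
    ev <- detect_collisions(f, cutoff = cutoff,
                            exclusion_bp = exclusion_bp, step = step,
                            braid_window = braid_window)
    ev_all[[length(ev_all) + 1]] <<- ev
    tl <- tally_collisions(ev) |>
      dplyr::mutate(key = paste0("n_type", .data$type, "_",
                                 .data$chirality)) |>
      dplyr::select("key", "count") |>
      tidyr::pivot_wider(names_from = "key", values_from = "count")
    dplyr::bind_cols(
      tibble::tibble(time = f$time, rg_nm = radius_of_gyration(conf)),
      dec[, c("c1", "c2", "c3", "c4", "c5", "q_unrep", "q_wrap", "q_rep",
              "delta_lk_total")],
      tl)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
                       n_collisions = rowSums(dplyr::pick(
                         dplyr::starts_with("n_type"))))
  class(out) <- c("topo_timeseries", class(out))
  if (keep_events) attr(out, "events") <- dplyr::bind_rows(ev_all)
  out
}

#' Average replicate time series
#'
#' Mean (and standard deviation) per time point across replicate
#' trajectories, mirroring multi-simulation averaging.
#'
#' @param reports a list of `topo_timeseries` tibbles with matching time
#'   grids.
#' @return A tibble with per-time mean columns and `sd_` dispersion
#'   columns for the topological components.
#' @export
average_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  dplyr::bind_rows(reports, .id = "replicate") |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(dplyr::across(
      dplyr::where(is.numeric) & !dplyr::matches("^replicate$"),
      list(mean = ~mean(.x), sd = ~stats::sd(.x)),
      .names = "{ifelse(.fn == 'mean', '', 'sd_')}{.col}"),
      .groups = "drop")
}

#' Compare replication stages
#'
#' Per-stage mean radius of gyration, mean collision counts, and the
#' percentage shares of the five linking-difference components, both as
#' signed shares of the total (c_k / dLk x 100) and as absolute shares
#' (|c_k| / sum|c| x 100).
#'
#' @param report_early,report_late `topo_timeseries` tibbles from
#'   [analyze_trajectory()].
#' @return A tibble with one row per stage x component, plus per-stage
#'   `rg_nm` and `n_collisions` means, of class `stage_comparison`.
#' @export
compare_stages <- function(report_early, report_late) {
  one <- function(rep, stage) {
    cmeans <- colMeans(rep[, c("c1", "c2", "c3", "c4", "c5")],
                       na.rm = TRUE)
    dlk <- mean(rep$delta_lk_total, na.rm = TRUE)
    tibble::tibble(
      stage = stage,
      component = paste0("c", 1:5),
      value = as.numeric(cmeans),
      share_signed_pct = 100 * as.numeric(cmeans) / dlk,
      share_abs_pct = 100 * abs(as.numeric(cmeans)) /
        sum(abs(cmeans)),
      delta_lk_total = dlk,
      rg_nm = mean(rep$rg_nm, na.rm = TRUE),
      n_collisions = mean(rep$n_collisions, na.rm = TRUE))
  }
  out <- dplyr::bind_rows(one(report_early, "early"),
                          one(report_late, "late"))
  class(out) <- c("stage_comparison", class(out))
  out
}
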