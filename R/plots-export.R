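# Plotting (ggplot2 autoplot methods) and tabular export helpers.

#' Plot a contribution matrix as a heat map
#'
#' The main diagonal carries the positive charge of the double helix;
#' secondary diagonals reveal plectonemic forms; for replication
#' intermediates the fork block boundaries are drawn.
#'
#' @param object a [contribution_matrix()].
#' @param downsample reduce the matrix by summing `downsample` x
#'   `downsample` tiles before plotting (default chosen so that at most
#'   ~512 rows are drawn).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.contribution_matrix <- function(object, downsample = NULL, ...) {
  M <- object$entries
  n <- nrow(M)
  if (is.null(downsample)) downsample <- max(1L, ceiling(n / 512))
  if (downsample > 1) {
    grp_r <- (seq_len(nrow(M)) - 1) %/% downsample
    grp_c <- (seq_len(ncol(M)) - 1) %/% downsample
    M <- rowsum(t(rowsum(M, grp_r)), grp_c)
    M <- t(M)
  }
  df <- tibble::tibble(
    i = rep(seq_len(nrow(M)) - 1L, times = ncol(M)) * downsample,
    j = rep(seq_len(ncol(M)) - 1L, each = nrow(M)) * downsample,
    charge = as.vector(M))
  lim <- max(abs(df$charge))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$charge)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b",
                                  limits = c(-lim, lim)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "segment j (curve B)", y = "segment i (curve A)",
                  fill = "charge\n(turns)") +
    ggplot2::theme_minimal()
  bb <- object$block_bounds
  if (!is.null(bb) && length(bb) > 1) {
    cuts <- bb[-1]
    p <- p + ggplot2::geom_hline(yintercept = cuts, linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = cuts, linewidth = 0.3)
  }
  p
}

#' Plot a collision tally
#'
#' Type x chirality bar chart of (mean per-frame) collision counts.
#'
#' @param tally a tibble from [tally_collisions()].
#' @return A ggplot object.
#' @export
plot_collision_tally <- function(tally) {
  ggplot2::ggplot(tally,
                  ggplot2::aes(x = factor(.data$type),
                               y = .data$count,
                               fill = .data$chirality)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "collision type", y = "events per frame",
                  fill = "chirality") +
    ggplot2::theme_minimal()
}

#' Plot a topology time series
#'
#' The five linking-difference components against pseudo-time.
#'
#' @param object a `topo_timeseries` from [analyze_trajectory()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.topo_timeseries <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("time", "c1", "c2", "c3", "c4", "c5")],
    -"time", names_to = "component", values_to = "turns")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$turns,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "moves (pseudo-time)", y = "turns") +
    ggplot2::theme_minimal()
}

#' Export a contribution matrix as TSV
#'
#' Row/column names are 0-based nucleotide (segment) indices.
#'
#' @param x a [contribution_matrix()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_contribution_matrix <- function(x, path) {
  stopifnot(inherits(x, "contribution_matrix"))
  M <- x$entries
  dimnames(M) <- list(0:(nrow(M) - 1), 0:(ncol(M) - 1))
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Export a charge decomposition as JSON or CSV
#'
#' @param x a `charge_decomposition`.
#' @param path output file; format chosen by extension (`.json` or
#'   `.csv`).
#' @return Invisibly, `path`.
#' @export
write_decomposition <- function(x, path) {
  stopifnot(inherits(x, "charge_decomposition"))
  g <- glance(x)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(as.list(g), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' Export collision events as CSV
#'
#' @param events a `collision_events` tibble.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a generator configuration as YAML
#'
#' Field names follow [generator_config()].
#'
#' @param path YAML file path.
#' @return `read_generator_config`: a [generator_config()].
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(generator_config)), "...")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown generator config keys: ", paste(extra, collapse = ", "))
  do.call(generator_config, y)
}

#' @rdname read_generator_config
#' @param config a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  keep <- c("n_bp", "frac_replicated", "q_unrep", "q_wrap", "q_rep",
            "precatenane_Ca", "braid_writhe", "n_plectoneme_branches",
            "seed", "helical_repeat_h", "rise_per_bp", "duplex_radius",
            "superhelix_radius", "braid_radius", "unrep_twist_fraction",
            "fork_gap_nm", "n_rep")
  vals <- config[intersect(keep, names(config))]
  vals$n_rep <- config$n_rep
  yaml::write_yaml(vals, path)
  invisible(path)
}
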