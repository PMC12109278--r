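#' Five-component decomposition of the linking number difference of a
#' replication intermediate
#'
#' Partitions the linking number of the two closed parental strands at the
#' fork indices into region charges, then splits those into the five
#' topological components of the linking difference:
#'
#' * `q_unrep` = (a1 x b1 block sum) - n_unrep / h, the charge of the
#'   unreplicated region relative to its relaxed baseline;
#' * `q_wrap` = (a1 x b2) + (a2 x b1) block sums, the wrapping between the
#'   strands of the unreplicated and replicated regions;
#' * `q_rep` = (a2 x b2) block sum, the charge of the replicated region.
#'
#' Component 1 is the twist change of the unreplicated duplex about its
#' axis, Component 2 the writhe-like remainder `q_unrep - c1`, Component 3
#' the wrapping `q_wrap`, Component 4 the precatenation `Ca` (Gauss linking
#' of the two daughter midpoint curves, each closed through its fork
#' junctions), and Component 5 the plectonemes-of-precatenanes remainder
#' `q_rep - c4`.  The components sum to the total linking difference by
#' construction.
#'
#' @param ri a [replication_intermediate()].
#' @return An object of class `charge_decomposition`; see [tidy()] and
#'   [glance()] methods.
#' @export
decompose_ri <- function(ri) {
  stopifnot(inherits(ri, "replication_intermediate"))
  n_unrep <- ri$n_unrep
  h <- ri$helical_repeat
  baseline <- n_unrep / h

  A <- ri$parentalA$points
  B <- ri$parentalB$points
  breaks <- c(0L, n_unrep)
  S <- gauss_block_sums_cpp(A, TRUE, B, TRUE, breaks, breaks)
  # S[1,1] = a1 x b1, S[1,2] = a1 x b2, S[2,1] = a2 x b1, S[2,2] = a2 x b2
  q_unrep <- S[1, 1] - baseline
  q_wrap <- S[1, 2] + S[2, 1]
  q_rep <- S[2, 2]

  dup <- ri_duplexes(ri)
  c1 <- duplex_twist(dup$unreplicated$A, dup$unreplicated$B,
                     closed = FALSE) - baseline
  c2 <- q_unrep - c1
  c3 <- q_wrap

  mid1 <- (dup$daughter1$A + dup$daughter1$B) / 2
  mid2 <- (dup$daughter2$A + dup$daughter2$B) / 2
  c4 <- sum(gauss_block_sums_cpp(mid1, TRUE, mid2, TRUE, 0L, 0L))
  c5 <- q_rep - c4

  structure(list(q_unrep = q_unrep, q_wrap = q_wrap, q_rep = q_rep,
                 c1_dTw_unrep = c1, c2_Wr_unrep = c2, c3_wrapping = c3,
                 c4_precatenanes = c4, c5_plectonemes_of_precatenanes = c5,
                 delta_lk_total = q_unrep + q_wrap + q_rep,
                 baseline_unrep = baseline,
                 n_unrep = n_unrep, n_rep = ri$n_rep,
                 helical_repeat = h),
            class = "charge_decomposition")
}

#' @export
print.charge_decomposition <- function(x, ...) {
  cat("<charge_decomposition>\n")
  cat(sprintf("  region charges: q_unrep = %+.3f, q_wrap = %+.3f, q_rep = %+.3f\n",
              x$q_unrep, x$q_wrap, x$q_rep))
  cat(sprintf("  c1 (dTw unrep)      %+.3f\n", x$c1_dTw_unrep))
  cat(sprintf("  c2 (Wr unrep)       %+.3f\n", x$c2_Wr_unrep))
  cat(sprintf("  c3 (wrapping)       %+.3f\n", x$c3_wrapping))
  cat(sprintf("  c4 (precatenanes)   %+.3f\n", x$c4_precatenanes))
  cat(sprintf("  c5 (plect. of prec) %+.3f\n", x$c5_plectonemes_of_precatenanes))
  cat(sprintf("  total delta Lk      %+.3f (baseline %g turns)\n",
              x$delta_lk_total, x$baseline_unrep))
  invisible(x)
}

#' Tidy a charge decomposition
#'
#' One row per component, in turns.
#'
#' @param x a `charge_decomposition`.
#' @param ... unused.
#' @return A tibble with `component`, `description`, `value`.
#' @export
tidy.charge_decomposition <- function(x, ...) {
  tibble::tibble(
    component = c("c1", "c2", "c3", "c4", "c5"),
    description = c("twist change of unreplicated region",
                    "writhe of unreplicated region",
                    "wrapping between regions",
                    "precatenanes",
                    "plectonemes of precatenanes"),
    value = c(x$c1_dTw_unrep, x$c2_Wr_unrep, x$c3_wrapping,
              x$c4_precatenanes, x$c5_plectonemes_of_precatenanes))
}

#' Glance at a charge decomposition
#'
#' @param x a `charge_decomposition`.
#' @param ... unused.
#' @return A one-row tibble with the region charges, components, total
#'   linking difference and baseline.
#' @export
glance.charge_decomposition <- function(x, ...) {
  tibble::tibble(
    q_unrep = x$q_unrep, q_wrap = x$q_wrap, q_rep = x$q_rep,
    c1 = x$c1_dTw_unrep, c2 = x$c2_Wr_unrep, c3 = x$c3_wrapping,
    c4 = x$c4_precatenanes, c5 = x$c5_plectonemes_of_precatenanes,
    delta_lk_total = x$delta_lk_total,
    baseline_unrep = x$baseline_unrep,
    n_unrep = x$n_unrep, n_rep = x$n_rep)
}

#' Contribution matrix of a conformation
#'
#' Convenience wrapper building the full strand-pair contribution matrix of
#' a duplex or replication intermediate, with block bounds at the fork
#' indices for the latter.
#'
#' @param x a `duplex_conformation` or `replication_intermediate`.
#' @return A [contribution_matrix()].
#' @export
conformation_matrix <- function(x) {
  if (inherits(x, "duplex_conformation"))
    contribution_matrix(x$strandA, x$strandB)
  else if (inherits(x, "replication_intermediate"))
    contribution_matrix(x$parentalA, x$parentalB,
                        block_bounds = c(0L, x$n_unrep))
  else stop("unsupported conformation type")
}
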