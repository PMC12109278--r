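# Readers and writers for oxDNA-style topology / configuration text files,
# with a sidecar JSON region map carrying the replication-intermediate
# annotation that plain oxDNA topology cannot express.  Internally all
# coordinates are nm; the oxDNA length unit (0.8518 nm) is applied at the
# I/O boundary.

OXDNA_NM_PER_UNIT <- 0.8518

#' Read oxDNA topology + configuration files
#'
#' Parses the classic oxDNA text formats: a topology file (counts line,
#' then one `strand base 3'-neighbour 5'-neighbour` record per nucleotide)
#' and a configuration file with one or more blocks (`t = ...` header, box
#' line, energy line, then one position + base vector + base normal +
#' velocity + angular velocity record per nucleotide).  Positions are
#' converted to nm.  Circular strands are recognised by the wrap-around
#' neighbour convention.  If a sidecar region map
#' (`<configuration_path>.regions.json`, or `region_map`) is present the
#' strands are assembled into a [replication_intermediate()]; two closed
#' equal-length strands give a [duplex_conformation()].
#'
#' @param topology_path,configuration_path file paths.
#' @param nm_per_unit length-unit conversion (default 0.8518 nm).
#' @param region_map optional explicit path to the region map JSON.
#' @param helical_repeat bp/turn carried into the conformation objects.
#' @return A list of [trajectory_frame()]s, one per configuration block.
#' @export
read_oxdna <- function(topology_path, configuration_path,
                       nm_per_unit = OXDNA_NM_PER_UNIT,
                       region_map = NULL, helical_repeat = 10.5) {
  top_lines <- readLines(topology_path)
  top_lines <- top_lines[nzchar(trimws(top_lines))]
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(top_lines[1]),
                                              "\\s+")[[1]]))
  if (length(hdr) < 2 || any(is.na(hdr)))
    stop("topology parse error at line 1: expected '<n_nt> <n_strands>'")
  n_nt <- as.integer(hdr[1])
  if (length(top_lines) - 1 != n_nt)
    stop(sprintf("topology declares %d nucleotides but has %d records",
                 n_nt, length(top_lines) - 1))
  rec <- strsplit(trimws(top_lines[-1]), "\\s+")
  strand <- integer(n_nt); nb3 <- integer(n_nt); nb5 <- integer(n_nt)
  for (i in seq_len(n_nt)) {
    r <- rec[[i]]
    if (length(r) < 4)
      stop("topology parse error at line ", i + 1,
           ": expected 4 fields")
    strand[i] <- suppressWarnings(as.integer(r[1]))
    nb3[i] <- suppressWarnings(as.integer(r[3]))
    nb5[i] <- suppressWarnings(as.integer(r[4]))
    if (is.na(strand[i]) || is.na(nb3[i]) || is.na(nb5[i]))
      stop("topology parse error at line ", i + 1,
           ": non-numeric field")
  }

  conf_lines <- readLines(configuration_path)
  starts <- grep("^\\s*t\\s*=", conf_lines)
  if (length(starts) == 0)
    stop("configuration parse error: no 't = ...' block header found")
  frames <- vector("list", length(starts))
  ends <- c(starts[-1] - 1, length(conf_lines))

  # sidecar region map
  if (is.null(region_map)) {
    cand <- paste0(configuration_path, ".regions.json")
    if (file.exists(cand)) region_map <- cand
  }
  rmap <- if (!is.null(region_map)) jsonlite::read_json(region_map) else
    NULL

  for (f in seq_along(starts)) {
    blk <- conf_lines[starts[f]:ends[f]]
    blk <- blk[nzchar(trimws(blk))]
    t_val <- suppressWarnings(
      as.numeric(sub("^\\s*t\\s*=\\s*", "", blk[1])))
    if (is.na(t_val))
      stop("configuration parse error: bad time header '", blk[1], "'")
    body <- blk[-(1:3)]  # skip t, box, energy lines
    if (length(body) != n_nt)
      stop(sprintf(paste0("configuration block %d has %d records but ",
                          "topology declares %d nucleotides ",
                          "(near line %d)"),
                   f, length(body), n_nt, starts[f] + 3))
    vals <- strsplit(trimws(body), "\\s+")
    P <- matrix(NA_real_, n_nt, 3)
    for (i in seq_len(n_nt)) {
      v <- suppressWarnings(as.numeric(vals[[i]]))
      if (length(v) < 3 || any(is.na(v[1:3])))
        stop("configuration parse error at line ", starts[f] + 2 + i,
             ": non-numeric position")
      P[i, ] <- v[1:3] * nm_per_unit
    }
    frames[[f]] <- trajectory_frame(
      t_val, assemble_conformation(P, strand, nb3, nb5, rmap,
                                   helical_repeat))
  }
  frames
}

# Build a conformation object from parsed per-nucleotide records.
assemble_conformation <- function(P, strand, nb3, nb5, rmap,
                                  helical_repeat) {
  sids <- sort(unique(strand))
  idx_of <- lapply(sids, function(s) which(strand == s))
  closed_of <- vapply(seq_along(sids), function(k) {
    ii <- idx_of[[k]]
    # circular convention: last nucleotide's 5' neighbour wraps to first
    nb5[ii[length(ii)]] == ii[1] - 1L || nb3[ii[1]] == ii[length(ii)] - 1L
  }, logical(1))

  if (!is.null(rmap)) {
    n_unrep <- rmap$n_unrep
    n_rep <- rmap$n_rep
    regA <- c(rep("unreplicated", n_unrep),
              rep("replicated_daughter1", n_rep))
    regB <- c(rep("unreplicated", n_unrep),
              rep("replicated_daughter2", n_rep))
    pA <- strand_curve(P[idx_of[[1]], , drop = FALSE], closed = TRUE,
                       region = regA)
    pB <- strand_curve(P[idx_of[[2]], , drop = FALSE], closed = TRUE,
                       region = regB)
    d1 <- strand_curve(P[idx_of[[3]], , drop = FALSE],
                       region = "replicated_daughter1",
                       nt_index = n_unrep:(n_unrep + n_rep - 1))
    d2 <- strand_curve(P[idx_of[[4]], , drop = FALSE],
                       region = "replicated_daughter2",
                       nt_index = n_unrep:(n_unrep + n_rep - 1))
    return(replication_intermediate(pA, pB, d1, d2, n_unrep = n_unrep,
                                    helical_repeat = helical_repeat))
  }
  if (length(sids) == 2 && all(closed_of) &&
      length(idx_of[[1]]) == length(idx_of[[2]])) {
    return(duplex_conformation(
      strand_curve(P[idx_of[[1]], , drop = FALSE], closed = TRUE),
      strand_curve(P[idx_of[[2]], , drop = FALSE], closed = TRUE),
      helical_repeat = helical_repeat, check_separation = FALSE))
  }
  # anything else: a bare set of strand curves
  curves <- lapply(seq_along(sids), function(k)
    strand_curve(P[idx_of[[k]], , drop = FALSE],
                 closed = closed_of[k],
                 nt_index = idx_of[[k]] - 1L))
  structure(list(strands = curves), class = "strand_set")
}

#' Write oxDNA topology + configuration files
#'
#' Writes a conformation (or list of frames of one molecule) in the classic
#' oxDNA text formats, with base vectors synthesized toward the paired
#' strand, base normals along the local tangent, and zero velocities.
#' Closed strands use the circular neighbour convention (the terminal
#' nucleotides wrap).  For replication intermediates a sidecar region map
#' `<configuration_path>.regions.json` is written alongside (0-based,
#' half-open index ranges per region plus the fork indices).
#'
#' @param frames a conformation, [trajectory_frame()], or list of frames.
#' @param topology_path,configuration_path output paths.
#' @param nm_per_unit length-unit conversion (default 0.8518 nm).
#' @param digits coordinate precision in the configuration file.
#' @return Invisibly, the paths written.
#' @export
write_oxdna <- function(frames, topology_path, configuration_path,
                        nm_per_unit = OXDNA_NM_PER_UNIT, digits = 8) {
  if (!is.list(frames) || inherits(frames, c("trajectory_frame",
                                             "duplex_conformation",
                                             "replication_intermediate")))
    frames <- list(frames)
  frames <- lapply(frames, function(f)
    if (inherits(f, "trajectory_frame")) f else trajectory_frame(0, f))
  conf0 <- frames[[1]]$conformation

  strands <- conformation_strands(conf0)
  n_nt <- sum(vapply(strands, function(s) nrow(s$points), 0))
  top <- character(n_nt + 1)
  top[1] <- sprintf("%d %d", n_nt, length(strands))
  base_cycle <- c("A", "T", "C", "G")
  at <- 1L
  for (k in seq_along(strands)) {
    s <- strands[[k]]
    n <- nrow(s$points)
    for (i in seq_len(n)) {
      g <- at + i - 1L          # 0-based global index is g - 1
      nb3 <- if (i > 1) g - 2L else if (s$closed) at + n - 2L else -1L
      nb5 <- if (i < n) g else if (s$closed) at - 1L else -1L
      top[g + 1L] <- sprintf("%d %s %d %d", k,
                             base_cycle[(i - 1) %% 4 + 1], nb3, nb5)
    }
    at <- at + n
  }
  writeLines(top, topology_path)

  fmt <- paste0("%.", digits, "f")
  blocks <- lapply(frames, function(fr) {
    conf <- fr$conformation
    sts <- conformation_strands(conf)
    P <- do.call(rbind, lapply(sts, function(s) s$points))
    BV <- do.call(rbind, lapply(sts, function(s) s$base_vec))
    NV <- do.call(rbind, lapply(sts, function(s) s$normal_vec))
    span <- max(apply(P, 2, function(c) diff(range(c)))) / nm_per_unit + 20
    rows <- sprintf(paste(rep(fmt, 9), collapse = " "),
                    P[, 1] / nm_per_unit, P[, 2] / nm_per_unit,
                    P[, 3] / nm_per_unit,
                    BV[, 1], BV[, 2], BV[, 3],
                    NV[, 1], NV[, 2], NV[, 3])
    c(sprintf("t = %g", fr$time),
      sprintf("b = %.4f %.4f %.4f", span, span, span),
      "E = 0 0 0",
      paste(rows, "0 0 0 0 0 0"))
  })
  writeLines(unlist(blocks), configuration_path)

  if (!inherits(conf0, "replication_intermediate")) {
    # drop any stale sidecar so a later read assembles the right type
    unlink(paste0(configuration_path, ".regions.json"))
  } else {
    n_u <- conf0$n_unrep; n_r <- conf0$n_rep; n_p <- conf0$n_parental
    rmap <- list(
      n_unrep = n_u, n_rep = n_r,
      fork_indices = conf0$fork_indices,
      regions = list(
        list(label = "unreplicated", strand = 1, from = 0, to = n_u),
        list(label = "replicated_daughter1", strand = 1, from = n_u,
             to = n_p),
        list(label = "unreplicated", strand = 2, from = 0, to = n_u),
        list(label = "replicated_daughter2", strand = 2, from = n_u,
             to = n_p),
        list(label = "replicated_daughter1", strand = 3, from = 0,
             to = n_r),
        list(label = "replicated_daughter2", strand = 4, from = 0,
             to = n_r)))
    jsonlite::write_json(rmap, paste0(configuration_path,
                                      ".regions.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(topology_path, configuration_path))
}

# Strand list of a conformation with synthesized base/normal vectors.
conformation_strands <- function(conf) {
  mk <- function(points, closed, partner) {
    bv <- rowunit(partner - points)
    nv <- polyline_tangents(points, closed)
    list(points = points, closed = closed, base_vec = bv, normal_vec = nv)
  }
  if (inherits(conf, "duplex_conformation")) {
    A <- conf$strandA$points; B <- conf$strandB$points
    list(mk(A, TRUE, B), mk(B, TRUE, A))
  } else if (inherits(conf, "replication_intermediate")) {
    A <- conf$parentalA$points; B <- conf$parentalB$points
    ir <- (conf$n_unrep + 1):conf$n_parental
    partnerA <- rbind(B[seq_len(conf$n_unrep), , drop = FALSE],
                      conf$daughter_new1$points)
    partnerB <- rbind(A[seq_len(conf$n_unrep), , drop = FALSE],
                      conf$daughter_new2$points)
    list(mk(A, TRUE, partnerA), mk(B, TRUE, partnerB),
         mk(conf$daughter_new1$points, FALSE, A[ir, , drop = FALSE]),
         mk(conf$daughter_new2$points, FALSE, B[ir, , drop = FALSE]))
  } else stop("unsupported conformation type")
}
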