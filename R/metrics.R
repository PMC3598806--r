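# Headline switch metrics: hydrophobic-pocket openness d (Calpha GLU16 -
# Calpha LEU48), windowed statistics, open/semi-closed/closed state labels,
# EF-site expansion and the position-2/position-9 backbone-N to
# position-12 glutamate side-chain "prong" distances.

#' Per-frame metric series
#'
#' A named per-frame scalar series with units and the atom anchors it was
#' measured between.
#'
#' @param name metric name.
#' @param values numeric per-frame values.
#' @param unit unit string, e.g. \code{"angstrom"} or \code{"degree"}.
#' @param anchors character vector describing the atoms the metric is
#'   anchored on (\code{"chain:resno:atom"}).
#' @param frames integer frame indices (default \code{1..F}).
#' @return an object of class \code{metric_series}.
#' @export
metric_series <- function(name, values, unit = "angstrom",
                          anchors = character(0),
                          frames = seq_along(values)) {
  stopifnot(is.numeric(values), length(frames) == length(values))
  structure(list(name = name, values = as.numeric(values), unit = unit,
                 anchors = anchors, frames = as.integer(frames)),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("metric '%s' [%s]: %d frames, mean %.3f, range [%.3f, %.3f]\n",
              x$name, x$unit, length(x$values), mean(x$values),
              min(x$values), max(x$values)))
  if (length(x$anchors))
    cat("  anchors:", paste(x$anchors, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metric_series <- function(x, ...) {
  data.frame(frame = x$frames, value = x$values)
}

#' @export
plot.metric_series <- function(x, ...) {
  plot(x$frames, x$values, type = "l", xlab = "frame",
       ylab = paste0(x$name, " (", x$unit, ")"), ...)
}

series_values <- function(x) {
  if (inherits(x, "metric_series")) x$values else as.numeric(x)
}

anchor_label <- function(struct, idx) {
  a <- struct$atoms
  sprintf("%s:%d:%s", a$chain_id[idx], a$residue_number[idx], a$atom_name[idx])
}

frame_distance_series <- function(traj, i, j, name) {
  di <- traj$coords[, i, , drop = FALSE]
  dj <- traj$coords[, j, , drop = FALSE]
  d <- sqrt(rowSums((matrix(di, dim(traj$coords)[1L], 3L) -
                       matrix(dj, dim(traj$coords)[1L], 3L))^2))
  metric_series(name, d,
                anchors = c(anchor_label(traj$topology, i),
                            anchor_label(traj$topology, j)))
}

#' Pocket-openness series d
#'
#' The openness of the A/B helix hydrophobic pocket measured per frame as
#' the distance between the alpha-carbons of the first A-helix residue
#' (GLU16) and the last B-helix residue (LEU48).
#'
#' @param traj a \code{trn_trajectory}.
#' @param res_a residue number of the first anchor (default 16).
#' @param res_b residue number of the second anchor (default 48).
#' @param chain chain id carrying TnC.
#' @return a \code{\link{metric_series}} in Angstrom.
#' @export
pocket_openness_series <- function(traj, res_a = 16L, res_b = 48L, chain) {
  stopifnot(inherits(traj, "trn_trajectory"))
  i <- find_atom(traj$topology, chain, res_a, "CA", required = TRUE)
  j <- find_atom(traj$topology, chain, res_b, "CA", required = TRUE)
  frame_distance_series(traj, i, j, "pocket_openness_d")
}

#' Windowed mean and sample SD of a series
#'
#' @param series a \code{metric_series} or numeric vector.
#' @param window \code{"all"}, \code{list(last_n_frames = n)} or
#'   \code{list(frame_range = c(lo, hi))}; the range is clipped to the series.
#' @return named numeric \code{c(mean, sd, n)}; SD uses the n-1 denominator.
#' @export
window_stats <- function(series, window = "all") {
  v <- series_values(series)
  f <- length(v)
  idx <- if (identical(window, "all")) {
    seq_len(f)
  } else if (is.list(window) && !is.null(window$last_n_frames)) {
    n <- as.integer(window$last_n_frames)
    seq.int(max(1L, f - n + 1L), f)
  } else if (is.list(window) && !is.null(window$frame_range)) {
    r <- as.integer(window$frame_range)
    seq.int(max(1L, r[1L]), min(f, r[2L]))
  } else stop("window_stats: unknown window specification", call. = FALSE)
  if (length(idx) == 0L || idx[1L] > f)
    stop("window_stats: empty window after clipping", call. = FALSE)
  vals <- v[idx]
  c(mean = mean(vals),
    sd = if (length(vals) > 1L) stats::sd(vals) else 0,
    n = length(vals))
}

#' Pocket state thresholds
#'
#' Defaults (14.5 / 18.0 Angstrom) separate the closed, semi-closed and open
#' regimes of the pocket-openness distance. They are configuration, not
#' analysis logic.
#'
#' @param closed_max largest mean d still called closed, Angstrom.
#' @param semi_closed_max largest mean d still called semi-closed, Angstrom.
#' @return an object of class \code{pocket_state_thresholds}.
#' @export
pocket_state_thresholds <- function(closed_max = 14.5, semi_closed_max = 18.0) {
  if (!is_scalar_number(closed_max) || !is_scalar_number(semi_closed_max) ||
      closed_max >= semi_closed_max)
    stop("pocket_state_thresholds: need closed_max < semi_closed_max",
         call. = FALSE)
  structure(list(closed_max = closed_max, semi_closed_max = semi_closed_max),
            class = "pocket_state_thresholds")
}

#' Classify the pocket state from a windowed mean openness
#'
#' @param mean_d windowed mean pocket openness, Angstrom (non-negative).
#' @param thresholds a \code{\link{pocket_state_thresholds}}.
#' @return one of \code{"closed"}, \code{"semi-closed"}, \code{"open"}.
#' @export
classify_pocket_state <- function(mean_d,
                                  thresholds = pocket_state_thresholds()) {
  stopifnot(inherits(thresholds, "pocket_state_thresholds"))
  if (!is_scalar_number(mean_d) || mean_d < 0)
    stop("classify_pocket_state: mean_d must be a non-negative number",
         call. = FALSE)
  if (mean_d <= thresholds$closed_max) "closed"
  else if (mean_d <= thresholds$semi_closed_max) "semi-closed"
  else "open"
}

#' EF-hand calcium-binding site definition
#'
#' A 12-residue binding loop. Defaults place site I at residues 29-40 and
#' site II at residues 65-76 (fast skeletal TnC author numbering). The ion
#' is coordinated by loop positions 1, 3, (5 in site II), 7 and 12; position
#' 12 is the invariant bidentate glutamate.
#'
#' @param site_id one of \code{"I"}, \code{"II"}, \code{"III"}, \code{"IV"}.
#' @param chain chain id carrying TnC.
#' @param loop_start first residue of the loop; defaults 29 (site I) and
#'   65 (site II), none for III/IV.
#' @param ligand_positions coordinating loop positions; defaults
#'   \code{c(1, 3, 7, 12)} for site I and \code{c(1, 3, 5, 7, 12)} for site II.
#' @return an object of class \code{ef_site}.
#' @export
ef_site <- function(site_id = c("I", "II", "III", "IV"), chain,
                    loop_start = NULL, ligand_positions = NULL) {
  site_id <- match.arg(site_id)
  if (is.null(loop_start))
    loop_start <- switch(site_id, I = 29L, II = 65L,
                         stop("ef_site: loop_start has no default for site ",
                              site_id, call. = FALSE))
  if (is.null(ligand_positions))
    ligand_positions <- if (site_id == "II") c(1L, 3L, 5L, 7L, 12L)
                        else c(1L, 3L, 7L, 12L)
  loop <- seq.int(loop_start, loop_start + 11L)
  if (!all(ligand_positions %in% 1:12))
    stop("ef_site: ligand positions must lie in 1..12", call. = FALSE)
  structure(list(site_id = site_id, chain = chain,
                 loop_residues = loop,
                 ligand_positions = sort(unique(as.integer(ligand_positions))),
                 position2_residue = loop[2L],
                 position9_residue = loop[9L],
                 position12_residue = loop[12L]),
            class = "ef_site")
}

#' @export
print.ef_site <- function(x, ...) {
  cat(sprintf("EF-hand site %s (chain %s): loop %d-%d, ligand positions %s\n",
              x$site_id, x$chain, x$loop_residues[1L], x$loop_residues[12L],
              paste(x$ligand_positions, collapse = ",")))
  invisible(x)
}

#' Calcium-site expansion series
#'
#' Per-frame distance between the alpha-carbons of loop positions 1 and 12;
#' the binding pocket expands on calcium release.
#'
#' @param traj a \code{trn_trajectory}.
#' @param site an \code{\link{ef_site}}.
#' @return a \code{\link{metric_series}} in Angstrom.
#' @export
site_expansion_series <- function(traj, site) {
  stopifnot(inherits(traj, "trn_trajectory"), inherits(site, "ef_site"))
  i <- find_atom(traj$topology, site$chain, site$loop_residues[1L], "CA",
                 required = TRUE)
  j <- find_atom(traj$topology, site$chain, site$position12_residue, "CA",
                 required = TRUE)
  s <- frame_distance_series(traj, i, j,
                             sprintf("site_%s_expansion", site$site_id))
  s
}

#' Prong-interaction distance series
#'
#' Four labelled series monitoring the hold the position-12 glutamate side
#' chain keeps on the loop backbone: for each of the backbone nitrogens at
#' loop positions 2 and 9, (a) the minimum distance to the side-chain
#' carboxylate oxygens OE1/OE2 and (b) the distance to the side-chain CD.
#'
#' @param traj a \code{trn_trajectory}.
#' @param site an \code{\link{ef_site}} whose position-12 residue carries
#'   CD, OE1 and OE2 side-chain atoms (a glutamate).
#' @return named list of four \code{\link{metric_series}}:
#'   \code{N2_OE}, \code{N2_CD}, \code{N9_OE}, \code{N9_CD}.
#' @export
prong_distance_series <- function(traj, site) {
  stopifnot(inherits(traj, "trn_trajectory"), inherits(site, "ef_site"))
  topo <- traj$topology
  r12 <- site$position12_residue
  side <- vapply(c("CD", "OE1", "OE2"), function(nm)
    find_atom(topo, site$chain, r12, nm), integer(1))
  if (anyNA(side))
    stop(sprintf(
      "position-12 residue %d (chain %s) lacks glutamate side-chain atoms %s",
      r12, site$chain,
      paste(c("CD", "OE1", "OE2")[is.na(side)], collapse = ", ")),
      call. = FALSE)
  f <- n_frames(traj)
  out <- list()
  for (pos in c(2L, 9L)) {
    res <- if (pos == 2L) site$position2_residue else site$position9_residue
    ni <- find_atom(topo, site$chain, res, "N", required = TRUE)
    npos <- matrix(traj$coords[, ni, ], f, 3L)
    d_oe1 <- sqrt(rowSums((npos - matrix(traj$coords[, side["OE1"], ], f, 3L))^2))
    d_oe2 <- sqrt(rowSums((npos - matrix(traj$coords[, side["OE2"], ], f, 3L))^2))
    d_cd <- sqrt(rowSums((npos - matrix(traj$coords[, side["CD"], ], f, 3L))^2))
    base <- sprintf("site_%s_N%d", site$site_id, pos)
    out[[sprintf("N%d_OE", pos)]] <- metric_series(
      paste0(base, "_OE"), pmin(d_oe1, d_oe2),
      anchors = c(anchor_label(topo, ni), anchor_label(topo, side["OE1"]),
                  anchor_label(topo, side["OE2"])))
    out[[sprintf("N%d_CD", pos)]] <- metric_series(
      paste0(base, "_CD"), d_cd,
      anchors = c(anchor_label(topo, ni), anchor_label(topo, side["CD"])))
  }
  out
}
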