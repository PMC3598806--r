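# Hydrogen-bond monitoring: amide-hydrogen placement, donor-acceptor
# distance series in heavy (N-O) or hydrogen (HN-O) mode, dwell-filtered
# breakage/reformation events, and the beta-sheet scaffold four-pair report.
#
# The bond criterion is distance-only (no donor-angle term); defaults are
# HN-O <= 2.5 A in hydrogen mode and N-O <= 3.5 A in heavy mode.

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HN")

#' Hydrogen-bond pair
#'
#' @param donor_chain,donor_resno chain and residue of the donor backbone
#'   nitrogen.
#' @param acceptor_chain,acceptor_resno chain and residue of the acceptor
#'   backbone oxygen.
#' @param label text label for reports.
#' @return an object of class \code{hbond_pair}.
#' @export
hbond_pair <- function(donor_chain, donor_resno, acceptor_chain,
                       acceptor_resno, label = NULL) {
  if (donor_chain == acceptor_chain && donor_resno == acceptor_resno)
    stop("hbond_pair: donor and acceptor must differ", call. = FALSE)
  if (is.null(label))
    label <- sprintf("%s%d(HN)-%s%d(O)", donor_chain, donor_resno,
                     acceptor_chain, acceptor_resno)
  structure(list(donor_chain = donor_chain,
                 donor_resno = as.integer(donor_resno),
                 acceptor_chain = acceptor_chain,
                 acceptor_resno = as.integer(acceptor_resno),
                 label = label),
            class = "hbond_pair")
}

# Place the amide hydrogen of one residue from backbone geometry:
# 1.01 A from N, opposite the bisector of the C_prev->N and CA->N directions.
place_amide_h <- function(n_pos, ca_pos, cprev_pos) {
  u1 <- unit(cprev_pos - n_pos)
  u2 <- unit(ca_pos - n_pos)
  n_pos + 1.01 * unit(-(u1 + u2))
}

#' Add missing amide hydrogens to a structure
#'
#' For every non-proline residue with a preceding residue in the same chain
#' (sequence-adjacent, so chain N-termini and chain breaks are skipped) and
#' no existing amide hydrogen, an H atom is placed 1.01 Angstrom from N in
#' the C_prev-N-CA plane, opposite the bisector of the two bonds. Heavy
#' atoms are never moved; the call is idempotent.
#'
#' @param struct a \code{trn_structure} with backbone N, CA (and C on the
#'   preceding residues).
#' @return a \code{trn_structure} with added \code{H} atoms appended after
#'   the existing atoms, carrying attributes \code{n_placed} and
#'   \code{n_skipped}.
#' @export
add_amide_hydrogens <- function(struct) {
  stopifnot(inherits(struct, "trn_structure"))
  a <- struct$atoms
  res <- unique(a[, c("chain_id", "residue_number", "residue_name")])
  res <- res[order(res$chain_id, res$residue_number), , drop = FALSE]
  new_rows <- list()
  new_xyz <- list()
  n_skipped <- 0L
  serial0 <- max(a$serial)
  for (k in seq_len(nrow(res))) {
    ch <- res$chain_id[k]; rn <- res$residue_number[k]
    if (res$residue_name[k] == "PRO") next
    if (!is.na(find_atom(struct, ch, rn, "H")) ||
        !is.na(find_atom(struct, ch, rn, "HN"))) next
    ni <- find_atom(struct, ch, rn, "N")
    cai <- find_atom(struct, ch, rn, "CA")
    cprev <- find_atom(struct, ch, rn - 1L, "C")
    if (is.na(cprev)) next  # chain N-terminus or chain break: no amide H
    if (is.na(ni) || is.na(cai)) {
      n_skipped <- n_skipped + 1L
      warning(sprintf("residue %s:%d lacks backbone anchors; amide H skipped",
                      ch, rn), call. = FALSE)
      next
    }
    h <- tryCatch(
      place_amide_h(struct$xyz[ni, ], struct$xyz[cai, ], struct$xyz[cprev, ]),
      error = function(e) NULL)
    if (is.null(h)) {
      n_skipped <- n_skipped + 1L
      warning(sprintf("residue %s:%d has degenerate backbone; amide H skipped",
                      ch, rn), call. = FALSE)
      next
    }
    serial0 <- serial0 + 1L
    new_rows[[length(new_rows) + 1L]] <- data.frame(
      serial = serial0, atom_name = "H", residue_name = res$residue_name[k],
      chain_id = ch, residue_number = rn, element = "H",
      alt_loc = NA_character_, hetatm = FALSE, stringsAsFactors = FALSE)
    new_xyz[[length(new_xyz) + 1L]] <- h
  }
  if (length(new_rows)) {
    struct <- new_structure(rbind(a, do.call(rbind, new_rows)),
                            rbind(struct$xyz, do.call(rbind, new_xyz)),
                            source = struct$source, model = struct$model)
  }
  attr(struct, "n_placed") <- length(new_rows)
  attr(struct, "n_skipped") <- n_skipped
  struct
}

#' Hydrogen-bond distance series
#'
#' Per-frame donor-acceptor distance for one pair. In \code{"heavy"} mode
#' the backbone N-O distance is reported. In \code{"hydrogen"} mode the
#' amide hydrogen is re-placed every frame from that frame's backbone
#' (C_prev, N, CA) so the hydrogen follows backbone motion, and the HN-O
#' distance is reported.
#'
#' @param traj a \code{trn_trajectory}.
#' @param pair an \code{\link{hbond_pair}}.
#' @param mode \code{"hydrogen"} (HN-O) or \code{"heavy"} (N-O).
#' @return a \code{\link{metric_series}} in Angstrom.
#' @export
hbond_distance_series <- function(traj, pair, mode = c("hydrogen", "heavy")) {
  stopifnot(inherits(traj, "trn_trajectory"), inherits(pair, "hbond_pair"))
  mode <- match.arg(mode)
  topo <- traj$topology
  ni <- find_atom(topo, pair$donor_chain, pair$donor_resno, "N",
                  required = TRUE)
  oi <- find_atom(topo, pair$acceptor_chain, pair$acceptor_resno, "O",
                  required = TRUE)
  f <- n_frames(traj)
  o_pos <- matrix(traj$coords[, oi, ], f, 3L)
  if (mode == "heavy") {
    n_pos <- matrix(traj$coords[, ni, ], f, 3L)
    d <- sqrt(rowSums((n_pos - o_pos)^2))
  } else {
    don_res <- topo$atoms$residue_name[ni]
    if (don_res == "PRO")
      stop("hbond_distance_series: proline has no amide hydrogen",
           call. = FALSE)
    cai <- find_atom(topo, pair$donor_chain, pair$donor_resno, "CA",
                     required = TRUE)
    cprev <- find_atom(topo, pair$donor_chain, pair$donor_resno - 1L, "C")
    if (is.na(cprev))
      stop(sprintf(
        "hbond_distance_series: residue %s:%d has no preceding C; cannot place HN",
        pair$donor_chain, pair$donor_resno), call. = FALSE)
    d <- vapply(seq_len(f), function(fr) {
      h <- place_amide_h(traj$coords[fr, ni, ], traj$coords[fr, cai, ],
                         traj$coords[fr, cprev, ])
      vnorm(h - o_pos[fr, ])
    }, numeric(1))
  }
  metric_series(paste0(pair$label, if (mode == "heavy") " [N-O]" else " [HN-O]"),
                d, anchors = c(anchor_label(topo, ni), anchor_label(topo, oi)))
}

#' Detect breakage/reformation transitions in a distance series
#'
#' Threshold crossings filtered by a dwell requirement: a crossing counts
#' only when the new state persists for at least \code{min_dwell} frames.
#' The initial state is the first frame's side of the threshold; reported
#' events alternate in kind. Values above the threshold are "broken".
#'
#' @param series a \code{metric_series} or numeric vector, Angstrom.
#' @param threshold bond threshold, Angstrom (> 0).
#' @param min_dwell minimum persistence of the new state, frames (>= 1).
#' @return data.frame with columns \code{kind} ("breakage"/"reformation"),
#'   \code{frame} (first frame of the new state, 1-based),
#'   \code{dwell_before} and \code{dwell_after} (frames).
#' @export
detect_transitions <- function(series, threshold, min_dwell = 1L) {
  if (!is_scalar_number(threshold) || threshold <= 0)
    stop("detect_transitions: threshold must be > 0", call. = FALSE)
  min_dwell <- as.integer(min_dwell)
  if (min_dwell < 1L)
    stop("detect_transitions: min_dwell must be >= 1", call. = FALSE)
  v <- series_values(series)
  broken <- v > threshold
  r <- rle(broken)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  state <- broken[1L]
  last_flip <- 1L
  out <- list()
  for (k in seq_along(r$lengths)[-1L]) {
    if (r$values[k] != state && r$lengths[k] >= min_dwell) {
      out[[length(out) + 1L]] <- data.frame(
        kind = if (r$values[k]) "breakage" else "reformation",
        frame = starts[k],
        dwell_before = starts[k] - last_flip,
        dwell_after = r$lengths[k],
        stringsAsFactors = FALSE)
      state <- r$values[k]
      last_flip <- starts[k]
    }
  }
  if (length(out) == 0L)
    return(data.frame(kind = character(0), frame = integer(0),
                      dwell_before = integer(0), dwell_after = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Beta-sheet scaffold report
#'
#' The four hydrogen-bond pairs of the short two-stranded beta-sheet joining
#' the two calcium-binding sites, monitored in hydrogen (HN-O) mode:
#' ILE36 O <- ILE72 HN, ILE72 O <- ILE36 HN, GLY34 O <- PHE74 HN and
#' THR38 HN -> GLY70 O. A pair counts as formed in a frame when HN-O is at
#' or below \code{formed_max}.
#'
#' @param traj a \code{trn_trajectory}.
#' @param chain chain id carrying TnC.
#' @param formed_max formed criterion on the HN-O distance, Angstrom.
#' @return list with \code{series} (named list of four
#'   \code{\link{metric_series}}), \code{formed_fraction} (named numeric) and
#'   \code{table} (per-pair summary data.frame).
#' @export
beta_scaffold_report <- function(traj, chain, formed_max = 2.5) {
  stopifnot(inherits(traj, "trn_trajectory"))
  pairs <- list(
    ILE36O_ILE72HN = hbond_pair(chain, 72L, chain, 36L,
                                label = "ILE36(O)-ILE72(HN)"),
    ILE72O_ILE36HN = hbond_pair(chain, 36L, chain, 72L,
                                label = "ILE72(O)-ILE36(HN)"),
    GLY34O_PHE74HN = hbond_pair(chain, 74L, chain, 34L,
                                label = "GLY34(O)-PHE74(HN)"),
    THR38HN_GLY70O = hbond_pair(chain, 38L, chain, 70L,
                                label = "THR38(HN)-GLY70(O)"))
  series <- lapply(pairs, function(p)
    hbond_distance_series(traj, p, mode = "hydrogen"))
  formed <- vapply(series, function(s) mean(s$values <= formed_max), numeric(1))
  tab <- data.frame(
    pair = vapply(pairs, `[[`, character(1), "label"),
    donor = vapply(pairs, function(p)
      sprintf("%s:%d:HN", p$donor_chain, p$donor_resno), character(1)),
    acceptor = vapply(pairs, function(p)
      sprintf("%s:%d:O", p$acceptor_chain, p$acceptor_resno), character(1)),
    mean = vapply(series, function(s) mean(s$values), numeric(1)),
    min = vapply(series, function(s) min(s$values), numeric(1)),
    formed_fraction = formed,
    row.names = NULL, stringsAsFactors = FALSE)
  list(series = series, formed_fraction = formed, table = tab,
       formed_max = formed_max)
}
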