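# Per-residue Calpha RMSF after rigid superposition, and cross-condition
# fold-change comparison.

#' Per-residue Calpha RMSF profile
#'
#' Every frame is superposed onto the reference via least-squares fitting on
#' the fit selection, then RMSF_i = sqrt(mean_f |r_i - rbar_i|^2) with rbar
#' the post-fit mean position of atom i. The default analyzed and fit
#' selection is the Calpha trace of residues 5-80 (the N-lobe); the
#' reference is the post-fit mean structure.
#'
#' @param traj a \code{trn_trajectory}.
#' @param analyze an \code{\link{selection}} of atoms to report; default
#'   Calpha of residues 5-80 on \code{chain}.
#' @param fit an \code{\link{selection}} of atoms to superpose on, or
#'   \code{NULL} for no superposition (identity fit); default = analyze.
#' @param reference \code{"mean"} (post-fit mean structure) or
#'   \code{"frame1"}.
#' @param chain chain id used for the default selections.
#' @return a \code{flexibility_profile}: data.frame with columns
#'   \code{residue} and \code{rmsf} (Angstrom), with the fit metadata in
#'   attributes.
#' @export
rmsf_profile <- function(traj, analyze = NULL, fit = analyze,
                         reference = c("mean", "frame1"), chain = NULL) {
  stopifnot(inherits(traj, "trn_trajectory"))
  reference <- match.arg(reference)
  if (is.null(analyze)) {
    analyze <- selection(chain = chain, residue_range = c(5L, 80L),
                         atom_names = "CA")
    if (missing(fit)) fit <- analyze
  }
  topo <- traj$topology
  idx_a <- resolve_selection(topo, analyze, require_atoms = 1L)
  f <- n_frames(traj)
  a <- nrow(topo$atoms)
  coords <- traj$coords

  if (!is.null(fit)) {
    idx_f <- resolve_selection(topo, fit, require_atoms = 3L)
    fit_to <- function(coords, ref_fit) {
      out <- coords
      for (fr in seq_len(f)) {
        frame <- matrix(coords[fr, , ], a, 3L)
        tr <- kabsch_superpose(frame[idx_f, , drop = FALSE], ref_fit)$transform
        out[fr, , ] <- apply_transform(tr, frame)
      }
      out
    }
    ref_fit <- matrix(coords[1L, idx_f, ], length(idx_f), 3L)
    aligned <- fit_to(coords, ref_fit)
    if (reference == "mean") {
      mean_fit <- apply(aligned[, idx_f, , drop = FALSE], c(2L, 3L), mean)
      aligned <- fit_to(coords, mean_fit)
    }
    coords <- aligned
  }

  sub <- coords[, idx_a, , drop = FALSE]
  mean_pos <- apply(sub, c(2L, 3L), mean)
  sq <- (sub - aperm(array(mean_pos, c(length(idx_a), 3L, f)),
                     c(3L, 1L, 2L)))^2
  rmsf <- sqrt(apply(sq, 2L, sum) / f)

  out <- data.frame(residue = topo$atoms$residue_number[idx_a], rmsf = rmsf)
  class(out) <- c("flexibility_profile", "data.frame")
  attr(out, "fit") <- if (is.null(fit)) "identity" else fit
  attr(out, "reference") <- if (is.null(fit)) "raw frames" else reference
  attr(out, "chain") <- chain
  out
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat(sprintf("RMSF profile: %d residues, mean %.3f A, max %.3f A (residue %d)\n",
              nrow(x), mean(x$rmsf), max(x$rmsf),
              x$residue[which.max(x$rmsf)]))
  invisible(x)
}

#' @export
plot.flexibility_profile <- function(x, ...) {
  plot(x$residue, x$rmsf, type = "l", xlab = "residue", ylab = "RMSF (A)", ...)
}

#' Fold change between two RMSF profiles
#'
#' Per-residue ratio a/b with a flooring of both profiles (so near-rigid
#' residues do not blow the ratio up), plus the list of peaks: contiguous
#' runs of residues above the ratio cutoff, reported with the run's
#' maximum-ratio residue as the center.
#'
#' @param a,b \code{flexibility_profile}s over the same residue set.
#' @param floor flooring applied to both profiles, Angstrom.
#' @param peak_min_ratio minimum ratio for a residue to join a peak.
#' @return list with \code{ratio} (data.frame residue/ratio) and
#'   \code{peaks} (data.frame center/start/end/max_ratio).
#' @export
rmsf_fold_change <- function(a, b, floor = 0.05, peak_min_ratio = 2.0) {
  stopifnot(inherits(a, "flexibility_profile"),
            inherits(b, "flexibility_profile"))
  if (!identical(a$residue, b$residue)) {
    only_a <- setdiff(a$residue, b$residue)
    only_b <- setdiff(b$residue, a$residue)
    stop("rmsf_fold_change: residue sets differ",
         if (length(only_a)) paste0("; only in a: ",
                                    paste(only_a, collapse = ",")) else "",
         if (length(only_b)) paste0("; only in b: ",
                                    paste(only_b, collapse = ",")) else "",
         call. = FALSE)
  }
  ratio <- pmax(a$rmsf, floor) / pmax(b$rmsf, floor)
  above <- ratio > peak_min_ratio
  peaks <- list()
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      span <- starts[k]:ends[k]
      top <- span[which.max(ratio[span])]
      peaks[[length(peaks) + 1L]] <- data.frame(
        center = a$residue[top], start = a$residue[starts[k]],
        end = a$residue[ends[k]], max_ratio = ratio[top])
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(center = integer(0), start = integer(0), end = integer(0),
               max_ratio = numeric(0))
  list(ratio = data.frame(residue = a$residue, ratio = ratio), peaks = peaks)
}
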