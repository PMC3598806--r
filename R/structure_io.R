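# PDB (fixed-width v3.3 ATOM/HETATM/MODEL/ENDMDL) and whitespace xyz-table
# reading and writing, plus atom selection resolution.
#
# Only the record types needed for trajectory analysis are interpreted;
# header semantics beyond MODEL are ignored. Alternate locations are reduced
# to a single conformer (highest occupancy, ties broken toward 'A') so that
# the topology is deterministic.

TWO_LETTER_ELEMENTS <- c("CA", "MG", "ZN", "FE", "NA", "CL", "MN", "BR",
                         "CU", "NI", "CO", "CD", "SE", "HG", "SR", "CS")

canonical_element <- function(sym) {
  s <- toupper(trimws(sym))
  ifelse(nchar(s) == 2L,
         paste0(substr(s, 1L, 1L), tolower(substr(s, 2L, 2L))),
         s)
}

# Infer the element from the PDB atom-name columns (13-16) when the element
# field (77-78) is blank. A name that starts in column 13 and whose trimmed
# form is a known two-letter symbol is taken as that element (this is what
# separates a calcium HETATM "CA" from an alpha-carbon " CA "); otherwise the
# first alphabetic character after stripping digits wins.
infer_element <- function(raw_name) {
  trimmed <- trimws(raw_name)
  stripped <- gsub("[0-9']", "", trimmed)
  first_char <- substr(raw_name, 1L, 1L)
  two <- toupper(substr(paste0(trimmed, " "), 1L, 2L))
  if (first_char != " " && nchar(trimmed) == 2L && two %in% TWO_LETTER_ELEMENTS)
    return(canonical_element(two))
  m <- regmatches(stripped, regexpr("[A-Za-z]", stripped))
  if (length(m) == 0L || !nzchar(m))
    stop("cannot infer element from atom name '", raw_name, "'", call. = FALSE)
  toupper(m)
}

parse_pdb_atom_lines <- function(lines, line_numbers) {
  n <- length(lines)
  if (n == 0L)
    return(data.frame(serial = integer(0), atom_name = character(0),
                      residue_name = character(0), chain_id = character(0),
                      residue_number = integer(0), element = character(0),
                      alt_loc = character(0), hetatm = logical(0),
                      occupancy = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), stringsAsFactors = FALSE))
  short <- nchar(lines) < 54L
  if (any(short))
    stop("malformed PDB record (too short) at line ",
         line_numbers[which(short)[1L]], call. = FALSE)
  field <- function(a, b) substr(lines, a, b)
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(field(a, b)))
    bad <- is.na(v)
    if (any(bad))
      stop("malformed PDB record (bad ", what, " field) at line ",
           line_numbers[which(bad)[1L]], call. = FALSE)
    v
  }
  raw_name <- field(13L, 16L)
  occ_raw <- trimws(field(55L, 60L))
  occ <- suppressWarnings(as.numeric(occ_raw))
  occ[is.na(occ)] <- 1
  ele_raw <- trimws(field(77L, 78L))
  element <- ifelse(nzchar(ele_raw), canonical_element(ele_raw),
                    vapply(raw_name, infer_element, character(1)))
  data.frame(
    serial = as.integer(num(7L, 11L, "serial")),
    atom_name = trimws(raw_name),
    residue_name = trimws(field(18L, 20L)),
    chain_id = substr(lines, 22L, 22L),
    residue_number = as.integer(num(23L, 26L, "residue number")),
    element = unname(element),
    alt_loc = trimws(field(17L, 17L)),
    hetatm = startsWith(lines, "HETATM"),
    occupancy = occ,
    x = num(31L, 38L, "x"), y = num(39L, 46L, "y"), z = num(47L, 54L, "z"),
    stringsAsFactors = FALSE)
}

# Reduce alternate locations to one conformer per (chain, residue, atom name):
# keep the highest occupancy, break ties toward altLoc 'A'.
collapse_altloc <- function(tab) {
  key <- paste(tab$chain_id, tab$residue_number, tab$atom_name, sep = ":")
  if (!anyDuplicated(key)) {
    tab$alt_loc <- ifelse(tab$alt_loc == "", NA_character_, tab$alt_loc)
    return(tab)
  }
  ord <- order(match(key, unique(key)), -tab$occupancy,
               ifelse(tab$alt_loc == "", "A", tab$alt_loc))
  tab <- tab[ord, , drop = FALSE]
  key <- key[ord]
  tab <- tab[!duplicated(key), , drop = FALSE]
  tab <- tab[order(tab$serial), , drop = FALSE]
  tab$alt_loc <- NA_character_
  rownames(tab) <- NULL
  tab
}

split_pdb_models <- function(lines) {
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L)
    return(list(list(model = 1L, idx = which(is_atom))))
  model_ends <- which(startsWith(lines, "ENDMDL"))
  lapply(seq_along(model_starts), function(i) {
    num <- suppressWarnings(as.integer(substr(lines[model_starts[i]], 11L, 14L)))
    if (is.na(num)) num <- i
    end <- model_ends[model_ends > model_starts[i]]
    end <- if (length(end)) end[1L] else length(lines) + 1L
    span <- seq(model_starts[i] + 1L, end - 1L)
    list(model = num, idx = span[is_atom[span]])
  })
}

#' Read a structure from a PDB file
#'
#' Parses fixed-width ATOM/HETATM records of the requested MODEL (default:
#' the first). Elements are inferred from the atom-name columns when the
#' element field is blank, so calcium HETATM ions stay distinguishable from
#' alpha-carbons. Alternate locations are collapsed to the highest-occupancy
#' conformer (ties toward 'A').
#'
#' @param path path to a PDB file.
#' @param model model number to read (matched against MODEL records).
#' @return a \code{\link{new_structure}} object.
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  models <- split_pdb_models(lines)
  nums <- vapply(models, `[[`, integer(1), "model")
  pick <- which(nums == as.integer(model))
  if (length(pick) == 0L)
    stop(sprintf("model %d not present; available models: %s",
                 as.integer(model), paste(nums, collapse = ", ")),
         call. = FALSE)
  idx <- models[[pick[1L]]]$idx
  if (length(idx) == 0L)
    stop("no ATOM/HETATM records found in ", path, call. = FALSE)
  tab <- collapse_altloc(parse_pdb_atom_lines(lines[idx], idx))
  new_structure(tab[, c("serial", "atom_name", "residue_name", "chain_id",
                        "residue_number", "element", "alt_loc", "hetatm")],
                cbind(tab$x, tab$y, tab$z),
                source = basename(path), model = as.integer(model))
}

#' Read a trajectory
#'
#' Multi-MODEL PDB: each MODEL block is one frame and all blocks must share
#' atom count and order; the topology is taken from the first model.
#' xyz-table: a whitespace-separated table with a header line and columns
#' \code{frame atom x y z}; the topology must be supplied.
#'
#' @param path path to the trajectory file.
#' @param format \code{"pdb"} (multi-MODEL) or \code{"xyz"} (xyz-table).
#' @param topology a \code{trn_structure}; required for \code{format = "xyz"}.
#' @return a \code{\link{new_trajectory}} object.
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz"), topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "xyz") return(read_xyz_table(path, topology))
  lines <- readLines(path, warn = FALSE)
  models <- split_pdb_models(lines)
  tabs <- lapply(models, function(m)
    collapse_altloc(parse_pdb_atom_lines(lines[m$idx], m$idx)))
  a0 <- nrow(tabs[[1L]])
  for (i in seq_along(tabs)) {
    if (nrow(tabs[[i]]) != a0)
      stop(sprintf(
        "model %d has %d atoms but model %d has %d: frame atom counts differ",
        models[[i]]$model, nrow(tabs[[i]]), models[[1L]]$model, a0),
        call. = FALSE)
  }
  topo <- new_structure(
    tabs[[1L]][, c("serial", "atom_name", "residue_name", "chain_id",
                   "residue_number", "element", "alt_loc", "hetatm")],
    cbind(tabs[[1L]]$x, tabs[[1L]]$y, tabs[[1L]]$z),
    source = basename(path), model = models[[1L]]$model)
  coords <- array(NA_real_, c(length(tabs), a0, 3L))
  for (i in seq_along(tabs))
    coords[i, , ] <- cbind(tabs[[i]]$x, tabs[[i]]$y, tabs[[i]]$z)
  new_trajectory(topo, coords)
}

read_xyz_table <- function(path, topology) {
  if (is.null(topology))
    stop("read_trajectory(format = 'xyz') needs a `topology` structure",
         call. = FALSE)
  stopifnot(inherits(topology, "trn_structure"))
  tab <- utils::read.table(path, header = TRUE)
  needed <- c("frame", "atom", "x", "y", "z")
  if (!all(needed %in% names(tab)))
    stop("xyz-table must have header columns: frame atom x y z", call. = FALSE)
  frames <- sort(unique(tab$frame))
  a <- nrow(topology$atoms)
  coords <- array(NA_real_, c(length(frames), a, 3L))
  for (i in seq_along(frames)) {
    sub <- tab[tab$frame == frames[i], , drop = FALSE]
    if (nrow(sub) != a || !setequal(sub$atom, seq_len(a)))
      stop(sprintf("xyz-table frame %d does not cover atoms 1..%d exactly",
                   frames[i], a), call. = FALSE)
    sub <- sub[order(sub$atom), , drop = FALSE]
    coords[i, , ] <- cbind(sub$x, sub$y, sub$z)
  }
  new_trajectory(topology, coords)
}

fmt_atom_name <- function(name, element) {
  if (nchar(name) >= 4L) return(substr(name, 1L, 4L))
  if (nchar(element) == 2L) return(formatC(name, width = -4L))
  formatC(paste0(" ", name), width = -4L)
}

pdb_atom_line <- function(atoms, xyz, i) {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (atoms$hetatm[i]) "HETATM" else "ATOM",
          atoms$serial[i] %% 100000L,
          fmt_atom_name(atoms$atom_name[i], atoms$element[i]),
          if (is.na(atoms$alt_loc[i])) " " else atoms$alt_loc[i],
          atoms$residue_name[i],
          atoms$chain_id[i],
          atoms$residue_number[i],
          xyz[i, 1L], xyz[i, 2L], xyz[i, 3L],
          1, 0,
          toupper(atoms$element[i]))
}

#' Write a trajectory
#'
#' PDB output uses MODEL/ENDMDL framing with the fixed-width 3-decimal
#' coordinate convention; coordinates that do not fit the 8-column field
#' raise an error instead of being silently truncated. xyz-table output is
#' the whitespace dialect read by \code{\link{read_trajectory}}.
#'
#' @param traj a \code{trn_trajectory}.
#' @param path output file path.
#' @param format \code{"pdb"} or \code{"xyz"}.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz")) {
  stopifnot(inherits(traj, "trn_trajectory"))
  format <- match.arg(format)
  f <- n_frames(traj)
  a <- nrow(traj$topology$atoms)
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("frame atom x y z", con)
    for (fr in seq_len(f)) {
      xyz <- matrix(traj$coords[fr, , ], a, 3L)
      writeLines(sprintf("%d %d %.6f %.6f %.6f",
                         fr, seq_len(a), xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    }
    return(invisible(path))
  }
  if (max(traj$coords) > 9999.999 || min(traj$coords) < -999.999)
    stop("coordinate exceeds the PDB 8-column field width; refusing to truncate",
         call. = FALSE)
  atoms <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in seq_len(f)) {
    writeLines(sprintf("MODEL     %4d", fr), con)
    xyz <- matrix(traj$coords[fr, , ], a, 3L)
    writeLines(vapply(seq_len(a), function(i) pdb_atom_line(atoms, xyz, i),
                      character(1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single structure as a one-model PDB file
#' @param struct a \code{trn_structure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(struct, path) {
  write_trajectory(new_trajectory(struct, struct$xyz), path, format = "pdb")
}

#' Atom selection
#'
#' A declarative selection resolved against a Structure. All non-NULL
#' criteria are combined with AND. Resolution is deterministic and
#' order-preserving (topology order, never request order).
#'
#' @param chain optional chain identifier.
#' @param residue_range optional inclusive \code{c(lo, hi)} residue pair.
#' @param residue_set optional explicit set of residue numbers.
#' @param atom_names optional set of atom names, e.g. \code{"CA"}.
#' @return an object of class \code{atom_selection}.
#' @export
selection <- function(chain = NULL, residue_range = NULL, residue_set = NULL,
                      atom_names = NULL) {
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    if (residue_range[1L] > residue_range[2L])
      stop("selection: residue_range must be increasing", call. = FALSE)
  }
  structure(list(chain = chain, residue_range = residue_range,
                 residue_set = residue_set, atom_names = atom_names),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  parts <- c(
    if (!is.null(x$chain)) paste0("chain ", x$chain),
    if (!is.null(x$residue_range)) paste0("residues ", x$residue_range[1L],
                                          "-", x$residue_range[2L]),
    if (!is.null(x$residue_set)) paste0("residue set {",
                                        paste(x$residue_set, collapse = ","),
                                        "}"),
    if (!is.null(x$atom_names)) paste0("atoms {",
                                       paste(x$atom_names, collapse = ","), "}"))
  cat("selection:", if (length(parts)) paste(parts, collapse = ", ")
      else "(all atoms)", "\n")
  invisible(x)
}

#' Resolve a selection against a structure
#'
#' Residues requested explicitly (by set or range) but absent from the
#' structure are skipped with a warning carrying the count (crystal
#' structures routinely have missing residues). Indices come back in
#' topology order.
#'
#' @param struct a \code{trn_structure}.
#' @param sel an \code{\link{selection}}.
#' @param require_atoms error if fewer than this many atoms resolve.
#' @return integer vector of atom indices (possibly empty), with attribute
#'   \code{n_missing_residues}.
#' @export
resolve_selection <- function(struct, sel, require_atoms = 0L) {
  stopifnot(inherits(struct, "trn_structure"), inherits(sel, "atom_selection"))
  a <- struct$atoms
  if (nrow(a) == 0L) stop("resolve_selection: empty structure", call. = FALSE)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain_id == sel$chain
  requested <- NULL
  if (!is.null(sel$residue_range))
    requested <- seq(sel$residue_range[1L], sel$residue_range[2L])
  if (!is.null(sel$residue_set))
    requested <- sort(unique(c(requested, as.integer(sel$residue_set))))
  if (!is.null(requested)) keep <- keep & a$residue_number %in% requested
  if (!is.null(sel$atom_names)) keep <- keep & a$atom_name %in% sel$atom_names
  idx <- which(keep)
  n_missing <- 0L
  if (!is.null(requested)) {
    pool <- a$residue_number[if (is.null(sel$chain)) TRUE
                             else a$chain_id == sel$chain]
    n_missing <- sum(!requested %in% pool)
    if (n_missing > 0L)
      warning(sprintf("%d requested residue(s) absent from the structure",
                      n_missing), call. = FALSE)
  }
  if (length(idx) < require_atoms)
    stop(sprintf("selection resolved %d atom(s); at least %d required",
                 length(idx), require_atoms), call. = FALSE)
  attr(idx, "n_missing_residues") <- n_missing
  idx
}

#' Chain-role map
#'
#' The crystal files do not state which chain letters carry TnC/TnI/TnT, so
#' the mapping is explicit user configuration.
#'
#' @param tnc chain id of the troponin C subunit.
#' @param tni,tnt optional chain ids of troponin I / troponin T.
#' @param calcium_het residue name(s) used by calcium HETATM ions.
#' @return an object of class \code{chain_map}.
#' @export
chain_map <- function(tnc, tni = NULL, tnt = NULL, calcium_het = "CA") {
  roles <- c(tnc = tnc, tni = tni, tnt = tnt)
  if (anyDuplicated(roles))
    stop("chain_map: roles must map to distinct chains", call. = FALSE)
  structure(list(tnc = tnc, tni = tni, tnt = tnt, calcium_het = calcium_het),
            class = "chain_map")
}

#' Validate a chain map against a structure
#' @param map a \code{chain_map}.
#' @param struct a \code{trn_structure}.
#' @return \code{map}, invisibly; errors if a mapped chain is absent.
#' @export
validate_chain_map <- function(map, struct) {
  stopifnot(inherits(map, "chain_map"), inherits(struct, "trn_structure"))
  chains <- unique(struct$atoms$chain_id)
  for (role in c("tnc", "tni", "tnt")) {
    ch <- map[[role]]
    if (!is.null(ch) && !ch %in% chains)
      stop(sprintf("chain_map: role %s maps to chain '%s' absent from structure",
                   role, ch), call. = FALSE)
  }
  invisible(map)
}

#' Count calcium ions in a structure
#' @param struct a \code{trn_structure}.
#' @return integer number of Ca HETATM ions.
#' @export
count_calcium_ions <- function(struct) {
  stopifnot(inherits(struct, "trn_structure"))
  sum(struct$atoms$hetatm & struct$atoms$element == "Ca")
}
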