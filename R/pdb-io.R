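#' Read a (multi-model) PDB file as a trajectory
#'
#' Parses `ATOM`/`HETATM`/`MODEL`/`ENDMDL` records. Each `MODEL` block becomes
#' one frame; a file without `MODEL` records yields a single-frame trajectory.
#' Water (`HOH`/`WAT`/`DOD`) and, by default, all other `HETATM` records are
#' stripped; hydrogens are stripped under the united-atom radii convention.
#' Alternate locations are reduced to a single copy per atom.
#'
#' @param path Path to a PDB file.
#' @param model_policy `"all"` (default) keeps every MODEL as a frame,
#'   `"first"` keeps only the first.
#' @param altloc_policy `"highest-occupancy"` (default) keeps the altloc copy
#'   with maximal occupancy (ties broken by altloc letter order); `"A"` keeps
#'   altloc blank or `"A"` only.
#' @param keep_hetatm Keep non-water `HETATM` records (e.g. ions)? Default
#'   `FALSE`.
#' @param radii Named radii vector from [vdw_radii()].
#' @param default_radius Fallback radius for elements absent from `radii`;
#'   `NULL` (default) makes unknown elements an error.
#' @param times Optional numeric vector of frame times (ps/ns); defaults to
#'   `0:(n_frames-1)`. Must be strictly increasing.
#' @return A `trajectory`: list with `frames` (list of `structure_model`) and
#'   `times`.
#' @seealso [write_pdb()], [select_chains()], [calpha_coordinates()]
#' @export
load_structure <- function(path,
                           model_policy = c("all", "first"),
                           altloc_policy = c("highest-occupancy", "A"),
                           keep_hetatm = FALSE,
                           radii = vdw_radii(),
                           default_radius = NULL,
                           times = NULL) {
  model_policy <- match.arg(model_policy)
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stopf("no ATOM records in %s", path)

  # Assign a model index to every line: 0 before any MODEL record.
  model_idx <- cumsum(rec == "MODEL ")
  atom_lines <- lines[is_atom]
  atom_model <- model_idx[is_atom]
  if (all(atom_model == 0L)) atom_model <- rep(1L, length(atom_model))

  frames_ids <- sort(unique(atom_model))
  if (model_policy == "first") frames_ids <- frames_ids[1]

  parse_block <- function(bl, frame_index) {
    field <- function(from, to) trimws(substr(bl, from, to))
    atoms <- data.frame(
      record   = trimws(substr(bl, 1, 6)),
      atom     = field(13, 16),
      altloc   = substr(bl, 17, 17),
      resname  = field(18, 20),
      chain    = trimws(substr(bl, 22, 22)),
      resno    = as.integer(field(23, 26)),
      insert   = trimws(substr(bl, 27, 27)),
      x        = as.numeric(field(31, 38)),
      y        = as.numeric(field(39, 46)),
      z        = as.numeric(field(47, 54)),
      occupancy = suppressWarnings(as.numeric(field(55, 60))),
      element  = field(77, 78),
      stringsAsFactors = FALSE
    )
    atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
    # Element fallback: first alphabetic character of the atom name.
    noel <- atoms$element == ""
    if (any(noel)) {
      atoms$element[noel] <- toupper(sub("^[0-9']*([A-Za-z]).*$", "\\1", atoms$atom[noel]))
    }
    atoms$element <- toupper(atoms$element)

    water <- atoms$resname %in% c("HOH", "WAT", "DOD")
    atoms <- atoms[!water, , drop = FALSE]
    if (!keep_hetatm) atoms <- atoms[atoms$record != "HETATM", , drop = FALSE]
    atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
    if (nrow(atoms) == 0L) stopf("no atoms left after filtering in %s", path)

    # Altloc reduction to one copy per (chain, resno, insert, atom name).
    if (any(atoms$altloc != " ")) {
      if (altloc_policy == "A") {
        atoms <- atoms[atoms$altloc %in% c(" ", "A"), , drop = FALSE]
      } else {
        key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "\r")
        keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
          if (length(idx) == 1L) return(idx)
          occ <- atoms$occupancy[idx]
          best <- idx[occ == max(occ)]
          best[order(atoms$altloc[best])][1]
        }), use.names = FALSE)
        atoms <- atoms[sort(keep), , drop = FALSE]
      }
    }
    atoms$altloc <- NULL
    atoms$record <- NULL
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
      stopf("non-finite coordinates in %s", path)
    }
    atoms$vdw_radius <- assign_radii(atoms$element, radii, default_radius)
    new_structure_model(atoms, frame_index = frame_index,
                        source_label = basename(path),
                        radii_table = attr(radii, "radii_table") %||% "custom")
  }

  frames <- lapply(seq_along(frames_ids), function(i) {
    parse_block(atom_lines[atom_model == frames_ids[i]], frame_index = i - 1L)
  })

  if (length(frames) > 1L) {
    ref <- frames[[1]]$atoms
    for (f in frames[-1]) {
      if (nrow(f$atoms) != nrow(ref) ||
          !identical(paste(f$atoms$chain, f$atoms$resno, f$atoms$atom),
                     paste(ref$chain, ref$resno, ref$atom))) {
        stopf("MODEL blocks in %s differ in atom identity; not a trajectory", path)
      }
    }
  }
  if (is.null(times)) times <- as.numeric(seq_along(frames) - 1L)
  new_trajectory(frames, times)
}

new_structure_model <- function(atoms, frame_index = 0L, source_label = "",
                                radii_table = "heavy4") {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate (chain, residue, atom) identity in frame")
  structure(list(atoms = atoms, frame_index = as.integer(frame_index),
                 source_label = source_label, radii_table = radii_table),
            class = "structure_model")
}

new_trajectory <- function(frames, times) {
  if (length(times) != length(frames)) stopf("times length must match frame count")
  if (length(times) > 1L && any(diff(times) <= 0)) stopf("frame times must be strictly increasing")
  structure(list(frames = frames, times = as.numeric(times)), class = "trajectory")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, chains: %s (frame %d, %s; radii: %s)\n",
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = ""),
              x$frame_index, x$source_label, x$radii_table))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frame(s) x %d atoms, t = [%g, %g]\n",
              length(x$frames), nrow(x$frames[[1]]$atoms),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Write a structure or trajectory to PDB
#'
#' Multi-frame trajectories are written as `MODEL`/`ENDMDL` blocks.
#'
#' @param x A `structure_model` or `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (i in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    a <- frames[[i]]$atoms
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(a)),
                     ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
                     a$resname, a$chain, a$resno,
                     ifelse(a$insert == "", " ", a$insert),
                     a$x, a$y, a$z, a$occupancy, 0, a$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Subset a structure to selected chains
#'
#' @param model A `structure_model`.
#' @param chains Character vector of chain identifiers; all must be present.
#' @return A `structure_model` with only the requested chains, order preserved.
#' @export
select_chains <- function(model, chains) {
  stopifnot(inherits(model, "structure_model"))
  present <- unique(model$atoms$chain)
  absent <- setdiff(chains, present)
  if (length(absent)) stopf("chain(s) not present: %s", paste(absent, collapse = ", "))
  out <- model
  out$atoms <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Alpha-carbon coordinates of a structure
#'
#' One entry per residue possessing a `CA` atom, in file order. Residues
#' lacking a `CA` are skipped with a warning.
#'
#' @param model A `structure_model`.
#' @return Data frame with columns `chain`, `resno`, `insert`, `x`, `y`, `z`.
#' @export
calpha_coordinates <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  reskey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  ca <- a[a$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stopf("structure has no CA atoms")
  missing <- setdiff(unique(reskey), paste(ca$chain, ca$resno, ca$insert, sep = "\r"))
  if (length(missing)) {
    warnf("%d residue(s) lack a CA atom and were skipped", length(missing))
  }
  out <- ca[, c("chain", "resno", "insert", "x", "y", "z")]
  rownames(out) <- NULL
  out
}
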