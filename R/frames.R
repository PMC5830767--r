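# Membrane configuration frames.
#
# A frame holds Cartesian coordinates in Angstrom with z along the
# bilayer normal, plus atom/residue bookkeeping and an orthorhombic
# box. Lateral coordinates are wrapped into [0, Lx) x [0, Ly) on
# construction; z is kept unwrapped because profiles are bilayer
# centred.

KNOWN_RESNAMES <- c("DMPC", "CHOL", "ASA", "SOL")

#' Construct a membrane configuration frame
#'
#' @param positions N x 3 numeric matrix of coordinates in Angstrom,
#'   z along the bilayer normal.
#' @param atom_names Character vector of atom names (length N).
#' @param res_names Residue names per atom (`DMPC`, `CHOL`, `ASA`,
#'   `SOL`; unknown names are kept with a warning).
#' @param res_ids Integer residue ids per atom.
#' @param box Box lengths `c(Lx, Ly, Lz)` in Angstrom, all positive.
#' @param elements Optional chemical elements per atom; inferred from
#'   the first alphabetic character of the atom name when `NULL`.
#' @return An object of class `membrane_frame`.
#' @export
membrane_frame <- function(positions, atom_names, res_names, res_ids, box,
                           elements = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, length(atom_names) == n,
            length(res_names) == n, length(res_ids) == n, length(box) == 3L)
  box <- as.numeric(box)
  if (any(!is.finite(box)) || any(box <= 0)) stop("box lengths must be positive")
  unknown <- setdiff(unique(res_names), KNOWN_RESNAMES)
  if (length(unknown))
    warning("unknown residue name(s) retained: ", paste(unknown, collapse = ", "))
  if (is.null(elements)) elements <- infer_element(atom_names)
  positions[, 1L] <- positions[, 1L] %% box[1L]
  positions[, 2L] <- positions[, 2L] %% box[2L]
  structure(list(positions = positions, atom_names = as.character(atom_names),
                 res_names = as.character(res_names),
                 res_ids = as.integer(res_ids), box = box,
                 elements = as.character(elements)),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  census <- table(x$res_names[!duplicated(x$res_ids)])
  cat(sprintf("<membrane_frame> %d atoms, %d residues, box %.1f x %.1f x %.1f A\n",
              nrow(x$positions), length(unique(x$res_ids)),
              x$box[1L], x$box[2L], x$box[3L]))
  cat("  residues:", paste(sprintf("%s=%d", names(census), census), collapse = ", "), "\n")
  invisible(x)
}

infer_element <- function(atom_names) {
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", sub("^[0-9]+", "", atom_names)), 1L, 1L))
  el[el == ""] <- "C"
  el
}

#' Read membrane frames from coordinate files
#'
#' Accepts files in the GRO (fixed-width, nm) or PDB conventions;
#' GRO coordinates are converted to Angstrom. A multi-model PDB file
#' yields one frame per model. A PDB file whose coordinates all fall
#' below 10 A triggers a unit-sanity warning (nm-scale values
#' mislabelled as Angstrom are a common hand-off error).
#'
#' @param paths Character vector of file paths.
#' @return A list of [membrane_frame] objects.
#' @export
read_frames <- function(paths) {
  out <- list()
  for (p in paths) {
    ext <- tolower(tools::file_ext(p))
    fr <- if (ext == "gro") list(read_gro(p)) else read_pdb_frames(p)
    out <- c(out, fr)
  }
  out
}

# GRO convention: title, atom count, fixed-width atom lines
# (resid+resname, atom name, index, x y z in nm), box line in nm.
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2L]))
  if (is.na(n)) stop("bad GRO atom count in ", path)
  at <- lines[3L:(2L + n)]
  boxline <- trimws(lines[3L + n])
  if (!nzchar(boxline)) stop("missing box record in GRO file ", path)
  box <- as.numeric(strsplit(boxline, "\\s+")[[1L]])[1:3] * 10
  if (anyNA(box)) stop("missing box record in GRO file ", path)
  res_ids <- as.integer(substr(at, 1L, 5L))
  res_names <- trimws(substr(at, 6L, 10L))
  atom_names <- trimws(substr(at, 11L, 15L))
  xyz <- cbind(as.numeric(substr(at, 21L, 28L)),
               as.numeric(substr(at, 29L, 36L)),
               as.numeric(substr(at, 37L, 44L))) * 10
  if (anyNA(xyz)) stop("malformed coordinate field in GRO file ", path)
  membrane_frame(xyz, atom_names, res_names, res_ids, box)
}

read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  cry <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cry)) stop("missing CRYST1 box record in PDB file ", path)
  box <- as.numeric(c(substr(cry[1L], 7, 15), substr(cry[1L], 16, 24),
                      substr(cry[1L], 25, 33)))
  xyz <- pdb$xyz
  nm <- if (is.matrix(xyz)) nrow(xyz) else 1L
  frames <- vector("list", nm)
  for (i in seq_len(nm)) {
    co <- matrix(if (is.matrix(xyz)) xyz[i, ] else as.numeric(xyz),
                 ncol = 3L, byrow = TRUE)
    if (max(abs(co)) < 10)
      warning("all coordinates < 10 A in ", path,
              ": possible nm-scale values mislabelled as Angstrom")
    frames[[i]] <- membrane_frame(co, a$elety, a$resid, a$resno, box)
  }
  frames
}

#' Write a frame in the GRO convention
#'
#' Coordinates and box are emitted in nm with the standard fixed-width
#' layout, so the file round-trips through [read_frames()].
#'
#' @param frame A [membrane_frame].
#' @param path Output path (conventionally `.gro`).
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "membrane frame") {
  stopifnot(inherits(frame, "membrane_frame"))
  n <- nrow(frame$positions)
  nm <- frame$positions / 10
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     frame$res_ids %% 100000L, frame$res_names,
                     substr(frame$atom_names, 1L, 5L), seq_len(n) %% 100000L,
                     nm[, 1L], nm[, 2L], nm[, 3L]),
             sprintf("%10.5f%10.5f%10.5f", frame$box[1L] / 10,
                     frame$box[2L] / 10, frame$box[3L] / 10))
  writeLines(lines, path)
  invisible(path)
}

#' Select atom indices in a frame
#'
#' @param frame A [membrane_frame].
#' @param resname Optional residue name(s) to keep.
#' @param name Optional regular expression matched against atom names.
#' @param element Optional element symbol(s) to keep.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(frame, resname = NULL, name = NULL, element = NULL) {
  keep <- rep(TRUE, nrow(frame$positions))
  if (!is.null(resname)) keep <- keep & frame$res_names %in% resname
  if (!is.null(name)) keep <- keep & grepl(name, frame$atom_names)
  if (!is.null(element)) keep <- keep & frame$elements %in% element
  which(keep)
}

# z of the bilayer midplane: centre of mass (unit weights) of lipid atoms
bilayer_centre <- function(frame) {
  idx <- which(frame$res_names %in% c("DMPC", "CHOL"))
  if (!length(idx)) idx <- seq_len(nrow(frame$positions))
  mean(frame$positions[idx, 3L])
}

# per-residue reference points used for leaflet assignment and grids:
# DMPC -> phosphorus, CHOL -> hydroxyl oxygen, ASA -> lateral centre of
# mass (all-bead mean); falls back to the residue mean position.
reference_points <- function(frame, species = c("DMPC", "CHOL", "ASA")) {
  keep <- frame$res_names %in% species
  rid <- frame$res_ids[keep]
  rn <- frame$res_names[keep]
  pos <- frame$positions[keep, , drop = FALSE]
  nm <- frame$atom_names[keep]
  el <- frame$elements[keep]
  ids <- unique(rid)
  out <- matrix(NA_real_, length(ids), 3L)
  spc <- character(length(ids))
  for (i in seq_along(ids)) {
    sel <- rid == ids[i]
    spc[i] <- rn[sel][1L]
    sub <- pos[sel, , drop = FALSE]
    ref <- switch(spc[i],
      DMPC = {
        p <- which(el[sel] == "P")
        if (length(p)) sub[p[1L], ] else colMeans(sub)
      },
      CHOL = {
        o <- which(el[sel] == "O")
        if (length(o)) sub[o[1L], ] else colMeans(sub)
      },
      colMeans(sub))
    # lateral mean must respect periodicity: use circular mean in x, y
    if (is.null(dim(ref))) out[i, ] <- ref
  }
  # periodic-safe centre for multi-atom references (ASA / fallbacks)
  for (i in seq_along(ids)) {
    sel <- rid == ids[i]
    if (sum(sel) > 1L && spc[i] %in% c("ASA", "SOL")) {
      sub <- pos[sel, , drop = FALSE]
      out[i, 1L] <- circular_mean(sub[, 1L], frame$box[1L])
      out[i, 2L] <- circular_mean(sub[, 2L], frame$box[2L])
      out[i, 3L] <- mean(sub[, 3L])
    }
  }
  data.frame(res_id = ids, species = spc,
             x = out[, 1L] %% frame$box[1L],
             y = out[, 2L] %% frame$box[2L], z = out[, 3L])
}

circular_mean <- function(x, L) {
  th <- x / L * 2 * pi
  (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * L) %% L
}

# leaflet tag per reference point: +1 above midplane, -1 below
leaflet_of <- function(z, z0) ifelse(z >= z0, 1L, -1L)
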