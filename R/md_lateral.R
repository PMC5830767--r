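# Lateral-organization analyses of membrane configuration frames:
# per-leaflet radial distribution functions, grid-based area per lipid
# (GridMAT-style), distance-resolved area and gauche profiles around
# the drug, density/SLD profiles along the bilayer normal, and
# close-contact statistics. All analysis paths are deterministic.

ELECTRONS <- c(H = 1, D = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
# coherent scattering lengths, fm
BCOH <- c(H = -3.739, D = 6.671, C = 6.6511, N = 9.37, O = 5.803,
          P = 5.13, S = 2.847)

min_image <- function(d, L) d - round(d / L) * L

resolve_selection <- function(frame, sel) {
  if (is.function(sel)) return(sel(frame))
  if (is.numeric(sel)) return(as.integer(sel))
  do.call(select_atoms, c(list(frame = frame), sel))
}

#' Radial distribution function, lateral or 3D
#'
#' Lateral mode computes in-plane (x, y) minimum-image pair distances
#' restricted to pairs in the same leaflet, normalised by the ideal 2D
#' density so that g(r) -> 1 for a homogeneous system; 3D mode uses
#' standard spherical-shell normalisation. Pairs within the same
#' residue are excluded by default, and the result is averaged over
#' frames.
#'
#' @param frames A list of [membrane_frame] objects (or one frame).
#' @param group_a,group_b Selections: a list of [select_atoms()]
#'   arguments (e.g. `list(resname = "DMPC", name = "^C[12]")`), an
#'   index vector, or a function of the frame.
#' @param r_max Maximum distance (A); must not exceed half the smallest
#'   lateral box length in lateral mode.
#' @param bin_width Bin width in A (default 0.2).
#' @param mode `"lateral_2d"` (default) or `"full_3d"`.
#' @param same_leaflet Restrict to same-leaflet pairs in lateral mode
#'   (default TRUE).
#' @param exclude_same_residue Drop intramolecular pairs (default TRUE).
#' @return An object of class `rdf_result`: data frame with `r` (bin
#'   centres) and `g`, plus metadata.
#' @export
lateral_rdf <- function(frames, group_a, group_b, r_max = 25,
                        bin_width = 0.2,
                        mode = c("lateral_2d", "full_3d"),
                        same_leaflet = TRUE, exclude_same_residue = TRUE) {
  mode <- match.arg(mode)
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  box <- frames[[1L]]$box
  if (mode == "lateral_2d" && r_max > min(box[1:2]) / 2)
    stop(sprintf("r_max = %.3g exceeds half the smallest lateral box length (%.3g A)",
                 r_max, min(box[1:2]) / 2))
  edges <- seq(0, r_max, by = bin_width)
  H <- numeric(length(edges) - 1L)
  norm <- 0
  for (fr in frames) {
    ia <- resolve_selection(fr, group_a)
    ib <- resolve_selection(fr, group_b)
    if (!length(ia) || !length(ib)) stop("empty atom selection")
    z0 <- bilayer_centre(fr)
    if (mode == "lateral_2d" && same_leaflet) {
      la <- leaflet_of(fr$positions[ia, 3L], z0)
      lb <- leaflet_of(fr$positions[ib, 3L], z0)
      for (lf in c(1L, -1L)) {
        sa <- ia[la == lf]; sb <- ib[lb == lf]
        if (!length(sa) || !length(sb)) next
        acc <- rdf_accumulate(fr, sa, sb, edges, mode, exclude_same_residue)
        H <- H + acc$hist
        norm <- norm + acc$norm
      }
    } else {
      acc <- rdf_accumulate(fr, ia, ib, edges, mode, exclude_same_residue)
      H <- H + acc$hist
      norm <- norm + acc$norm
    }
  }
  r_mid <- edges[-length(edges)] + bin_width / 2
  shell <- if (mode == "lateral_2d")
    pi * (edges[-1L]^2 - edges[-length(edges)]^2)
  else
    4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  g <- if (norm > 0) H / (norm * shell) else rep(NA_real_, length(r_mid))
  structure(list(r = r_mid, g = g, bin_width = bin_width, mode = mode,
                 n_frames = length(frames)),
            class = "rdf_result")
}

rdf_accumulate <- function(fr, sa, sb, edges, mode, exclude_same_residue) {
  box <- fr$box
  pa <- fr$positions[sa, , drop = FALSE]
  pb <- fr$positions[sb, , drop = FALSE]
  dx <- min_image(outer(pa[, 1L], pb[, 1L], "-"), box[1L])
  dy <- min_image(outer(pa[, 2L], pb[, 2L], "-"), box[2L])
  d2 <- dx^2 + dy^2
  if (mode == "full_3d") {
    dz <- min_image(outer(pa[, 3L], pb[, 3L], "-"), box[3L])
    d2 <- d2 + dz^2
  }
  mask <- outer(sa, sb, "==")                       # identical atoms
  if (exclude_same_residue)
    mask <- mask | outer(fr$res_ids[sa], fr$res_ids[sb], "==")
  d <- sqrt(d2[!mask])
  h <- graphics::hist(d[d < max(edges)], breaks = edges, plot = FALSE)$counts
  area_or_vol <- if (mode == "lateral_2d") box[1L] * box[2L] else prod(box)
  rho_b <- length(sb) / area_or_vol
  list(hist = h, norm = length(sa) * rho_b)
}

#' @export
print.rdf_result <- function(x, ...) {
  pk <- x$r[which.max(x$g)]
  cat(sprintf("<rdf_result> %s, %d bins to %.1f A over %d frame(s); first max near r = %.2f A\n",
              x$mode, length(x$r), max(x$r) + x$bin_width / 2, x$n_frames, pk))
  invisible(x)
}

#' Grid-based area per lipid (GridMAT-style)
#'
#' The lateral plane of each leaflet is tessellated into square cells
#' (<= 0.5 A); every cell is claimed by the nearest same-leaflet
#' reference point under the periodic minimum image (DMPC: phosphorus;
#' CHOL: hydroxyl oxygen). A lipid's area is its cell count times the
#' cell area, so the claimed areas in a leaflet sum exactly to Lx * Ly.
#'
#' @param frame A [membrane_frame].
#' @param cell_size Grid cell edge in A (default 0.5, the maximum).
#' @param policy `"dmpc_only"` (CHOL claims its cells but only DMPC
#'   areas are reported as lipid areas) or `"chol_as_lipid"` (CHOL rows
#'   reported alongside DMPC).
#' @param species Residue names whose reference points claim cells.
#' @return An object of class `area_map`: data frame `areas` with
#'   `res_id`, `species`, `leaflet`, `area`, plus `cell_size`, `box`,
#'   `policy`.
#' @export
grid_area_map <- function(frame, cell_size = 0.5,
                          policy = c("dmpc_only", "chol_as_lipid"),
                          species = c("DMPC", "CHOL")) {
  policy <- match.arg(policy)
  if (cell_size > 0.5) stop("cell_size must be <= 0.5 A")
  refs <- reference_points(frame, species)
  if (!nrow(refs)) stop("no reference points for species ",
                        paste(species, collapse = ", "))
  z0 <- bilayer_centre(frame)
  refs$leaflet <- leaflet_of(refs$z, z0)
  box <- frame$box
  nx <- max(2L, round(box[1L] / cell_size))
  ny <- max(2L, round(box[2L] / cell_size))
  csx <- box[1L] / nx; csy <- box[2L] / ny
  gx <- (seq_len(nx) - 0.5) * csx
  gy <- (seq_len(ny) - 0.5) * csy
  cells <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  out <- list()
  for (lf in c(1L, -1L)) {
    rr <- refs[refs$leaflet == lf, , drop = FALSE]
    if (!nrow(rr)) {
      if (!nrow(refs[refs$leaflet == -lf, ])) stop("empty leaflet")
      next
    }
    dx <- min_image(outer(cells[, 1L], rr$x, "-"), box[1L])
    dy <- min_image(outer(cells[, 2L], rr$y, "-"), box[2L])
    nearest <- max.col(-(dx^2 + dy^2), ties.method = "first")
    cnt <- tabulate(nearest, nbins = nrow(rr))
    out[[length(out) + 1L]] <- data.frame(
      res_id = rr$res_id, species = rr$species, leaflet = lf,
      area = cnt * csx * csy)
  }
  areas <- do.call(rbind, out)
  structure(list(areas = areas, cell_size = cell_size, box = box,
                 policy = policy),
            class = "area_map")
}

#' Per-lipid areas reported under the map's species policy
#'
#' @param map An `area_map`.
#' @return Data frame of reported lipid areas.
#' @export
lipid_areas <- function(map) {
  a <- map$areas
  if (map$policy == "dmpc_only") a <- a[a$species == "DMPC", , drop = FALSE]
  a
}

# lateral distance from each DMPC reference to its nearest same-leaflet
# ASA reference; returns data.frame(res_id, leaflet, dist)
dmpc_asa_distances <- function(frame) {
  refs <- reference_points(frame, c("DMPC", "ASA"))
  if (!any(refs$species == "ASA")) stop("frame contains no ASA residues")
  z0 <- bilayer_centre(frame)
  refs$leaflet <- leaflet_of(refs$z, z0)
  dm <- refs[refs$species == "DMPC", , drop = FALSE]
  out <- dm[, c("res_id", "leaflet")]
  out$dist <- NA_real_
  for (lf in unique(dm$leaflet)) {
    asa <- refs[refs$species == "ASA" & refs$leaflet == lf, , drop = FALSE]
    sel <- dm$leaflet == lf
    if (!nrow(asa)) next
    dx <- min_image(outer(dm$x[sel], asa$x, "-"), frame$box[1L])
    dy <- min_image(outer(dm$y[sel], asa$y, "-"), frame$box[2L])
    out$dist[sel] <- sqrt(apply(dx^2 + dy^2, 1L, min))
  }
  out
}

#' Area per DMPC at increasing distance from the drug
#'
#' For every frame, each DMPC's grid area ([grid_area_map()]) is
#' accumulated into the half-open distance bin `[lo, hi)` matching its
#' lateral distance to the nearest same-leaflet ASA reference point;
#' bins are averaged over frames.
#'
#' @param frames List of [membrane_frame] objects containing ASA.
#' @param bins Bin edges in A (default `seq(0, 30, 2)`).
#' @param cell_size Grid cell size for the area map.
#' @return An object of class `radial_profile` with columns `r_lo`,
#'   `r_hi`, `statistic` (mean area, A^2), `counts`.
#' @export
distance_resolved_area <- function(frames, bins = seq(0, 30, by = 2),
                                   cell_size = 0.5) {
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  nb <- length(bins) - 1L
  tot <- cnt <- numeric(nb)
  for (fr in frames) {
    d <- dmpc_asa_distances(fr)
    am <- lipid_areas(grid_area_map(fr, cell_size = cell_size))
    a <- am$area[match(d$res_id, am$res_id)]
    bi <- findInterval(d$dist, bins, rightmost.closed = FALSE)
    ok <- !is.na(d$dist) & bi >= 1L & bi <= nb & !is.na(a)
    tot <- tot + as.numeric(tapply(a[ok], factor(bi[ok], levels = seq_len(nb)),
                                   sum, default = 0))
    cnt <- cnt + tabulate(bi[ok], nbins = nb)
  }
  radial_profile(bins, ifelse(cnt > 0, tot / cnt, NA_real_), cnt,
                 statistic_name = "area_per_dmpc")
}

radial_profile <- function(bins, statistic, counts, statistic_name) {
  if (missing(statistic_name)) statistic_name <- "statistic"
  structure(data.frame(r_lo = bins[-length(bins)], r_hi = bins[-1L],
                       statistic = statistic, counts = counts),
            statistic = statistic_name,
            class = c("radial_profile", "data.frame"))
}

#' Gauche fraction of chain dihedrals
#'
#' Classifies dihedral angles as gauche when |phi| < 120 degrees in the
#' IUPAC convention (trans at +/- 180). Angles supplied in the
#' Ryckaert-Bellemans convention (trans at 0) are converted first, so
#' the classification is convention-independent. Invariant under
#' phi -> -phi.
#'
#' @param angles Dihedral angles in degrees, in (-180, 180].
#' @param convention `"iupac"` (default) or `"rb"`.
#' @return Fraction of gauche dihedrals.
#' @export
gauche_fraction <- function(angles, convention = c("iupac", "rb")) {
  convention <- match.arg(convention)
  if (!length(angles)) stop("empty dihedral input")
  if (any(angles <= -180 - 1e-9) || any(angles > 180 + 1e-9))
    stop("angles must lie in (-180, 180] degrees")
  if (convention == "rb") {
    angles <- angles - 180
    angles <- ((angles + 180) %% 360) - 180
    angles[angles == -180] <- 180
  }
  mean(abs(angles) < 120)
}

# IUPAC dihedral angles (degrees, trans = +/-180) for bead quadruples;
# p1..p4 are n x 3 matrices
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- vcross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

vcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# all chain dihedrals of one DMPC residue in a frame, per tail;
# tail atoms follow the C1x (sn1) / C2x (sn2) naming with the chain
# order given by the name's trailing characters
chain_dihedrals <- function(frame, res_id,
                            tail_patterns = c(sn1 = "^C1", sn2 = "^C2")) {
  sel <- which(frame$res_ids == res_id)
  out <- list()
  for (tag in names(tail_patterns)) {
    idx <- sel[grepl(tail_patterns[[tag]], frame$atom_names[sel])]
    if (length(idx) < 4L) {
      stop("residue ", res_id, " has no resolvable ", tag,
           " chain (atom pattern ", tail_patterns[[tag]], ")")
    }
    idx <- idx[order(frame$atom_names[idx])]
    p <- frame$positions[idx, , drop = FALSE]
    n <- nrow(p)
    # unwrap: consecutive beads are bonded, so lateral jumps are
    # periodic-image artifacts
    for (i in 2:n) {
      p[i, 1L] <- p[i - 1L, 1L] + min_image(p[i, 1L] - p[i - 1L, 1L], frame$box[1L])
      p[i, 2L] <- p[i - 1L, 2L] + min_image(p[i, 2L] - p[i - 1L, 2L], frame$box[2L])
    }
    out[[tag]] <- dihedral_angle(p[1:(n - 3L), , drop = FALSE],
                                 p[2:(n - 2L), , drop = FALSE],
                                 p[3:(n - 1L), , drop = FALSE],
                                 p[4:n, , drop = FALSE])
  }
  out
}

#' Gauche fraction at increasing distance from the drug
#'
#' Shell membership of each DMPC (lateral distance to the nearest
#' same-leaflet ASA reference, half-open bins) is recomputed every
#' `stride` frames, mirroring index-file regeneration in trajectory
#' tools; chain dihedrals of member lipids are classified with
#' [gauche_fraction()] every frame, the SN1 and SN2 tails are averaged,
#' and bins are accumulated over all frames.
#'
#' @param frames List of [membrane_frame] objects containing ASA.
#' @param bins Distance bin edges in A (default `seq(0, 30, 2)`).
#' @param stride Frames between membership updates (default 50).
#' @param tail_patterns Named regex pair selecting the two tails.
#' @return A `radial_profile` whose statistic is the gauche fraction.
#' @export
distance_resolved_gauche <- function(frames, bins = seq(0, 30, by = 2),
                                     stride = 50L,
                                     tail_patterns = c(sn1 = "^C1",
                                                       sn2 = "^C2")) {
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  if (stride > length(frames))
    message("stride (", stride, ") exceeds frame count (", length(frames),
            "); shell membership evaluated once")
  nb <- length(bins) - 1L
  g1 <- n1 <- g2 <- n2 <- matrix(0, nb, 1L)
  membership <- NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (is.null(membership) || (i - 1L) %% stride == 0L) {
      d <- dmpc_asa_distances(fr)
      d$bin <- findInterval(d$dist, bins, rightmost.closed = FALSE)
      membership <- d[!is.na(d$dist) & d$bin >= 1L & d$bin <= nb, ]
    }
    for (j in seq_len(nrow(membership))) {
      di <- chain_dihedrals(fr, membership$res_id[j], tail_patterns)
      b <- membership$bin[j]
      g1[b] <- g1[b] + sum(abs(di$sn1) < 120); n1[b] <- n1[b] + length(di$sn1)
      g2[b] <- g2[b] + sum(abs(di$sn2) < 120); n2[b] <- n2[b] + length(di$sn2)
    }
  }
  f1 <- ifelse(n1 > 0, g1 / n1, NA_real_)
  f2 <- ifelse(n2 > 0, g2 / n2, NA_real_)
  radial_profile(bins, as.numeric((f1 + f2) / 2), as.numeric(n1 + n2),
                 statistic_name = "gauche_fraction")
}

#' Density profile along the bilayer normal
#'
#' Histograms each group's atoms along z (bilayer centred at z = 0),
#' weighted by electrons per element or by coherent neutron scattering
#' length (fm), with hydrogens in `deuteration_map` selections treated
#' as deuterium. Densities are per volume (weight / (Lx Ly dz)),
#' averaged over frames; the integral of an electron-mode profile times
#' the lateral box area recovers each group's total electron count.
#'
#' @param frames List of [membrane_frame] objects.
#' @param groups Named list of selections (see [lateral_rdf()]).
#' @param weighting `"electron"` or `"neutron_sl"`.
#' @param deuteration_map Optional list of selections whose H atoms are
#'   treated as deuterium (neutron mode).
#' @param bin_width z bin width in A (<= 1).
#' @param symmetrise Average rho(z) with rho(-z) (default FALSE).
#' @return An object of class `density_profile`: `z` (bin centres) and
#'   a column per group in `density`.
#' @export
density_profile <- function(frames, groups,
                            weighting = c("electron", "neutron_sl"),
                            deuteration_map = NULL, bin_width = 1,
                            symmetrise = FALSE) {
  weighting <- match.arg(weighting)
  if (bin_width > 1) stop("bin_width must be <= 1 A")
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  Lz <- frames[[1L]]$box[3L]
  edges <- seq(-Lz / 2, Lz / 2, by = bin_width)
  mids <- edges[-length(edges)] + bin_width / 2
  dens <- matrix(0, length(mids), length(groups),
                 dimnames = list(NULL, names(groups)))
  for (fr in frames) {
    z0 <- bilayer_centre(fr)
    area <- fr$box[1L] * fr$box[2L]
    deut <- logical(nrow(fr$positions))
    if (!is.null(deuteration_map))
      for (sel in deuteration_map)
        deut[resolve_selection(fr, sel)] <- TRUE
    el <- fr$elements
    el[deut & el == "H"] <- "D"
    wt_tab <- if (weighting == "electron") ELECTRONS else BCOH
    unknown <- setdiff(unique(el), names(wt_tab))
    if (length(unknown))
      stop("unknown element(s): ", paste(unknown, collapse = ", "))
    wt <- wt_tab[el]
    for (gname in names(groups)) {
      idx <- resolve_selection(fr, groups[[gname]])
      zz <- min_image(fr$positions[idx, 3L] - z0, fr$box[3L])
      bi <- findInterval(zz, edges, rightmost.closed = TRUE)
      bi[bi < 1L] <- 1L; bi[bi > length(mids)] <- length(mids)
      acc <- tapply(wt[idx], factor(bi, levels = seq_along(mids)), sum,
                    default = 0)
      dens[, gname] <- dens[, gname] +
        as.numeric(acc) / (area * bin_width * length(frames))
    }
  }
  if (symmetrise) dens <- (dens + dens[rev(seq_len(nrow(dens))), , drop = FALSE]) / 2
  structure(list(z = mids, density = dens, weighting = weighting,
                 bin_width = bin_width, n_frames = length(frames)),
            class = "density_profile")
}

#' Close-contact statistics between two species
#'
#' For every A-B residue pair, counts frames in which any heavy-atom
#' (non-hydrogen) pair lies within `cutoff` under the 3D minimum image,
#' and reports the per-pair time fraction plus per-frame contact-pair
#' counts. The default 3.5 A cutoff is a donor/acceptor heavy-atom
#' proxy for hydrogen bonding.
#'
#' @param frames List of [membrane_frame] objects.
#' @param group_a,group_b Selections (see [lateral_rdf()]).
#' @param cutoff Contact distance in A (> 0; default 3.5).
#' @return List with `pairs` (data frame `res_a`, `res_b`,
#'   `time_fraction`), `per_frame` (contact-pair count per frame) and
#'   `n_frames`.
#' @export
contact_fraction <- function(frames, group_a, group_b, cutoff = 3.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  tallies <- new.env(parent = emptyenv())
  per_frame <- integer(length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    ia <- resolve_selection(fr, group_a)
    ib <- resolve_selection(fr, group_b)
    ia <- ia[fr$elements[ia] != "H"]
    ib <- ib[fr$elements[ib] != "H"]
    if (!length(ia) || !length(ib)) stop("empty heavy-atom selection")
    box <- fr$box
    dx <- min_image(outer(fr$positions[ia, 1L], fr$positions[ib, 1L], "-"), box[1L])
    dy <- min_image(outer(fr$positions[ia, 2L], fr$positions[ib, 2L], "-"), box[2L])
    dz <- min_image(outer(fr$positions[ia, 3L], fr$positions[ib, 3L], "-"), box[3L])
    close <- (dx^2 + dy^2 + dz^2) <= cutoff^2
    close <- close & !outer(fr$res_ids[ia], fr$res_ids[ib], "==")
    hit <- which(close, arr.ind = TRUE)
    if (nrow(hit)) {
      pr <- unique(data.frame(a = fr$res_ids[ia][hit[, 1L]],
                              b = fr$res_ids[ib][hit[, 2L]]))
      per_frame[k] <- nrow(pr)
      for (j in seq_len(nrow(pr))) {
        key <- paste(pr$a[j], pr$b[j], sep = "_")
        tallies[[key]] <- (tallies[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(tallies)
  pairs <- if (length(keys)) {
    sp <- do.call(rbind, strsplit(keys, "_"))
    data.frame(res_a = as.integer(sp[, 1L]), res_b = as.integer(sp[, 2L]),
               time_fraction = vapply(keys, function(k) tallies[[k]], 0L) /
                 length(frames))
  } else data.frame(res_a = integer(), res_b = integer(),
                    time_fraction = numeric())
  rownames(pairs) <- NULL
  list(pairs = pairs, per_frame = per_frame, n_frames = length(frames))
}
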