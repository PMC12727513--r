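#' Binding-pocket enforcement: placeholder helix, guiding potential, burial
#'
#' During generative backbone scaffolding, a temporary ideal helix marks the
#' substrate entry channel, and a flat-bottom distance potential on all
#' backbone atoms keeps the denoising trajectory centred on it; the helix is
#' stripped afterwards, leaving a vacant pocket. This module provides the
#' helix placement geometry, the potential with analytic gradients (as a
#' pure-function callback contract for an external diffusion wrapper), the
#' ligand burial metric and protein-ligand clash counting.
#'
#' @name pocket
NULL

## ideal helix backbone as atom table plus CA-fitted axis
.helix_geometry <- function(length) {
  bb <- .build_backbone(rep(-57, length), rep(-47, length))
  ca <- as.matrix(bb[bb$atom == "CA", c("x", "y", "z")])
  cen <- colMeans(ca)
  pc <- svd(sweep(ca, 2, cen))$v[, 1]
  # orient axis from first to last residue
  if (sum((ca[nrow(ca), ] - ca[1, ]) * pc) < 0) pc <- -pc
  list(backbone = bb, axis = pc, center = cen, ca = ca)
}

.new_channel_helix <- function(backbone, length, axis, chain_id = "X") {
  structure(list(backbone = backbone, length = length, axis = axis,
                 chain_id = chain_id), class = "ChannelHelix")
}

#' Place the entry-channel placeholder helix
#'
#' Builds an ideal alpha-helix whose axis runs from the catalytic
#' functional-atom centroid through the ligand heavy-atom centroid, with its
#' near end `standoff` Angstrom beyond the ligand centroid, and searches a
#' deterministic grid of axial rotations (30 degree steps) and additional
#' offsets (1 Angstrom steps up to 5) for a placement that does not clash
#' with the motif or the ligand.
#'
#' @param assembly MotifAssembly
#' @param ligand ligand atom table (`atom`, `x`, `y`, `z`, `element`)
#' @param length helix length in residues
#' @param standoff initial distance from ligand centroid to the helix near
#'   end (Angstrom)
#' @param params [clash_params()]
#' @param chain_id reserved placeholder chain label
#' @return [ChannelHelix]
#' @export
place_channel_helix <- function(assembly, ligand, length = 9, standoff = 4,
                                params = clash_params(), chain_id = "X") {
  stopifnot(length(assembly$placements) >= 1)
  lig <- ligand[.is_heavy(ligand$element), , drop = FALSE]
  if (nrow(lig) == 0L) stop("ligand has no heavy atoms")
  fcen <- colMeans(do.call(rbind, lapply(assembly$placements, function(p) {
    side <- p$rebuilt_residue[.is_heavy(p$rebuilt_residue$element) &
                                !p$rebuilt_residue$atom %in% c("N", "CA", "C", "O"), ]
    as.matrix(side[, c("x", "y", "z")])
  })))
  lcen <- colMeans(as.matrix(lig[, c("x", "y", "z")]))
  axis <- .unit(lcen - fcen)
  geo <- .helix_geometry(length)
  motif_atoms <- do.call(rbind, lapply(assembly$placements, .placement_atoms))
  obstacles <- rbind(motif_atoms[, c("atom", "x", "y", "z", "element")],
                     lig[, c("atom", "x", "y", "z", "element")])
  # rotate canonical helix axis onto the target axis
  v <- .cross(geo$axis, axis)
  s <- .vnorm(v); cth <- sum(geo$axis * axis)
  R0 <- if (s < 1e-12) {
    if (cth > 0) diag(3) else .axis_rotation(if (abs(axis[1]) < 0.9) .cross(axis, c(1, 0, 0)) else .cross(axis, c(0, 1, 0)), 180)
  } else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  bbm <- as.matrix(geo$backbone[, c("x", "y", "z")])
  ca0 <- geo$ca[1, ]  # near end reference (first CA)
  # two unit vectors perpendicular to the axis, for the tilt fallback
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp1 <- .unit(.cross(axis, ref))
  perp2 <- .cross(axis, perp1)
  tilts <- list(c(0, 0))
  for (t1 in c(-20, -10, 10, 20)) tilts <- c(tilts, list(c(t1, 0), c(0, t1)))
  for (tilt in tilts) {
    ax <- .unit(as.numeric(.axis_rotation(perp1, tilt[1]) %*%
                             .axis_rotation(perp2, tilt[2]) %*% axis))
    Rt <- if (all(tilt == 0)) R0 else {
      v2 <- .cross(geo$axis, ax); s2 <- .vnorm(v2); c2 <- sum(geo$axis * ax)
      if (s2 < 1e-12) R0 else {
        K2 <- matrix(c(0, v2[3], -v2[2], -v2[3], 0, v2[1], v2[2], -v2[1], 0), 3, 3)
        diag(3) + K2 + K2 %*% K2 * ((1 - c2) / s2^2)
      }
    }
    for (extra in 0:5) {
      for (rot in seq(0, 330, by = 30)) {
        R <- .axis_rotation(ax, rot) %*% Rt
        target_near <- lcen + ax * (standoff + extra)
        t_ <- target_near - as.numeric(R %*% ca0)
        xyz <- .apply_transform(bbm, R, t_)
        bb <- geo$backbone
        bb$x <- xyz[, 1]; bb$y <- xyz[, 2]; bb$z <- xyz[, 3]
        cc <- clash_check(bb[, c("atom", "x", "y", "z", "element")], obstacles,
                          params)
        if (cc$count == 0L) {
          return(.new_channel_helix(bb, length, ax, chain_id))
        }
      }
    }
  }
  stop("no clash-free placeholder-helix placement found within search budget ",
       "(rotations 0-330 deg, offsets 0-5 A, tilts up to 20 deg)")
}

#' Point on the helix axis at a fractional position
#'
#' @param helix [ChannelHelix]
#' @param fraction position along the axis segment in [0, 1]; 0 is the axis
#'   point nearest the first residue.
#' @return 3-vector (Angstrom)
#' @export
pocket_center <- function(helix, fraction = 0.5) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  ca <- as.matrix(helix$backbone[helix$backbone$atom == "CA", c("x", "y", "z")])
  cen <- colMeans(ca)
  proj <- as.numeric((ca - matrix(cen, nrow(ca), 3, byrow = TRUE)) %*% helix$axis)
  lo <- cen + min(proj) * helix$axis
  hi <- cen + max(proj) * helix$axis
  lo + fraction * (hi - lo)
}

#' Flat-bottom pocket guiding potential
#'
#' `E = weight * sum_i max(0, d_i - r0)^2` with `d_i = |x_i - center|`, plus
#' the analytic gradient `2 * weight * (d_i - r0) * (x_i - center) / d_i`
#' outside the flat region and zero inside. A pure function of the
#' coordinates, suitable as a per-step auxiliary potential callback for an
#' external backbone-diffusion wrapper. An atom exactly at the center gets
#' zero gradient by convention.
#'
#' @param backbone_coords N x 3 matrix of backbone atom positions (Angstrom)
#' @param params list with `center` (3-vector), `flat_radius` (r0 > 0),
#'   `weight` (>= 0); see [pocket_potential_params()]
#' @return list with `energy` (scalar) and `gradient` (N x 3)
#' @export
pocket_potential <- function(backbone_coords, params) {
  x <- as.matrix(backbone_coords)
  stopifnot(nrow(x) >= 1, params$flat_radius > 0, params$weight >= 0)
  dx <- sweep(x, 2, params$center)
  d <- sqrt(rowSums(dx^2))
  excess <- pmax(0, d - params$flat_radius)
  grad <- matrix(0, nrow(x), 3)
  out <- which(excess > 0 & d > 0)
  if (length(out)) {
    grad[out, ] <- 2 * params$weight * (excess[out] / d[out]) * dx[out, , drop = FALSE]
  }
  list(energy = params$weight * sum(excess^2), gradient = grad)
}

#' Pocket potential parameters
#' @param center 3-vector, typically from [pocket_center()]
#' @param flat_radius flat-bottom radius r0 (Angstrom, > 0)
#' @param weight energy units per square Angstrom (>= 0)
#' @export
pocket_potential_params <- function(center, flat_radius = 12, weight = 1) {
  stopifnot(length(center) == 3, flat_radius > 0, weight >= 0)
  list(center = as.numeric(center), flat_radius = flat_radius, weight = weight)
}

#' Ligand burial: alpha-carbons near the substrate
#'
#' Counts protein CA atoms with minimum distance `<= cutoff` (inclusive) to
#' any ligand heavy atom, normalized by the number of ligand heavy atoms.
#' Natural enzymes bury their substrates deeply by this measure.
#'
#' @param s [Structure] of the protein-ligand complex
#' @param ligand_selection `"chain:resno"` spec of the ligand residue
#' @param cutoff distance cutoff (Angstrom, default 8)
#' @param model model number
#' @return list (`BurialReport`): `n_calpha_within_cutoff`,
#'   `n_ligand_heavy`, `cutoff`, `burial`
#' @export
burial_score <- function(s, ligand_selection, cutoff = 8, model = NULL) {
  a <- .model_atoms(s, model)
  spec <- .parse_resspec(ligand_selection)
  lig <- a[a$chain == spec$chain & a$resno == spec$resno, , drop = FALSE]
  if (nrow(lig) == 0L) stop("ligand not found: ", ligand_selection)
  lig <- lig[.is_heavy(lig$element), , drop = FALSE]
  if (nrow(lig) == 0L) stop("ligand has no heavy atoms: ", ligand_selection)
  prot <- a[!(a$chain == spec$chain & a$resno == spec$resno) &
              a$resname %in% .std_aa & a$atom == "CA", , drop = FALSE]
  nca <- neighbor_count(as.matrix(prot[, c("x", "y", "z")]),
                        as.matrix(lig[, c("x", "y", "z")]), cutoff)
  list(n_calpha_within_cutoff = nca, n_ligand_heavy = nrow(lig),
       cutoff = cutoff, burial = nca / nrow(lig))
}

#' Clashes between protein backbone and ligand
#'
#' @inheritParams burial_score
#' @param params [clash_params()]
#' @return as [clash_check()]
#' @export
ligand_clash_count <- function(s, ligand_selection, params = clash_params(),
                               model = NULL) {
  a <- .model_atoms(s, model)
  spec <- .parse_resspec(ligand_selection)
  lig <- a[a$chain == spec$chain & a$resno == spec$resno, , drop = FALSE]
  if (nrow(lig) == 0L) stop("ligand not found: ", ligand_selection)
  lig <- lig[.is_heavy(lig$element), , drop = FALSE]
  bb <- a[!(a$chain == spec$chain & a$resno == spec$resno) &
            a$resname %in% .std_aa &
            a$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
  clash_check(bb[, c("atom", "x", "y", "z", "element")],
              lig[, c("atom", "x", "y", "z", "element")], params)
}

#' Remove the placeholder helix chain
#'
#' Drops every residue of the given chain in all models; nothing else is
#' touched (no renumbering).
#'
#' @param s [Structure]
#' @param chain_id placeholder chain label
#' @return [Structure]
#' @export
strip_placeholder <- function(s, chain_id) {
  if (!chain_id %in% s$atoms$chain) stop("chain not present: ", chain_id)
  .new_structure(s$atoms[s$atoms$chain != chain_id, , drop = FALSE],
                 header = s$header)
}

#' Add a channel helix to a Structure as its placeholder chain
#' @param s [Structure]
#' @param helix [ChannelHelix]
#' @return [Structure] with the helix appended (resname GLY)
#' @export
add_channel_helix <- function(s, helix) {
  bb <- helix$backbone
  add <- data.frame(model = s$atoms$model[1], record = "ATOM",
                    serial = NA_integer_, atom = bb$atom, altloc = " ",
                    resname = "GLY", chain = helix$chain_id, resno = bb$resno,
                    icode = " ", x = bb$x, y = bb$y, z = bb$z, occ = 1, b = 0,
                    element = bb$element, stringsAsFactors = FALSE)
  .new_structure(rbind(s$atoms, add), header = s$header)
}
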