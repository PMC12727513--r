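#' Seeded synthetic-data generators
#'
#' Every module in the package is testable offline: these generators build
#' toy rotamer libraries, ideal helical fragments, small constructed
#' catalytic arrays with placeholder ligands, jittered conformational
#' ensembles and synthetic metric/kinetics tables, all pure functions of
#' their seed (identical config gives byte-identical artifacts). The
#' geometries are constructed from ideal internal coordinates, not copied
#' from any deposited structure.
#'
#' @name fixtures
NULL

#' Toy backbone-dependent rotamer library
#'
#' Covers Lys/Tyr/Asn/His/Glu/Arg/Ser with at least two rotamers in the
#' alpha-helical (phi, psi) bin; per-bin probabilities are normalized to
#' sum to 1. Chi means are placed near canonical gauche/trans positions
#' with a small seeded perturbation.
#'
#' @param seed integer seed
#' @param n_rotamers rotamers per (identity, bin)
#' @param bin_width degrees
#' @param extra_bins additional (phi, psi) bin centers to populate beyond
#'   the helical bin
#' @return [rotamer_library()]
#' @export
make_toy_rotamer_library <- function(seed = 1, n_rotamers = 3, bin_width = 10,
                                     extra_bins = list(c(-120, 130))) {
  identities <- c("LYS", "TYR", "ASN", "HIS", "GLU", "ARG", "SER")
  bins <- c(list(c(-57, -47)), extra_bins)
  self_clash_free <- function(id, chi) {
    res <- build_sidechain_forward(id, chi = chi)
    beyond <- res[!res$atom %in% c("N", "CA", "C", "O", "CB") &
                    .is_heavy(res$element), ]
    bb <- res[res$atom %in% c("N", "C", "O"), ]
    clash_check(beyond, bb)$count == 0L
  }
  withr::with_seed(seed, {
    rows <- list()
    for (id in identities) {
      nch <- n_chi(id)
      # canonical gauche/trans chi patterns, walked in a fixed order; a
      # pattern is kept only if the jittered rotamer builds without
      # folding back onto its own backbone
      patterns <- as.matrix(expand.grid(rep(list(c(-60, 180, 60)),
                                            nch))[, nch:1, drop = FALSE])
      for (b in bins) {
        probs <- rev(sort(stats::runif(n_rotamers)))
        probs <- probs / sum(probs)
        taken <- 0L
        for (pi in seq_len(nrow(patterns))) {
          chi <- .wrap180(patterns[pi, ] + stats::runif(nch, -8, 8))
          if (!self_clash_free(id, chi)) next
          taken <- taken + 1L
          row <- data.frame(identity = id, phi = b[1], psi = b[2],
                            chi1 = NA_real_, chi2 = NA_real_,
                            chi3 = NA_real_, chi4 = NA_real_,
                            prob = probs[taken], stringsAsFactors = FALSE)
          row[, paste0("chi", seq_len(nch))] <- chi
          rows[[length(rows) + 1L]] <- row
          if (taken == n_rotamers) break
        }
        if (taken < n_rotamers) {
          stop("could not find ", n_rotamers, " self-consistent rotamers for ",
               id)
        }
      }
    }
    rotamer_library(do.call(rbind, rows), bin_width = bin_width)
  })
}

#' Ideal alpha-helical fragment
#'
#' Convenience wrapper over [helical_fragment()] with ideal helix dihedrals
#' (phi -57, psi -47).
#'
#' @param length residues (>= 3)
#' @param abundance fragment weight
#' @export
make_ideal_helix <- function(length = 7, abundance = 1) {
  helical_fragment(length = length, phi = -57, psi = -47,
                   abundance = abundance,
                   id = sprintf("ideal_helix_%d", length))
}

## rigid-place a template-built residue so `tip` lands on `tip_target` with
## the CA->tip direction along `direction`, rolled by `roll` degrees
.place_residue_at <- function(identity, chi, tip, tip_target, direction, roll) {
  res <- build_sidechain_forward(identity, chi = chi)
  xyz <- as.matrix(res[, c("x", "y", "z")])
  rownames(xyz) <- res$atom
  v <- .unit(xyz[tip, ] - xyz["CA", ])
  w <- .unit(direction)
  axis <- .cross(v, w); s <- .vnorm(axis)
  R <- if (s < 1e-9) diag(3) else {
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - sum(v * w)) / s^2)
  }
  R <- .axis_rotation(w, roll) %*% R
  t_ <- tip_target - as.numeric(R %*% xyz[tip, ])
  moved <- .apply_transform(xyz, R, t_)
  res$x <- moved[, 1]; res$y <- moved[, 2]; res$z <- moved[, 3]
  res
}

#' Constructed toy catalytic arrays
#'
#' `"ra_tetrad"`: Lys + Tyr + Asn + Tyr arranged around a small placeholder
#' ketol ligand, with the lysine amine poised at the carbonyl and the
#' tyrosine/asparagine functional groups at H-bond distance (2.6-3.2
#' Angstrom) of the ligand oxygens -- the retro-aldolase active-site
#' pattern. `"mbh_triad"`: His (nucleophile) + Glu (H-bonded to the
#' histidine ring nitrogen) + Arg (oxyanion stabilizer) around a two-part
#' enone/aldehyde ligand -- the Morita-Baylis-Hillman pattern. Geometry is
#' built from ideal internal coordinates; `seed` only jitters the roll
#' angles (default 0 jitter keeps it fully deterministic).
#'
#' @param kind `"ra_tetrad"` or `"mbh_triad"`
#' @param seed integer seed (recorded; construction is deterministic)
#' @return [catalytic_array()] with `$ligand` set
#' @export
make_toy_catalytic_array <- function(kind = c("ra_tetrad", "mbh_triad"),
                                     seed = 1) {
  kind <- match.arg(kind)
  lig <- function(atom, x, y, z, element, resno = 1L) {
    data.frame(atom = atom, x = x, y = y, z = z, element = element,
               resname = "LIG", resno = resno, stringsAsFactors = FALSE)
  }
  if (kind == "ra_tetrad") {
    ligand <- rbind(
      lig("C1", 0.00, 0.00, 0.00, "C"),
      lig("O1", 1.23, 0.00, 0.30, "O"),
      lig("C2", -0.80, 1.25, 0.00, "C"),
      lig("C3", -0.80, -1.25, 0.00, "C"),
      lig("O2", -2.10, -1.40, 0.55, "O"))
    lcen <- colMeans(as.matrix(ligand[, c("x", "y", "z")]))
    o1 <- c(1.23, 0.00, 0.30); o2 <- c(-2.10, -1.40, 0.55)
    place <- function(identity, tip, target, dirv, roll) {
      .place_residue_at(identity, template_chi(identity), tip, target,
                        .unit(dirv), roll)
    }
    specs <- list(
      list(id = "LYS", tip = "NZ", target = o1 + 2.90 * .unit(c(1.0, 0.4, 1.2)),
           roll = 40),
      list(id = "TYR", tip = "OH", target = o2 + 2.80 * .unit(c(-1.0, -0.6, 1.0)),
           roll = -30),
      list(id = "ASN", tip = "ND2", target = o1 + 2.95 * .unit(c(0.4, -1.2, -1.0)),
           roll = 100),
      list(id = "TYR", tip = "OH", target = o2 + 2.85 * .unit(c(-0.3, -0.8, -1.4)),
           roll = 180))
    labels <- c("toy K1", "toy Y2", "toy N3", "toy Y4")
  } else {
    ligand <- rbind(
      lig("C1", 0.00, 0.00, 0.00, "C", 1L),
      lig("O1", 1.22, 0.00, 0.35, "O", 1L),
      lig("C2", -0.75, 1.25, 0.00, "C", 1L),
      lig("C3", -1.45, 2.45, 0.10, "C", 1L),
      lig("C4", 3.40, 1.80, 0.20, "C", 2L),
      lig("O4", 4.40, 2.30, 0.80, "O", 2L),
      lig("C5", 3.60, 0.45, -0.40, "C", 2L))
    lcen <- colMeans(as.matrix(ligand[, c("x", "y", "z")]))
    c3 <- c(-1.45, 2.45, 0.10); o1 <- c(1.22, 0.00, 0.35)
    o4 <- c(4.40, 2.30, 0.80)
    his <- .place_residue_at("HIS", template_chi("HIS"), "NE2",
                             c3 + 3.00 * .unit(c(-1.0, 0.8, 0.9)),
                             -.unit(c(-1.0, 0.8, 0.9)), 30)
    hx <- as.matrix(his[, c("x", "y", "z")]); rownames(hx) <- his$atom
    nd1 <- hx["ND1", ]
    # glutamate carboxylate H-bonded to the histidine ND1
    glu_dir <- .unit(nd1 - lcen + c(0, 0, 1.3))
    glu <- .place_residue_at("GLU", template_chi("GLU"), "OE1",
                             nd1 + 2.80 * glu_dir, -glu_dir, -60)
    arg_dir <- .unit(c(0.9, -0.9, 1.1))
    arg <- .place_residue_at("ARG", template_chi("ARG"), "NH1",
                             o1 + 2.95 * arg_dir, -arg_dir, 150)
    residues <- list(
      catalytic_residue("HIS", .residue_fa(his, "HIS"), "toy H1"),
      catalytic_residue("GLU", .residue_fa(glu, "GLU"), "toy E2"),
      catalytic_residue("ARG", .residue_fa(arg, "ARG"), "toy R3"))
    return(catalytic_array(residues, ligand = ligand,
                           name = paste0("toy_", kind)))
  }
  residues <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    res <- .place_residue_at(sp$id, template_chi(sp$id), sp$tip, sp$target,
                             .unit(lcen - sp$target), sp$roll)
    catalytic_residue(sp$id, .residue_fa(res, sp$id), labels[i])
  })
  catalytic_array(residues, ligand = ligand, name = paste0("toy_", kind))
}

## functional-atom matrix of a placed full-atom residue
.residue_fa <- function(res, identity) {
  nm <- functional_atoms_default(identity)
  xyz <- as.matrix(res[match(nm, res$atom), c("x", "y", "z")])
  rownames(xyz) <- nm
  xyz
}

#' Jittered conformational ensemble
#'
#' Adds seeded isotropic Gaussian noise (sd `sigma`) to every atom of the
#' base structure, once per frame. `sigma = 0` yields identical frames.
#'
#' @param base single-model [Structure]
#' @param n_frames number of models to generate
#' @param sigma noise sd (Angstrom, >= 0)
#' @param seed integer seed
#' @return multi-model [Structure]
#' @export
make_ensemble <- function(base, n_frames = 10, sigma = 0.2, seed = 1) {
  stopifnot(sigma >= 0, n_frames >= 1)
  a0 <- .model_atoms(base)
  withr::with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      a <- a0
      a$model <- f
      if (sigma > 0) {
        n <- nrow(a)
        a$x <- a$x + stats::rnorm(n, sd = sigma)
        a$y <- a$y + stats::rnorm(n, sd = sigma)
        a$z <- a$z + stats::rnorm(n, sd = sigma)
      }
      a
    })
    .new_structure(do.call(rbind, frames))
  })
}

#' Synthetic parameter-recovery tables
#'
#' Generates rows from a named generating model with seeded noise and
#' returns the ground truth alongside, for fit-recovery tests.
#'
#' \describe{
#' \item{stability}{design metrics drawn uniformly, midpoints linear in the
#'   four predictors plus Gaussian noise (`noise` in M GdnHCl).}
#' \item{mm}{a 1:1 substrate dilution series (8 points from 1 mM), rates
#'   from the Michaelis-Menten model with multiplicative Gaussian noise.}
#' \item{two_pka}{pH 4.6 to 10.6 in 0.4 steps, bell-shaped two-pKa profile
#'   with multiplicative noise.}
#' \item{design_metrics}{per-design metric table (pLDDT, energy, SAP, core
#'   contacts, motif RMSDs) with independent seeded variation.}
#' }
#'
#' @param kind table kind
#' @param truth named list of generating parameters (defaults supplied)
#' @param noise noise level (sd; multiplicative for mm/two_pka)
#' @param n number of rows/designs where applicable
#' @param seed integer seed
#' @return list with `table` and `truth`
#' @export
make_synthetic_tables <- function(kind = c("stability", "mm", "two_pka",
                                           "design_metrics"),
                                  truth = list(), noise = 0, n = 30, seed = 1) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    switch(kind,
      stability = {
        tr <- utils::modifyList(
          list(intercept = 1.5,
               coefficients = c(energy_total = -0.02, plddt_avg = 0.05,
                                sap_total = -0.1, core_contacts = 0.15)), truth)
        tab <- data.frame(
          energy_total = stats::runif(n, -300, -100),
          plddt_avg = stats::runif(n, 60, 95),
          sap_total = stats::runif(n, 0, 20),
          core_contacts = stats::runif(n, 10, 30))
        tab$midpoint <- tr$intercept +
          as.matrix(tab) %*% tr$coefficients[names(tab)] +
          stats::rnorm(n, sd = noise)
        tab$midpoint <- as.numeric(tab$midpoint)
        list(table = tab, truth = tr)
      },
      mm = {
        tr <- utils::modifyList(list(kcat = 0.036, km = 1e-4), truth)
        s <- 1e-3 / 2^(0:7)
        v <- tr$kcat * s / (tr$km + s)
        if (noise > 0) v <- v * (1 + stats::rnorm(length(s), sd = noise))
        list(table = data.frame(s_conc = s, v = pmax(v, 1e-12)), truth = tr)
      },
      two_pka = {
        tr <- utils::modifyList(list(pka1 = 7.5, pka2 = 10.0, rate_max = 1.0),
                                truth)
        ph <- seq(4.6, 10.6, by = 0.4)
        r <- tr$rate_max / (1 + 10^(tr$pka1 - ph) + 10^(ph - tr$pka2))
        if (noise > 0) r <- r * (1 + stats::rnorm(length(ph), sd = noise))
        list(table = data.frame(ph = ph, rate = pmax(r, 1e-12)), truth = tr)
      },
      design_metrics = {
        tab <- data.frame(
          design = sprintf("d%03d", seq_len(n)),
          plddt_avg = stats::runif(n, 60, 95),
          energy_total = stats::runif(n, -300, -100),
          sap_total = stats::runif(n, 0, 20),
          core_contacts = stats::runif(n, 10, 30),
          sidechain_rmsd = stats::runif(n, 0.2, 3),
          motif_backbone_rmsd = stats::runif(n, 0.1, 2),
          stringsAsFactors = FALSE)
        list(table = tab, truth = list())
      })
  })
}
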