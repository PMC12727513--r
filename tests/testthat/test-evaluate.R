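mapping_for <- function(s) {
  a <- s$atoms
  keys <- unique(a[a$resname %in% rsk:::.std_aa & a$atom == "CA",
                   c("chain", "resno")])
  data.frame(model_chain = keys$chain, model_resno = keys$resno,
             ref_chain = keys$chain, ref_resno = keys$resno)
}

test_that("motif_rmsd is zero on self and handles symmetric namings", {
  s <- fx("complex")
  map <- mapping_for(s)
  for (sel in c("ca", "backbone", "sidechain-heavy", "functional-group")) {
    expect_equal(motif_rmsd(s, s, map, sel), 0, tolerance = 1e-9)
  }
  # tyrosine ring relabel CD1<->CD2 / CE1<->CE2 leaves the RMSD unchanged
  flipped <- s
  tyr <- flipped$atoms$resname == "TYR"
  nm <- flipped$atoms$atom
  swap <- function(nm, a, b) {
    i <- nm == a & tyr; j <- nm == b & tyr
    nm[i] <- b; nm[j] <- a
    nm
  }
  nm <- swap(nm, "CD1", "CD2"); nm <- swap(nm, "CE1", "CE2")
  flipped$atoms$atom <- nm
  expect_equal(motif_rmsd(flipped, s, map, "sidechain-heavy"), 0,
               tolerance = 1e-9)
  # a real perturbation is detected
  pert <- s
  k <- which(pert$atoms$atom == "OH")[1]
  pert$atoms$x[k] <- pert$atoms$x[k] + 1
  expect_gt(motif_rmsd(pert, s, map, "sidechain-heavy"), 0.05)
  expect_error(motif_rmsd(s, s, data.frame(model_chain = "Q", model_resno = 1,
                                           ref_chain = "A", ref_resno = 4),
                          "ca"), "unresolvable")
})

test_that("motif_rmsd functional-group selection follows the closed form", {
  # single ASN residue: 3 functional atoms, displace one by 0.5 A
  asn <- build_sidechain_forward("ASN")
  mk <- function(res) {
    rsk:::.new_structure(data.frame(
      model = 1L, record = "ATOM", serial = NA_integer_, atom = res$atom,
      altloc = " ", resname = "ASN", chain = "A", resno = 1L, icode = " ",
      x = res$x, y = res$y, z = res$z, occ = 1, b = 0, element = res$element,
      stringsAsFactors = FALSE))
  }
  ref <- mk(asn)
  moved <- asn
  i <- which(moved$atom == "OD1")
  moved$x[i] <- moved$x[i] + 0.5
  map <- data.frame(model_chain = "A", model_resno = 1, ref_chain = "A",
                    ref_resno = 1)
  expect_equal(motif_rmsd(mk(moved), ref, map, "functional-group"),
               sqrt(0.25 / 3), tolerance = 1e-9)
})

test_that("sap_score follows the exposure-weighted hydrophobicity definition", {
  # poly-glycine helix: no sidechain heavy atoms, SAP identically zero
  bb <- rsk:::.build_backbone(rep(-57, 8), rep(-47, 8))
  pg <- rsk:::.new_structure(data.frame(
    model = 1L, record = "ATOM", serial = NA_integer_, atom = bb$atom,
    altloc = " ", resname = "GLY", chain = "A", resno = bb$resno, icode = " ",
    x = bb$x, y = bb$y, z = bb$z, occ = 1, b = 0, element = bb$element,
    stringsAsFactors = FALSE))
  sp <- sap_score(pg)
  expect_true(all(sp$per_residue$sap == 0))
  expect_equal(sp$total, 0)

  # a fully exposed phenylalanine scores positive
  phe <- build_sidechain_forward("PHE")
  mk1 <- function(res, chain = "A", shift = c(0, 0, 0)) {
    data.frame(model = 1L, record = "ATOM", serial = NA_integer_,
               atom = res$atom, altloc = " ", resname = "PHE", chain = chain,
               resno = 1L, icode = " ", x = res$x + shift[1],
               y = res$y + shift[2], z = res$z + shift[3], occ = 1, b = 0,
               element = res$element, stringsAsFactors = FALSE)
  }
  alone <- rsk:::.new_structure(mk1(phe))
  sap_alone <- sap_score(alone)
  expect_gt(sap_alone$total, 0)

  # burying it between two neighbouring copies strictly lowers the SAP
  buried <- rsk:::.new_structure(rbind(mk1(phe),
                                       mk1(phe, "B", c(0, 3.6, 0)),
                                       mk1(phe, "C", c(0, -3.6, 0))))
  res_a <- sap_score(buried)$per_residue
  expect_lt(res_a$sap[res_a$chain == "A"], sap_alone$total)
})

test_that("core_contacts measures packing density invariantly", {
  mkca <- function(i, chain, x) {
    pdb_line(i, "CA", "GLY", chain, i, x, 0, 0, element = "C")
  }
  sparse <- parse_structure(c(mkca(1, "A", 0), mkca(2, "B", 50)))
  expect_equal(as.numeric(core_contacts(sparse)), 0)

  s <- fx("complex")
  dense <- core_contacts(s)
  # pulling the chains 20 A apart strictly lowers the density
  spread <- s
  for (i in seq_along(LETTERS[1:4])) {
    sel <- spread$atoms$chain == LETTERS[i]
    spread$atoms$x[sel] <- spread$atoms$x[sel] + 20 * i
  }
  expect_lt(as.numeric(core_contacts(spread)), as.numeric(dense))
  # rigid-motion invariance
  R0 <- rsk:::.random_rotation()
  rot <- s
  xyz <- rsk:::.apply_transform(as.matrix(s$atoms[, c("x", "y", "z")]), R0,
                                c(1, 2, 3))
  rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
  expect_equal(as.numeric(core_contacts(rot)), as.numeric(dense),
               tolerance = 1e-9)
})

test_that("composite_site_metric is an exact sum of absolute deviations", {
  # constructed complexes with atoms at controlled distances
  mkat <- function(serial, name, chain, resno, x, resname = "GLY",
                   record = "ATOM", element = substr(name, 1, 1)) {
    pdb_line(serial, name, resname, chain, resno, x, 0, 0,
             element = element, record = record)
  }
  ideal <- parse_structure(c(
    mkat(1, "NZ", "A", 1, 0, "LYS"), mkat(2, "O1", "Z", 9, 2.8, "LIG", "HETATM"),
    mkat(3, "OH", "B", 2, 10, "TYR"), mkat(4, "O2", "Z", 9, 12.8, "LIG", "HETATM")))
  sub <- parse_structure(c(
    mkat(1, "NZ", "A", 1, 0, "LYS"), mkat(2, "C1", "Z", 9, 3.5, "LIG", "HETATM")))
  geo <- active_site_geometry(
    hbond_pairs = data.frame(donor = c("A:1:NZ", "B:2:OH"),
                             acceptor = c("Z:9:O1", "Z:9:O2"),
                             ideal = c(2.8, 2.8)),
    attack_pair = data.frame(nucleophile = "A:1:NZ", electrophile = "Z:9:C1",
                             ideal = 3.5))
  expect_equal(composite_site_metric(sub, ideal, geo), 0)
  # +0.3 A on one H-bond raises the score by exactly 0.3
  pert <- parse_structure(c(
    mkat(1, "NZ", "A", 1, 0, "LYS"), mkat(2, "O1", "Z", 9, 3.1, "LIG", "HETATM"),
    mkat(3, "OH", "B", 2, 10, "TYR"), mkat(4, "O2", "Z", 9, 12.8, "LIG", "HETATM")))
  expect_equal(composite_site_metric(sub, pert, geo), 0.3)
  # permutation invariance over pair ordering
  geo_r <- active_site_geometry(geo$hbond_pairs[2:1, ], geo$attack_pair)
  expect_equal(composite_site_metric(sub, pert, geo_r), 0.3)
  bad <- active_site_geometry(
    hbond_pairs = data.frame(donor = "A:1:QQ", acceptor = "Z:9:O1", ideal = 2.8),
    attack_pair = geo$attack_pair)
  expect_error(composite_site_metric(sub, ideal, bad), "A:1:QQ")
})

test_that("ensemble_metrics recovers Gaussian jitter statistics", {
  s <- fx("complex")
  sel <- data.frame(chain = c("A", "B", "C", "D"), resno = 4)
  refgeo <- assembly_reference(fx("assembly"))

  static <- make_ensemble(s, n_frames = 3, sigma = 0, seed = 1)
  em0 <- ensemble_metrics(static, sel, reference = refgeo,
                          hbond_pairs = data.frame(
                            ref_a = "A:4:NZ", ref_b = "Z:1:O1",
                            ref_distance = 2.9))
  expect_equal(em0$rmsf_per_residue$rmsf, rep(0, 4), tolerance = 1e-9)
  expect_equal(em0$fg_displacement, 0, tolerance = 1e-6)

  sigma <- 0.2
  ens <- make_ensemble(s, n_frames = 500, sigma = sigma, seed = 9)
  em <- ensemble_metrics(ens, sel, reference = refgeo)
  expected <- sigma * sqrt(3)
  for (v in em$rmsf_per_residue$rmsf) {
    expect_equal(v, expected, tolerance = 0.05 * expected / expected)
    expect_lt(abs(v - expected) / expected, 0.05)
  }
  # doubling sigma doubles the RMSF within sampling error
  ens2 <- make_ensemble(s, n_frames = 500, sigma = 2 * sigma, seed = 9)
  em2 <- ensemble_metrics(ens2, sel, reference = refgeo)
  ratio <- em2$rmsf_per_residue$rmsf / em$rmsf_per_residue$rmsf
  expect_true(all(abs(ratio - 2) < 0.2))

  # missing atom in a frame is reported with the frame number
  broken <- ens
  drop <- which(broken$atoms$model == 2)[1]
  broken$atoms <- broken$atoms[-drop, ]
  expect_error(ensemble_metrics(broken, sel), "frame 2")
})

test_that("radius of gyration and Kratky transform match closed forms", {
  # two equal-mass points at +/- d/2
  d <- 6
  two <- data.frame(atom = c("C1", "C2"), x = c(-d / 2, d / 2), y = 0, z = 0,
                    element = "C")
  expect_equal(radius_of_gyration(two), d / 2)
  # uniform solid sphere: Rg = R * sqrt(3/5) (Monte Carlo at 1e5 points)
  set.seed(99)
  R <- 10
  n <- 1e5
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * R * runif(n)^(1 / 3)
  sph <- data.frame(atom = "C", x = u[, 1], y = u[, 2], z = u[, 3],
                    element = "C")
  expect_equal(radius_of_gyration(sph), R * sqrt(3 / 5), tolerance = 0.01)
  # Guinier scatterer: dimensionless Kratky peak at qRg = sqrt(3), 3/e
  rg <- 20
  q <- seq(1e-3, 0.2, by = 1e-4)
  curve <- kratky_dimensionless(q, exp(-(q * rg)^2 / 3), rg = rg, i0 = 1)
  expect_equal(curve$qrg[which.max(curve$kratky)], sqrt(3), tolerance = 1e-2)
  expect_equal(max(curve$kratky), 3 / exp(1), tolerance = 1e-4)
  expect_error(kratky_dimensionless(numeric(0), numeric(0), 1, 1), "empty")
})
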