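test_that("toy rotamer library is normalized, deterministic and buildable", {
  rl <- make_toy_rotamer_library(seed = 1)
  e <- rl$entries
  key <- paste(e$identity, e$phi_bin, e$psi_bin)
  sums <- tapply(e$prob, key, sum)
  expect_true(all(sums <= 1 + 1e-6))
  # helical bin populated with >= 2 rotamers for every covered identity
  for (id in c("LYS", "TYR", "ASN", "HIS", "GLU", "ARG", "SER")) {
    expect_gte(length(compatible_rotamers(id, -57, -47, rl, 0)), 2L)
  }
  expect_identical(make_toy_rotamer_library(seed = 1)$entries, e)
  expect_false(identical(make_toy_rotamer_library(seed = 2)$entries, e))

  # every helical rotamer forward-builds without sidechain/backbone clash
  for (id in c("LYS", "TYR", "ASN", "HIS", "GLU", "ARG", "SER")) {
    for (rot in compatible_rotamers(id, -57, -47, rl, 0)) {
      res <- build_sidechain_forward(id, chi = rot$chi)
      beyond_cb <- res[!res$atom %in% c("N", "CA", "C", "O", "CB") &
                         rsk:::.is_heavy(res$element), ]
      backbone <- res[res$atom %in% c("N", "C", "O"), ]
      expect_equal(clash_check(beyond_cb, backbone)$count, 0L)
    }
  }

  # TSV round trip
  path <- tempfile(fileext = ".tsv")
  write_rotamer_library(rl, path)
  back <- read_rotamer_library(path)
  expect_equal(back$entries$prob, e$prob)
  expect_equal(back$entries$chi1, e$chi1, tolerance = 1e-9)
})

test_that("ideal helix satisfies fragment invariants", {
  h <- make_ideal_helix(7)
  expect_equal(h$length, 7L)
  expect_equal(h$anchor_index, 4L)
  ca <- as.matrix(h$backbone[h$backbone$atom == "CA", c("x", "y", "z")])
  dca <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dca - 3.8) < 0.1))
  # recomputed dihedrals match the targets within 1 degree
  pp <- h$phi_psi
  expect_true(all(abs(pp$phi[-1] + 57) < 1))
  expect_true(all(abs(pp$psi[-nrow(pp)] + 47) < 1))
  # rise per residue 1.5 +/- 0.1 along the fitted axis
  geo <- rsk:::.helix_geometry(9)
  proj <- as.numeric(sweep(geo$ca, 2, geo$center) %*% geo$axis)
  expect_true(all(abs(diff(proj) - 1.5) < 0.1))
  expect_error(helical_fragment(length = 2), "length")
  expect_error(helical_fragment(anchor_index = 1), "interior")

  # fragment-set TSV round trip
  path <- tempfile(fileext = ".tsv")
  write_fragment_set(list(make_ideal_helix(7), make_ideal_helix(9)), path)
  back <- read_fragment_set(path)
  expect_length(back, 2L)
  expect_equal(back[[2]]$length, 9L)
  expect_equal(as.matrix(back[[1]]$backbone[, c("x", "y", "z")]),
               as.matrix(make_ideal_helix(7)$backbone[, c("x", "y", "z")]))
})

test_that("toy catalytic arrays satisfy their geometric contracts", {
  for (kind in c("ra_tetrad", "mbh_triad")) {
    arr <- make_toy_catalytic_array(kind)
    expect_s3_class(arr, "CatalyticArray")
    # deterministic per seed
    arr2 <- make_toy_catalytic_array(kind)
    for (i in seq_along(arr$residues)) {
      expect_identical(arr$residues[[i]]$functional_atoms,
                       arr2$residues[[i]]$functional_atoms)
    }
    # residues do not clash with each other or the ligand at gamma 0.75
    dfs <- lapply(arr$residues, function(r) {
      fa <- r$functional_atoms
      data.frame(atom = rownames(fa), x = fa[, 1], y = fa[, 2], z = fa[, 3],
                 element = vapply(rownames(fa), rsk:::.guess_element, ""),
                 stringsAsFactors = FALSE)
    })
    for (i in seq_along(dfs)) {
      expect_equal(clash_check(dfs[[i]], arr$ligand)$count, 0L)
      if (i > 1) for (j in seq_len(i - 1)) {
        expect_equal(clash_check(dfs[[i]], dfs[[j]])$count, 0L)
      }
    }
  }
  # designed H-bond pairs sit in the 2.6-3.2 A window
  ra <- make_toy_catalytic_array("ra_tetrad")
  lig <- ra$ligand
  at <- function(n) unlist(lig[lig$atom == n, c("x", "y", "z")])
  fa <- function(i, n) ra$residues[[i]]$functional_atoms[n, ]
  dists <- c(sqrt(sum((fa(1, "NZ") - at("O1"))^2)),
             sqrt(sum((fa(2, "OH") - at("O2"))^2)),
             sqrt(sum((fa(3, "ND2") - at("O1"))^2)),
             sqrt(sum((fa(4, "OH") - at("O2"))^2)))
  expect_true(all(dists >= 2.6 & dists <= 3.2))
  mbh <- make_toy_catalytic_array("mbh_triad")
  glu_his <- sqrt(sum((mbh$residues[[2]]$functional_atoms["OE1", ] -
                         mbh$residues[[1]]$functional_atoms["ND1", ])^2))
  expect_gte(glu_his, 2.6); expect_lte(glu_his, 3.2)
})

test_that("make_ensemble jitter has the stated statistics", {
  s <- fx("complex")
  frozen <- make_ensemble(s, n_frames = 4, sigma = 0, seed = 1)
  a1 <- rsk:::.model_atoms(frozen, 1); a4 <- rsk:::.model_atoms(frozen, 4)
  expect_equal(a1$x, a4$x)
  # empirical per-coordinate displacement sd within 5% of sigma at 500 frames
  sigma <- 0.3
  ens <- make_ensemble(s, n_frames = 500, sigma = sigma, seed = 5)
  base <- rsk:::.model_atoms(s)
  dx <- vapply(1:500, function(m) rsk:::.model_atoms(ens, m)$x - base$x,
               numeric(nrow(base)))
  expect_lt(abs(sd(as.numeric(dx)) - sigma) / sigma, 0.05)
  # seed determinism
  expect_equal(make_ensemble(s, 3, 0.2, seed = 8)$atoms,
               make_ensemble(s, 3, 0.2, seed = 8)$atoms)
})

test_that("synthetic tables carry their generating truth", {
  mm <- make_synthetic_tables("mm", truth = list(kcat = 0.02, km = 2e-4))
  km_row <- which.min(abs(mm$table$s_conc - mm$truth$km))
  v_at_km <- mm$truth$kcat * mm$truth$km / (2 * mm$truth$km)
  expect_equal(v_at_km, mm$truth$kcat / 2)
  expect_identical(make_synthetic_tables("mm", seed = 3)$table,
                   make_synthetic_tables("mm", seed = 3)$table)
  dm <- make_synthetic_tables("design_metrics", n = 12)
  expect_equal(nrow(dm$table), 12L)
  expect_true(all(c("plddt_avg", "sidechain_rmsd") %in% names(dm$table)))
})

test_that("CLI dispatch covers the main verbs", {
  dir <- tempfile(); dir.create(dir)
  expect_equal(rsk_main(c("fixtures", "make", "ra_tetrad", "--seed", "1",
                          "--out", dir)), 0L)
  expect_true(file.exists(file.path(dir, "ra_tetrad.pdb")))
  expect_true(file.exists(file.path(dir, "rotamers.tsv")))

  pdb <- file.path(dir, "ra_tetrad.pdb")
  out <- capture.output(status <- rsk_main(c("pocket", "burial", pdb,
                                             "--ligand", "Z:1")))
  expect_equal(status, 0L)
  expect_match(out, "burial")

  out2 <- capture.output(status2 <- rsk_main(c("pocket", "check-grad",
                                               "--n", "3", "--seed", "1")))
  expect_equal(status2, 0L)

  lib_out <- file.path(dir, "library.pdb")
  out3 <- capture.output(status3 <- rsk_main(c(
    "motiflib", "build", "--array", pdb, "--ligand", "Z:1",
    "--rotlib", file.path(dir, "rotamers.tsv"),
    "--fragments", file.path(dir, "fragments.tsv"),
    "--min-prob", "0", "--out", lib_out)))
  expect_equal(status3, 0L)
  expect_true(file.exists(lib_out))
  expect_true(file.exists(file.path(dir, "library.json")))

  csv <- file.path(dir, "mm.csv")
  tab <- make_synthetic_tables("mm")$table
  write.csv(tab, csv, row.names = FALSE)
  out4 <- capture.output(status4 <- rsk_main(c("eval", "mm-fit", csv)))
  expect_equal(status4, 0L)
  expect_match(out4, "kcat")

  ref <- file.path(dir, "ref.pdb"); mod <- file.path(dir, "mod.pdb")
  write_structure_file(fx("complex"), ref)
  write_structure_file(fx("complex"), mod)
  out5 <- capture.output(status5 <- rsk_main(c("rmsd", ref, mod)))
  expect_equal(status5, 0L)
  expect_match(out5, "rmsd")
  expect_equal(rsk_main(character(0)), 2L)
})
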