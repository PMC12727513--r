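chi_bearing <- setdiff(c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY",
                         "HIS","ILE","LEU","LYS","MET","PHE","PRO","SER",
                         "THR","TRP","TYR","VAL"), c("GLY", "ALA"))

test_that("forward sidechain construction honours template geometry and chi", {
  gly <- build_sidechain_forward("GLY")
  expect_false(any(grepl("^C[BGDEZ]", gly$atom)))

  ala <- build_sidechain_forward("ALA")
  xyz <- as.matrix(ala[, c("x", "y", "z")]); rownames(xyz) <- ala$atom
  expect_equal(sqrt(sum((xyz["CA", ] - xyz["CB", ])^2)), 1.52,
               tolerance = 0.02)

  ser <- build_sidechain_forward("SER", chi = 60)
  expect_equal(measure_chi(ser, "SER"), 60, tolerance = 1e-6)

  # requested chi angles are realized for every chi-bearing identity
  set.seed(7)
  for (id in setdiff(chi_bearing, "PRO")) {
    chi <- runif(n_chi(id), -170, 170)
    built <- build_sidechain_forward(id, chi = chi)
    expect_equal(rsk:::.wrap180(measure_chi(built, id) - chi),
                 rep(0, n_chi(id)), tolerance = 1e-6)
  }
  expect_error(build_sidechain_forward("SER", chi = c(1, 2)), "chi")
})

test_that("rotamer inversion closes the forward round trip for all 18 chi-bearing identities", {
  set.seed(13)
  for (id in chi_bearing) {
    for (rep_i in 1:2) {
      chi <- if (id == "PRO") template_chi(id) else runif(n_chi(id), -170, 170)
      built <- build_sidechain_forward(id, chi = chi)
      bx <- as.matrix(built[, c("x", "y", "z")]); rownames(bx) <- built$atom
      R0 <- rsk:::.random_rotation(); t0 <- rnorm(3, sd = 10)
      moved <- rsk:::.apply_transform(bx, R0, t0)
      fa <- moved[functional_atoms_default(id), , drop = FALSE]
      frame <- invert_rotamer(catalytic_residue(id, fa), chi)
      expect_lt(max(abs(frame - moved[c("N", "CA", "C"), ])), 1e-6)
      # forward rebuild from the recovered frame reproduces the functional atoms
      rebuilt <- build_sidechain_forward(id, frame, chi)
      rx <- as.matrix(rebuilt[, c("x", "y", "z")]); rownames(rx) <- rebuilt$atom
      expect_lt(max(abs(rx[rownames(fa), ] - fa)), 1e-6)
    }
  }
})

test_that("inversion is a fixed point of the functional atoms (lysine chi4)", {
  chi <- template_chi("LYS")
  built <- build_sidechain_forward("LYS", chi = chi)
  bx <- as.matrix(built[, c("x", "y", "z")]); rownames(bx) <- built$atom
  fa <- bx[functional_atoms_default("LYS"), ]
  res <- catalytic_residue("LYS", fa)
  f1 <- invert_rotamer(res, chi)
  chi2 <- chi; chi2[4] <- rsk:::.wrap180(chi2[4] + 120)
  f2 <- invert_rotamer(res, chi2)
  # CA moves, the fixed functional atoms do not
  expect_gt(max(abs(f1["CA", ] - f2["CA", ])), 0.1)
  for (f in list(f1, f2)) {
    rb <- build_sidechain_forward("LYS", f, if (identical(f, f1)) chi else chi2)
    rx <- as.matrix(rb[, c("x", "y", "z")]); rownames(rx) <- rb$atom
    expect_lt(max(abs(rx["NZ", ] - fa["NZ", ])), 1e-6)
  }
  # two distinct chi sets give two distinct backbone frames
  expect_gt(rmsd(f1, f2), 0.01)
})

test_that("compatible_rotamers filters and orders by probability", {
  ent <- data.frame(identity = "SER", phi = -60, psi = -45,
                    chi1 = c(55, 175, -65), chi2 = NA, chi3 = NA, chi4 = NA,
                    prob = c(0.3, 0.5, 0.1))
  lib <- rotamer_library(ent, bin_width = 10)
  got <- compatible_rotamers("SER", -60, -45, lib, min_prob = 0.2)
  expect_length(got, 2L)
  expect_equal(vapply(got, function(r) r$probability, 0), c(0.5, 0.3))
  expect_equal(got[[1]]$chi, 175)
  expect_length(compatible_rotamers("SER", 100, 100, lib), 0L)
  expect_error(compatible_rotamers("LYS", -60, -45, lib), "absent")
  # lookup returns exactly the stored helical-bin rotamers of the fixture lib
  rl <- fx("rotlib")
  hel <- compatible_rotamers("LYS", -57, -47, rl, min_prob = 0)
  stored <- rl$entries[rl$entries$identity == "LYS" &
                         rl$entries$phi == -57, ]
  expect_length(hel, nrow(stored))
  expect_equal(sort(vapply(hel, function(r) r$probability, 0)),
               sort(stored$prob))
})

test_that("place_fragment is rigid and lands the anchor on the frame", {
  frag <- make_ideal_helix(7)
  rot <- list(chi = template_chi("LYS"), probability = 0.4)
  own <- rsk:::.anchor_frame_of(frag)
  p0 <- place_fragment(frag, own, rot, "LYS")
  expect_equal(p0$transform$rotation, diag(3), tolerance = 1e-9)
  expect_lt(max(abs(p0$transform$translation)), 1e-9)

  arr <- fx("array")
  frame <- invert_rotamer(arr$residues[[1]], rot$chi)
  p <- place_fragment(frag, frame, rot, "LYS")
  anchor_bb <- p$backbone[p$backbone$resno == frag$anchor_index &
                            p$backbone$atom %in% c("N", "CA", "C"), ]
  got <- as.matrix(anchor_bb[match(c("N", "CA", "C"), anchor_bb$atom),
                             c("x", "y", "z")])
  expect_lt(max(abs(got - frame)), 1e-3)
  # rigidity: pairwise distances preserved
  d0 <- dist(as.matrix(frag$backbone[, c("x", "y", "z")]))
  d1 <- dist(as.matrix(p$backbone[, c("x", "y", "z")]))
  expect_lt(max(abs(d0 - d1)), 1e-6)
})

test_that("clash_check applies the soft-overlap criterion and matches brute force", {
  mk <- function(xyz, element = "C") {
    data.frame(atom = paste0("X", seq_len(nrow(xyz))), x = xyz[, 1],
               y = xyz[, 2], z = xyz[, 3], element = element,
               stringsAsFactors = FALSE)
  }
  far <- clash_check(mk(matrix(0, 1, 3)), mk(matrix(c(100, 0, 0), 1, 3)))
  expect_equal(far$count, 0L)
  near <- clash_check(mk(matrix(0, 1, 3)), mk(matrix(c(2, 0, 0), 1, 3)))
  expect_equal(near$count, 1L)  # threshold 0.75 * 3.4 = 2.55
  expect_equal(near$pairs$threshold, 2.55)
  ok <- clash_check(mk(matrix(0, 1, 3)), mk(matrix(c(2.6, 0, 0), 1, 3)))
  expect_equal(ok$count, 0L)
  expect_error(clash_check(mk(matrix(0, 1, 3), element = "XX"),
                           mk(matrix(1, 1, 3))), "radius")

  set.seed(41)
  a <- mk(matrix(runif(60, 0, 10), 20, 3),
          element = sample(c("C", "N", "O", "S"), 20, TRUE))
  b <- mk(matrix(runif(60, 0, 10), 20, 3),
          element = sample(c("C", "N", "O", "S"), 20, TRUE))
  par <- clash_params()
  brute <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(b$x[j], b$y[j], b$z[j]))^2))
    thr <- 0.75 * (par$vdw_radii[a$element[i]] + par$vdw_radii[b$element[j]])
    if (d < thr) brute <- brute + 1L
  }
  expect_equal(clash_check(a, b, par)$count, brute)
})

test_that("score_assembly combines log probability and log abundance", {
  mk <- function(p, ab) list(rotamer = list(probability = p),
                             fragment = list(abundance = ab))
  expect_equal(score_assembly(list(mk(1, 0), mk(1, 0)), c(1, 1)), 0)
  s1 <- score_assembly(list(mk(0.5, 0), mk(0.5, 0)), c(1, 1))
  s2 <- score_assembly(list(mk(0.9, 0), mk(0.1, 0)), c(1, 1))
  expect_equal(s1, log(0.5))         # mean log = -0.693
  expect_equal(s2, mean(log(c(0.9, 0.1))))
  expect_gt(s1, s2)
  # strictly increasing in any single abundance
  base <- score_assembly(list(mk(0.5, 2), mk(0.5, 3)), c(1, 1))
  more <- score_assembly(list(mk(0.5, 2), mk(0.5, 4)), c(1, 1))
  expect_gt(more, base)
})

test_that("enumerate_assemblies equals brute-force Cartesian filtering", {
  arr <- fx("array")
  rl <- fx("rotlib")
  frag <- fx("fragments")[[1]]
  params <- clash_params()
  candidates <- lapply(arr$residues, function(res) {
    rots <- compatible_rotamers(res$identity, -57, -47, rl, min_prob = 0)
    lapply(seq_along(rots), function(k) {
      p <- place_fragment(frag, invert_rotamer(res, rots[[k]]$chi),
                          rots[[k]], res$identity)
      p$tag <- k
      p
    })
  })
  sizes <- vapply(candidates, length, 0L)
  expect_lte(prod(sizes), 1000)

  got <- enumerate_assemblies(candidates, ligand = arr$ligand,
                              params = params, max_out = 10000L)
  got_tags <- vapply(got, function(a) {
    paste(vapply(a$placements, function(p) p$tag, 0L), collapse = "-")
  }, "")

  atoms <- lapply(candidates, function(cl) lapply(cl, rsk:::.placement_atoms))
  combos <- expand.grid(lapply(sizes, seq_len))
  brute_tags <- character(0)
  for (r in seq_len(nrow(combos))) {
    pick <- unlist(combos[r, ])
    ok <- TRUE
    for (i in seq_along(pick)) {
      if (clash_check(atoms[[i]][[pick[i]]], arr$ligand, params)$count > 0) {
        ok <- FALSE; break
      }
      if (ok && i > 1) for (j in seq_len(i - 1)) {
        if (clash_check(atoms[[i]][[pick[i]]], atoms[[j]][[pick[j]]],
                        params)$count > 0) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) brute_tags <- c(brute_tags, paste(pick, collapse = "-"))
  }
  expect_setequal(got_tags, brute_tags)
  # scores non-increasing, truncation deterministic
  scores <- vapply(got, function(a) a$score, 0)
  expect_true(all(diff(scores) <= 1e-12))
  top5 <- enumerate_assemblies(candidates, ligand = arr$ligand,
                               params = params, max_out = 5L)
  expect_length(top5, min(5L, length(got)))
  expect_equal(vapply(top5, function(a) a$score, 0), scores[seq_along(top5)])

  # single residue with k placements -> k single-fragment assemblies
  single <- enumerate_assemblies(candidates[1], ligand = NULL,
                                 params = params, max_out = 100L)
  expect_length(single, length(candidates[[1]]))

  # empty candidate list -> empty result with diagnostic, not an exception
  empty <- enumerate_assemblies(list(candidates[[1]], list()),
                                params = params)
  expect_length(empty, 0L)
  expect_match(attr(empty, "diagnostic"), "empty candidate list")
})

test_that("build_motif_library pins functional atoms and serializes losslessly", {
  arr <- fx("array")
  ml <- fx("library")
  expect_s3_class(ml, "MotifLibrary")
  expect_gte(length(ml$assemblies), 1L)
  for (a in ml$assemblies) {
    for (i in seq_along(a$placements)) {
      fa <- arr$residues[[i]]$functional_atoms
      rr <- a$placements[[i]]$rebuilt_residue
      got <- as.matrix(rr[match(rownames(fa), rr$atom), c("x", "y", "z")])
      expect_lt(max(abs(got - fa)), 1e-3)
    }
    # no returned assembly contains a clash (re-check post hoc)
    pl <- a$placements
    for (i in seq_along(pl)) {
      expect_equal(clash_check(pl[[i]], arr$ligand)$count, 0L)
      if (i > 1) for (j in seq_len(i - 1)) {
        expect_equal(clash_check(pl[[i]], pl[[j]])$count, 0L)
      }
    }
  }
  # determinism: identical config gives identical libraries
  ml2 <- build_motif_library(arr, fx("rotlib"), fx("fragments"),
                             config = list(min_prob = 0, max_out = 20))
  expect_equal(vapply(ml2$assemblies, function(a) a$score, 0),
               vapply(ml$assemblies, function(a) a$score, 0))

  pdb <- tempfile(fileext = ".pdb")
  write_motif_library(ml, pdb)
  back <- read_motif_library(pdb)
  expect_equal(n_models(back$structure), length(ml$assemblies))
  m1 <- rsk:::.model_atoms(back$structure, 1)
  orig <- assembly_to_structure(ml$assemblies[[1]])$atoms
  expect_equal(max(abs(as.matrix(m1[, c("x", "y", "z")]) -
                         as.matrix(orig[, c("x", "y", "z")]))), 0,
               tolerance = 1e-3)
  expect_equal(back$meta$assemblies[[1]]$score, ml$assemblies[[1]]$score,
               tolerance = 1e-9)

  # forced failure: two residues whose functional atoms overlap
  res <- arr$residues[[1]]
  clash_arr <- catalytic_array(list(res, res), ligand = NULL, name = "overlap")
  empty <- build_motif_library(clash_arr, fx("rotlib"), fx("fragments"),
                               config = list(min_prob = 0,
                                             clash = clash_params(tolerance_factor = 1)))
  expect_length(empty$assemblies, 0L)
  expect_match(empty$diagnostic, "clash")
})
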