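# The toy generator: determinism, chain statistics, closed analysis loops.

test_that("toy protomer has ideal helix geometry and a consistent BW map", {
  p <- build_toy_protomer()
  at <- atoms(p$structure)
  for (rng in list(192:201, 383:392)) {
    ca <- as.matrix(at[at$name == "CA" & at$resSeq %in% rng, c("x", "y", "z")])
    steps <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(abs(steps - 3.8) < 0.1))
  }
  expect_equal(bw_resolve(p$bw, "5.48")$resSeq, 199L)
  expect_equal(bw_resolve(p$bw, "6.52")$resSeq, 390L)
  expect_equal(at$resName[at$resSeq == 199][1], "TYR")
  expect_equal(at$resName[at$resSeq == 390][1], "PHE")
})

test_that("rotamer sequences honor the stationary target and determinism", {
  spec <- synthetic_spec(n_frames = 4000, seed = 101,
                         rotamers = list(rotamer_plan("A", 199, 1.0),
                                         rotamer_plan("A", 390, 0.9)))
  s1 <- generate_rotamer_sequence(spec, 1)
  expect_true(all(s1$states == "trans"))
  # angular distance to the trans center stays within the noise band
  circ_dev <- pmin(abs(s1$angles - 180), 360 - abs(s1$angles - 180))
  expect_lt(max(circ_dev), 90)
  expect_equal(sum(classify_rotamer(s1$angles) == "cis"), 0)

  s2a <- generate_rotamer_sequence(spec, 2)
  s2b <- generate_rotamer_sequence(spec, 2)
  expect_identical(s2a$angles, s2b$angles)       # fixed seed, identical output
  expect_false(identical(s1$angles, s2a$angles)) # distinct residues differ

  expect_error(generate_rotamer_sequence(
    synthetic_spec(n_frames = 10, rotamers = list(
      rotamer_plan("A", 199, 0.99, p_stay = 0.9))), 1), "unreachable")
})

test_that("i.i.d. persistence gives binomial transition counts", {
  p <- 0.7
  spec <- synthetic_spec(n_frames = 8000, seed = 55,
                         rotamers = list(rotamer_plan("A", 199, p, p_stay = p)))
  s <- generate_rotamer_sequence(spec, 1)
  st <- s$states
  # with p_stay = p the chain is i.i.d.: P(next = trans) = p regardless
  from_trans <- which(st[-length(st)] == "trans")
  frac <- mean(st[from_trans + 1] == "trans")
  se <- sqrt(p * (1 - p) / length(from_trans))
  expect_lt(abs(frac - p), 3 * se)
})

test_that("generated trajectories are deterministic and carry their truth", {
  spec <- synthetic_spec(n_frames = 12, seed = 7)
  g1 <- generate_monomer_trajectory(spec)
  g2 <- generate_monomer_trajectory(spec)
  expect_identical(g1$traj$coords, g2$traj$coords)
  expect_identical(g1$truth$states, g2$truth$states)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(g1$traj, f1); write_pdb(g2$traj, f2)
  expect_identical(readLines(f1), readLines(f2))  # bit-identical files
})

test_that("monomer ground truth is recovered by the analysis operations", {
  spec <- synthetic_spec(n_frames = 200, seed = 3)
  gen <- generate_monomer_trajectory(spec)
  # chi1 angles decoded from coordinates match the generator script
  tr199 <- chi1_trace(gen$traj, "A", 199)
  expect_equal(tr199$chi1, gen$truth$angles[["A:199"]], tolerance = 1e-6)
  expect_identical(classify_rotamer(tr199$chi1), gen$truth$states[["A:199"]])
  # scripted contact fraction recovered exactly at the planted residue
  cf <- contact_frequency(gen$traj, "chain L", "protein", bw = gen$bw)
  expect_equal(cf$fraction[cf$resSeq == 196], gen$truth$contact_fraction)
  # jitter-only: superposed backbone RMSD ~ 0 (backbone is rigid)
  bb <- rmsd_trace(gen$traj, "backbone", reference = 1)
  expect_lt(max(bb$rmsd), 1e-6)
})

test_that("scripted pose excursions set the stability onset exactly", {
  k <- 61L
  spec <- synthetic_spec(n_frames = 150, seed = 9,
                         ligand = list(resSeq = 196, target = 3.5,
                                       contact_fraction = 0.3, switch_frame = k))
  gen <- generate_monomer_trajectory(spec)
  lig <- rmsd_trace(gen$traj, "chain l", reference = "final",
                    fit_sel = "backbone")
  w <- stability_onset(lig, threshold = 3.0)
  expect_equal(w$onset_frame, k)
  expect_equal(w$onset, gen$truth$onset)
})

test_that("dimer ground truth is recovered: separations, H-bonds, occupancies", {
  spec <- synthetic_spec(n_frames = 250, seed = 17,
                         dimer = list(separation = 15, hbond_fraction = 0.04))
  gen <- generate_dimer_trajectory(spec)
  d <- interface_distance_trace(gen$traj, "chain a", "chain b")
  expect_equal(d$cog_dist, gen$truth$separations, tolerance = 1e-9)
  expect_lt(max(abs(gen$truth$separations - gen$truth$separation_script)), 0.2)

  hb <- hbond_occupancy(gen$traj, "chain a and resid 199 and name oh",
                        "chain b and resid 199 and name oh")
  expect_equal(hb$occupancy, gen$truth$hbond_fraction)
  expect_equal(hb$occupancy, 0.04)

  for (key in names(gen$truth$states_b)) {
    rs <- as.integer(sub("B:", "", key))
    tr <- chi1_trace(gen$traj, "B", rs)
    expect_identical(classify_rotamer(tr$chi1), gen$truth$states_b[[key]])
  }

  # scripted per-frame separation
  sep_script <- seq(14, 20, length.out = 40)
  spec2 <- synthetic_spec(n_frames = 40, seed = 18,
                          dimer = list(separation = sep_script,
                                       hbond_fraction = 0))
  gen2 <- generate_dimer_trajectory(spec2)
  d2 <- interface_distance_trace(gen2$traj, "chain a", "chain b")
  expect_equal(d2$cog_dist, gen2$truth$separations, tolerance = 1e-9)
  expect_lt(max(abs(gen2$truth$separations - sep_script)), 0.2)
})

test_that("a 30 A-separated dimer has zero interface energy in every frame", {
  spec <- synthetic_spec(n_frames = 10, seed = 19,
                         dimer = list(separation = 30, hbond_fraction = 0))
  gen <- generate_dimer_trajectory(spec)
  e <- interface_energy(gen$traj)
  expect_true(all(e$energies$energy == 0))
  scan <- alanine_scan(gen$traj, tibble::tibble(chainId = c("A", "B"),
                                                resSeq = c(199L, 199L)))
  expect_equal(scan$contribution, 0)
})

test_that("synthetic datasets round trip through disk", {
  spec <- synthetic_spec(n_frames = 5, seed = 23)
  gen <- generate_monomer_trajectory(spec)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(gen, dir)
  tr <- read_pdb(file.path(dir, "trajectory.pdb"), dt = spec$dt)
  expect_equal(n_frames(tr), 5)
  expect_lt(max(abs(tr$coords - gen$traj$coords)), 1e-3 + 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 23)
  m <- load_bw_map(file.path(dir, "bw_map.tsv"))
  expect_equal(bw_resolve(m, "6.52")$resSeq, 390L)
})
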