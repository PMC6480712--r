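# Dimer interface distances, H-bonds, energy model, alanine scanning.

two_chain_structure <- function(ma, mb, element = "C") {
  a <- atoms_from_coords(ma, chain = "A", element = element)$atoms
  b <- atoms_from_coords(mb, chain = "B", element = element)$atoms
  b$serial <- b$serial + nrow(a)
  md_structure(dplyr::bind_rows(a, b))
}

test_that("interface distance traces report both definitions correctly", {
  ma <- cbind(0, 0, seq(0, 9, by = 1.5))
  mb <- cbind(10, 0, seq(0, 9, by = 1.5))   # parallel, 10 A apart
  s <- two_chain_structure(ma, mb)
  tr <- traj_from_frames(s, list(coords_matrix(s)))
  d <- interface_distance_trace(tr, "chain A", "chain B")
  expect_equal(d$cog_dist, 10, tolerance = 0.1)
  expect_equal(d$min_dist, 10)
  expect_error(interface_distance_trace(tr, "chain A", "chain A"),
               "distinct chains")
})

test_that("residue pair min distance summarizes correctly over frames", {
  s <- two_chain_structure(matrix(0, 1, 3), matrix(c(4, 0, 0), 1, 3))
  f2 <- coords_matrix(s); f2[2, 1] <- 6
  tr <- traj_from_frames(s, list(coords_matrix(s), f2))
  out <- residue_pair_min_distance(tr, "chain A", "chain B")
  expect_equal(out$dist, c(4, 6))
  expect_equal(attr(out, "summary")$mean, 5)
  expect_equal(attr(out, "summary")$sd, 1)
  expect_equal(glance(out)$mean, 5)

  # constant geometry: SD exactly 0
  tc <- traj_from_frames(s, list(coords_matrix(s), coords_matrix(s)))
  expect_equal(attr(residue_pair_min_distance(tc, "chain A", "chain B"),
                    "summary")$sd, 0)

  # random frames vs brute force
  set.seed(13)
  sA <- matrix(rnorm(12, sd = 3), 4, 3); sB <- matrix(rnorm(15, sd = 3), 5, 3)
  st <- two_chain_structure(sA, sB)
  frames <- replicate(6, coords_matrix(st) + matrix(rnorm(27, sd = 1), 9, 3),
                      simplify = FALSE)
  trr <- traj_from_frames(st, frames)
  got <- residue_pair_min_distance(trr, "chain A", "chain B")
  for (i in 1:6) {
    expect_equal(got$dist[i],
                 oracle_min_distance(frames[[i]][1:4, , drop = FALSE],
                                     frames[[i]][5:9, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("hbond occupancy applies distance, angle and symmetric-mode rules", {
  near <- two_chain_structure(matrix(0, 1, 3), matrix(c(2.8, 0, 0), 1, 3),
                              element = "O")
  tr <- traj_from_frames(near, list(coords_matrix(near)))
  expect_equal(hbond_occupancy(tr, "chain A", "chain B")$occupancy, 1.0)

  far <- two_chain_structure(matrix(0, 1, 3), matrix(c(4, 0, 0), 1, 3),
                             element = "O")
  trf <- traj_from_frames(far, list(coords_matrix(far)))
  expect_equal(hbond_occupancy(trf, "chain A", "chain B")$occupancy, 0.0)

  # explicit hydrogen: ideal linear D-H...A passes, bent geometry fails
  mk_h <- function(hpos) {
    at <- dplyr::bind_rows(
      tibble::tibble(serial = 1L, name = "OG", element = "O", resName = "SER",
                     resSeq = 1L, chainId = "A", het = FALSE,
                     x = 0, y = 0, z = 0),
      tibble::tibble(serial = 2L, name = "HG", element = "H", resName = "SER",
                     resSeq = 1L, chainId = "A", het = FALSE,
                     x = hpos[1], y = hpos[2], z = hpos[3]),
      tibble::tibble(serial = 3L, name = "OG", element = "O", resName = "SER",
                     resSeq = 2L, chainId = "B", het = FALSE,
                     x = 2.8, y = 0, z = 0))
    s <- md_structure(at)
    traj_from_frames(s, list(coords_matrix(s)))
  }
  lin <- mk_h(c(0.97, 0, 0))
  bent <- mk_h(c(0, 0.97, 0))
  don <- "chain A and name OG"; acc <- "chain B and name OG"
  expect_equal(hbond_occupancy(lin, don, acc, symmetric = FALSE)$occupancy, 1)
  expect_equal(hbond_occupancy(bent, don, acc, symmetric = FALSE)$occupancy, 0)
  # symmetric mode rescues it: the bare acceptor may donate instead
  expect_equal(hbond_occupancy(bent, don, acc, symmetric = TRUE)$occupancy, 1)

  # monotone in the distance cutoff
  occ_at <- function(dc) hbond_occupancy(trf, "chain A", "chain B",
                                         criterion = hbond_criterion(dc))$occupancy
  expect_true(all(diff(vapply(c(2, 3.5, 4.5, 6), occ_at, 0)) >= 0))
  expect_error(hbond_criterion(-1), "positive")
  expect_error(hbond_criterion(3.5, 200), "180")
})

test_that("interface energy matches closed forms and the double-loop oracle", {
  params <- energy_params()
  # far protomers: zero
  s_far <- two_chain_structure(matrix(0, 3, 3) + rnorm(9, sd = 0.5),
                               matrix(30, 3, 3) + rnorm(9, sd = 0.5))
  expect_equal(interface_energy(s_far, params)$mean, 0)

  # two neutral carbons at the LJ minimum: E = -eps
  sig <- 3.55; eps <- 0.07
  r0 <- 2^(1 / 6) * sig
  s_min <- two_chain_structure(matrix(0, 1, 3), matrix(c(r0, 0, 0), 1, 3))
  expect_equal(interface_energy(s_min, params)$mean, -eps, tolerance = 1e-12)

  # 20-atom toy dimers vs the exhaustive double loop
  set.seed(14)
  for (i in 1:15) {
    ma <- matrix(rnorm(30, sd = 3), 10, 3)
    mb <- matrix(rnorm(30, sd = 3), 10, 3) + 5
    s <- two_chain_structure(ma, mb)
    # sprinkle in charged residues so the Coulomb term is exercised
    at <- atoms(s)
    at$resName[c(1, 11)] <- "ASP"; at$name[c(1, 11)] <- "OD1"
    at$element[c(1, 11)] <- "O"
    at$resName[c(2, 12)] <- "LYS"; at$name[c(2, 12)] <- "NZ"
    at$element[c(2, 12)] <- "N"
    s <- md_structure(at)
    pa <- rotadimer:::atom_params(at[at$chainId == "A", ], params)
    pb <- rotadimer:::atom_params(at[at$chainId == "B", ], params)
    got <- interface_energy(s, params)$mean
    want <- oracle_interface_energy(ma, mb, pa, pb, params$cutoff)
    expect_equal(got, want, tolerance = 1e-8)
  }

  # unknown element errors by name
  bad <- two_chain_structure(matrix(0, 1, 3), matrix(3, 1, 3), element = "XX")
  expect_error(interface_energy(bad, params), "XX")
})

test_that("interface energy is symmetric under protomer swap and rigid motion", {
  set.seed(15)
  params <- energy_params()
  ma <- matrix(rnorm(24, sd = 3), 8, 3)
  mb <- matrix(rnorm(24, sd = 3), 8, 3) + 4
  e_ab <- interface_energy(two_chain_structure(ma, mb), params)$mean
  e_ba <- interface_energy(two_chain_structure(mb, ma), params)$mean
  expect_equal(e_ab, e_ba, tolerance = 1e-10)
  for (i in 1:5) {
    r <- random_rotation(); t <- rnorm(3, sd = 15)
    e_mov <- interface_energy(two_chain_structure(
      sweep(ma %*% r, 2, t, `+`), sweep(mb %*% r, 2, t, `+`)), params)$mean
    expect_equal(e_mov, e_ab, tolerance = 1e-8)
  }
})

test_that("alanine truncation removes exactly the distal sidechain", {
  p <- build_toy_protomer()
  s <- p$structure
  tyr_atoms <- sum(atoms(s)$resSeq == 199)
  expect_equal(tyr_atoms, 12L)                  # full Tyr heavy-atom count
  mut <- mutate_to_alanine(s, tibble::tibble(chainId = "A", resSeq = 199L))
  expect_equal(sum(atoms(mut)$resSeq == 199), 5L)  # N CA C O CB
  expect_true(all(atoms(mut)$resName[atoms(mut)$resSeq == 199] == "ALA"))
  # idempotent
  mut2 <- mutate_to_alanine(mut, tibble::tibble(chainId = "A", resSeq = 199L))
  expect_equal(atoms(mut2), atoms(mut))
  # double mutant bookkeeping: Tyr loses 7, Phe loses 6
  both <- mutate_to_alanine(s, tibble::tibble(chainId = "A",
                                              resSeq = c(199L, 390L)))
  expect_equal(n_atoms(s) - n_atoms(both), 13L)
  expect_error(mutate_to_alanine(s, tibble::tibble(chainId = "A", resSeq = 195L)),
               "no CB")
})

test_that("alanine-scan contributions are additive over removed pair terms", {
  params <- energy_params()
  # mutated residue far from the interface: contribution ~ 0
  spec <- synthetic_spec(n_frames = 3, seed = 20, jitter = FALSE,
                         dimer = list(separation = 15, hbond_fraction = 0))
  gen <- generate_dimer_trajectory(spec)
  # TM6 Phe390 of protomer A faces B, but TM5 glycines' neighbors: use a
  # residue pair fully outside the 12 A cutoff instead: mutate B's Tyr199
  # after pushing the dimer far apart
  far <- synthetic_spec(n_frames = 2, seed = 21, jitter = FALSE,
                        dimer = list(separation = 40, hbond_fraction = 0))
  gf <- generate_dimer_trajectory(far)
  scan_far <- alanine_scan(gf$traj, tibble::tibble(chainId = "A", resSeq = 199L),
                           params)
  expect_lt(abs(scan_far$contribution), 1e-6)

  # single attractive pair: contribution equals that pair's energy exactly
  ma <- rbind(c(0, 0, 0), c(0, 3, 0))        # residue 1 = CB-less stub pair
  at <- dplyr::bind_rows(
    tibble::tibble(serial = 1:3, name = c("CB", "CG", "CA"), element = "C",
                   resName = "XXX", resSeq = 1L, chainId = "A", het = FALSE,
                   x = c(0, 0, -20), y = c(0, 1.5, 0), z = 0),
    tibble::tibble(serial = 4L, name = "C1", element = "C", resName = "UNK",
                   resSeq = 2L, chainId = "B", het = FALSE,
                   x = 4, y = 1.5, z = 0))
  s <- md_structure(at)
  # only CG (sidechain, removed by mutation) is within 12 A of chain B;
  # CB stays but contributes too -- compute both terms explicitly
  e_full <- interface_energy(s, params)$mean
  scan <- alanine_scan(s, tibble::tibble(chainId = "A", resSeq = 1L), params)
  pa <- rotadimer:::atom_params(at[1:3, ], params)
  pb <- rotadimer:::atom_params(at[4, , drop = FALSE], params)
  term <- function(i) oracle_interface_energy(
    matrix(c(at$x[i], at$y[i], at$z[i]), 1, 3),
    matrix(c(at$x[4], at$y[4], at$z[4]), 1, 3),
    lapply(pa, `[`, i), pb, params$cutoff)
  expect_equal(scan$contribution, term(2), tolerance = 1e-10)
  expect_equal(scan$E_wt, e_full)
  expect_equal(scan$E_wt - scan$E_mut, scan$contribution)

  expect_equal(energy_contribution(-11.7, -8.6), -3.1)
  expect_equal(energy_contribution(-5, -5), 0)
})

test_that("docking interface scores are annotated against the -5 convention", {
  ann <- annotate_interface_score(c(-9.7, -4.2))
  expect_identical(ann$satisfactory, c(TRUE, FALSE))
})
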