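test_that("density profiles count, normalise and localise correctly", {
  # one frame, all atoms in one slab of z
  atoms <- data.frame(residue_id = 1:50, residue_name = "SOL", name = "OW",
                      x = runif(50, 0, 2), y = runif(50, 0, 2),
                      z = runif(50, 4.0, 4.1))
  snap <- snapshot(atoms, box = c(2, 2, 8))
  prof <- density_profile(list(snap), "SOL", n_bins = 80)
  occupied <- which(prof$density > 0)
  expect_true(all(prof$z_centers[occupied] > 3.9 &
                    prof$z_centers[occupied] < 4.2))
  expect_equal(sum(prof$density) * 2 * 2 * prof$bin_width, 50)
  expect_error(density_profile(list(snap), "XXX"), "matches no atoms")
  expect_error(density_profile(list(snap), ""), "nonempty")

  # doubling the bins leaves the density estimate unchanged within noise
  snaps <- make_density_snapshots(6, 2, 0.3, 33, n_frames = 50, seed = 11)
  p1 <- density_profile(snaps, "SOL", n_bins = 60)
  p2 <- density_profile(snaps, "SOL", n_bins = 120)
  expect_equal(p1$bulk_density, p2$bulk_density, tolerance = 0.02)
  mid1 <- p1$density[which.min(abs(p1$z_centers - 6))]
  mid2 <- p2$density[which.min(abs(p2$z_centers - 6))]
  expect_equal(mid1, mid2, tolerance = 0.1)
})

test_that("the Gibbs dividing surface is recovered across interface widths", {
  for (w in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
    snaps <- make_density_snapshots(6, 2.0, w, 33, n_frames = 200,
                                    seed = round(100 * w))
    prof <- density_profile(snaps, "SOL", n_bins = 240)
    gds <- gibbs_dividing_surface(prof)
    expect_lt(abs(as.numeric(gds) - 2.0), prof$bin_width)
  }
  # near-step profile: crossing within a bin of the step
  snaps <- make_density_snapshots(6, 2.0, 0.02, 33, n_frames = 100,
                                  seed = 12)
  prof <- density_profile(snaps, "SOL", n_bins = 120)
  expect_lt(abs(as.numeric(gibbs_dividing_surface(prof)) - 2.0),
            prof$bin_width)
  # uniform density: no interface to find
  atoms <- data.frame(residue_id = 1:2000, residue_name = "SOL",
                      name = "OW", x = runif(2000, 0, 4),
                      y = runif(2000, 0, 4), z = runif(2000, 0, 12))
  expect_error(gibbs_dividing_surface(
    density_profile(list(snapshot(atoms, c(4, 4, 12))), "SOL",
                    n_bins = 24)),
    "no interface")
})

test_that("the interphase region brackets the GDS", {
  expect_equal(interphase_region(2.2, 0.6), c(1.6, 2.8))
  expect_equal(interphase_region(2.0, 0.5), c(1.5, 2.5))
  expect_error(interphase_region(2.0, 0), "> 0")
})

test_that("hydrogen-bond counting honours both cutoffs", {
  sel_count <- function(geom, crit = hbond_criteria()) {
    snap <- make_hbond_fixture(geom, seed = 13)
    s <- hbond_triplet_selection(snap)
    count_hbonds(snap, s$donors, s$hydrogens, s$acceptors, crit)
  }
  expect_equal(sel_count(cbind(0.28, 0)), 1)      # ideal bond
  expect_equal(sel_count(cbind(0.40, 0)), 0)      # distance cut 0.35 nm
  expect_equal(sel_count(cbind(0.30, 45)), 0)     # angle cut 30 deg
  expect_equal(sel_count(cbind(0.30, 29.9)), 1)
  expect_equal(sel_count(rbind(c(0.28, 0), c(0.40, 0), c(0.34, 10))), 2)
  # donor-vertex convention is much stricter for the same geometry
  expect_equal(sel_count(cbind(0.30, 25),
                         hbond_criteria(angle_vertex = "donor")), 1)
  # a hydrogen without a donor mapping is an input error
  snap <- make_hbond_fixture(cbind(0.3, 0), seed = 14)
  s <- hbond_triplet_selection(snap)
  expect_error(count_hbonds(snap, integer(0), s$hydrogens, s$acceptors),
               "donor")
})

test_that("hydrogen-bond counts match a brute-force recount on random fixtures", {
  for (k in 1:50) {
    set.seed(2000 + k)
    n <- sample(3:12, 1)
    geom <- cbind(runif(n, 0.15, 0.55), runif(n, 0, 90))
    snap <- make_hbond_fixture(geom, seed = 3000 + k)
    s <- hbond_triplet_selection(snap)
    for (vertex in c("hydrogen", "donor")) {
      crit <- hbond_criteria(angle_vertex = vertex)
      expect_identical(
        count_hbonds(snap, s$donors, s$hydrogens, s$acceptors, crit),
        brute_hbond_count(snap, s$donors, s$hydrogens, s$acceptors, crit))
    }
  }
})

test_that("counts are invariant under whole-box translation (minimum image)", {
  geom <- cbind(runif(8, 0.2, 0.5), runif(8, 0, 60))
  snap <- make_hbond_fixture(geom, seed = 15)
  s <- hbond_triplet_selection(snap)
  base <- count_hbonds(snap, s$donors, s$hydrogens, s$acceptors)
  shifted <- snap
  shifted$atoms$x <- shifted$atoms$x + snap$box[1]
  shifted$atoms$z <- shifted$atoms$z - 2 * snap$box[3]
  expect_identical(count_hbonds(shifted, s$donors, s$hydrogens,
                                s$acceptors), base)
  cp_base <- close_pairs(snap, 1, cutoff = 0.5)
  cp_shift <- close_pairs(shifted, 1, cutoff = 0.5)
  expect_equal(cp_shift$distance, cp_base$distance, tolerance = 1e-12)
})

test_that("per-window mean bond counts recover planted values", {
  mk_frames <- function(k_bonds, n_frames, seed) {
    lapply(seq_len(n_frames), function(f) {
      geom <- rbind(matrix(c(rep(0.29, k_bonds), rep(5, k_bonds)),
                           ncol = 2),
                    c(0.45, 0))  # one decoy beyond the distance cutoff
      make_hbond_fixture(geom, seed = seed + f)
    })
  }
  snaps <- list("1.0" = mk_frames(2, 3, 100), "1.5" = mk_frames(3, 3, 200),
                "2.0" = mk_frames(4, 3, 300))
  out <- hbond_vs_r(snaps)
  expect_equal(out$r, c(1.0, 1.5, 2.0))
  expect_equal(out$mean_count, c(2, 3, 4))
  # empty windows are excluded with a warning, not an error
  snaps$empty <- list()
  names(snaps)[4] <- "2.5"
  expect_warning(out2 <- hbond_vs_r(snaps), "without snapshots")
  expect_equal(nrow(out2), 3)
})

test_that("orientation histograms are normalised and shape-correct", {
  al <- orientation_distribution(make_orientation_fixture("aligned", 100),
                                 n_bins = 20)
  expect_equal(sum(al$density * diff(al$edges)), 1, tolerance = 1e-9)
  expect_equal(al$counts[20], 100)
  expect_true(all(al$counts[1:19] == 0))

  iso <- orientation_distribution(
    make_orientation_fixture("isotropic", 1e5, seed = 16), n_bins = 20)
  expect_equal(sum(iso$density * diff(iso$edges)), 1, tolerance = 1e-9)
  expect_gt(suppressWarnings(stats::chisq.test(iso$counts)$p.value), 0.01)

  # a sample plus its negation is symmetric about cos(theta) = 0
  v <- make_orientation_fixture("isotropic", 2e4, seed = 17)
  h <- orientation_distribution(rbind(v, -v), n_bins = 10)
  expect_equal(h$counts, rev(h$counts))

  # arbitrary magnitudes are normalised; zero vectors are rejected
  expect_equal(orientation_distribution(rbind(c(0, 0, 5)), 4)$counts[4], 1)
  expect_error(orientation_distribution(rbind(c(0, 0, 0))), "zero vector")
})

test_that("close pairs honour the cutoff and match the brute-force oracle", {
  two <- function(d) snapshot(
    data.frame(residue_id = 1, residue_name = "MOL", name = c("A", "B"),
               x = c(1, 1 + d), y = 1, z = 1), box = c(5, 5, 5))
  expect_equal(nrow(close_pairs(two(0.30), 1, cutoff = 0.35)), 1)
  expect_equal(nrow(close_pairs(two(0.40), 1, cutoff = 0.35)), 0)
  expect_error(close_pairs(two(0.3), 99, 0.35), "unknown residue")

  for (k in 1:50) {
    set.seed(4000 + k)
    atoms <- data.frame(residue_id = 5, residue_name = "MOL",
                        name = sprintf("C%d", 1:20),
                        x = runif(20, 0, 2), y = runif(20, 0, 2),
                        z = runif(20, 0, 2))
    snap <- snapshot(atoms, box = c(2, 2, 2))
    got <- close_pairs(snap, 5, cutoff = 0.35)
    want <- brute_close_pairs(snap, 5, cutoff = 0.35)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
    expect_identical(paste(got$i, got$j), paste(want$i, want$j))
  }
})

test_that("bonded neighbours can be excluded from close pairs", {
  # linear chain A-B-C with short bonds; only the 1-3 pair survives
  atoms <- data.frame(residue_id = 1, residue_name = "MOL",
                      name = c("A", "B", "C"),
                      x = c(1, 1.15, 1.30), y = 1, z = 1)
  snap <- snapshot(atoms, box = c(5, 5, 5))
  topo <- rbind(c(1, 2), c(2, 3))
  all_pairs <- close_pairs(snap, 1, cutoff = 0.35)
  expect_equal(nrow(all_pairs), 3)
  kept <- close_pairs(snap, 1, cutoff = 0.35, min_bond_separation = 2,
                      topology = topo)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$distance, 0.30, tolerance = 1e-12)
})

test_that("donor-acceptor angle distributions round-trip planted angles", {
  snap <- make_hbond_fixture(rbind(c(0.30, 10), c(0.30, 40), c(0.30, 90)),
                             seed = 18)
  s <- hbond_triplet_selection(snap)
  h <- hda_angle_distribution(snap, s$donors, s$hydrogens, s$acceptors,
                              max_da_distance = 0.35)
  expect_equal(sort(h$angles), c(10, 40, 90), tolerance = 1e-3)
  expect_equal(sum(h$density * diff(h$edges)), 1, tolerance = 1e-9)
  # no pairs in range: an empty histogram, not an error
  far <- make_hbond_fixture(cbind(0.6, 0), seed = 19)
  sf <- hbond_triplet_selection(far)
  h0 <- hda_angle_distribution(far, sf$donors, sf$hydrogens, sf$acceptors,
                               max_da_distance = 0.35)
  expect_equal(h0$n, 0)
  expect_true(all(h0$density == 0))
})
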