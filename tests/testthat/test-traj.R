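# minimal in-code topology: positions given per atom, all heavy unless H
mk_topo <- function(resno, name, element, mass = NULL) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
  data.frame(eleno = seq_along(resno), name = name, resno = resno,
             resname = "GLY", element = element,
             heavy = element != "H",
             mass = if (is.null(mass)) unname(masses[element]) else mass,
             h_of = NA_integer_, donor = FALSE, acceptor = FALSE,
             stringsAsFactors = FALSE)
}
mk_frames <- function(...) {
  rows <- list(...)
  frame_series(do.call(rbind, lapply(rows, function(m) as.vector(t(m)))))
}

test_that("distance series handle atoms, centers of mass and planted schedules", {
  topo <- mk_topo(c(1, 1, 2), c("CA", "CB", "CA"), c("C", "C", "C"),
                  mass = c(1, 1, 1))
  fr <- mk_frames(rbind(c(0, 0, 0), c(3, 4, 0), c(10, 0, 0)))
  expect_equal(distance_series(fr, topo, 1, 2)$values, 5)
  # COM of two unit-mass atoms at +/- offsets sits at the midpoint
  topo2 <- mk_topo(c(1, 1, 2), c("CA", "CB", "CA"), c("C", "C", "C"),
                   mass = c(1, 1, 1))
  fr2 <- mk_frames(rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_equal(distance_series(fr2, topo2, "com:1", "ca:2")$values, 0)
  expect_error(distance_series(fr2, topo2, "ca:9", "ca:2"), "matches no atoms")

  # planted separation schedule from the two-state generator
  ens <- gen_two_state_ensemble(n_frames = 120, seed = 3)
  ds <- distance_series(ens$frames, ens$topology,
                        ens$truth$label_site, ens$truth$cluster_site)
  expect_equal(ds$values, ens$truth$separations, tolerance = 1e-9)
})

test_that("gyration radius matches closed forms and is rotation-invariant", {
  topo <- mk_topo(c(1, 1), c("CA", "CB"), c("C", "C"), mass = c(1, 1))
  d <- 6
  fr <- mk_frames(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(gyration_radius_series(fr, topo, 1), d / 2)
  # single atom: zero with a warning
  topo1 <- mk_topo(1, "CA", "C")
  fr1 <- mk_frames(rbind(c(2, 3, 4)))
  expect_warning(rg1 <- gyration_radius_series(fr1, topo1, 1), "single")
  expect_equal(rg1, 0)
  # mass weighting shifts the center toward the heavy atom
  topo3 <- mk_topo(c(1, 1), c("CA", "CB"), c("C", "C"), mass = c(3, 1))
  expect_equal(gyration_radius_series(fr, topo3, 1),
               sqrt((3 * 1.5^2 + 1 * 4.5^2) / 4))
  # rigid-body transform leaves Rg unchanged to 1e-9
  ens <- gen_two_state_ensemble(n_frames = 25, seed = 8)
  rg <- gyration_radius_series(ens$frames, ens$topology, 1:20)
  set.seed(4)
  rg_t <- gyration_radius_series(rigid_transform_frames(ens$frames),
                                 ens$topology, 1:20)
  expect_equal(rg_t, rg, tolerance = 1e-9)
})

test_that("contact numbers count heavy-atom pairs inclusively and symmetrically", {
  # hand-placed frame with exactly 3 qualifying heavy pairs (H ignored)
  topo <- mk_topo(c(1, 1, 1, 2, 2), c("CA", "CB", "H", "CA", "CB"),
                  c("C", "C", "H", "C", "C"))
  fr <- mk_frames(rbind(
    c(0, 0, 0),      # CA1: 4.50 to CA2 (inclusive boundary), 4.24 to CB2
    c(1, 2, 0),      # CB1: 4.03 to CA2, 5.39 to CB2
    c(0, 0, 1),      # H (never counted)
    c(4.5, 0, 0),    # CA2
    c(3, -3, 0)))    # CB2
  cs <- contact_number_series(fr, topo, 1, 2)
  expect_equal(cs$counts, 3L)
  # swap symmetry
  expect_equal(contact_number_series(fr, topo, 2, 1)$counts, cs$counts)
  # far-apart residues give an all-zero series
  fr_far <- mk_frames(rbind(c(0, 0, 0), c(1, 2, 0), c(0, 0, 1),
                            c(40, 0, 0), c(43, 0, 0)))
  expect_equal(contact_number_series(fr_far, topo, 1, 2)$counts, 0L)
  # counts are non-decreasing in the cutoff
  for (ct in list(c(3, 4.5), c(4.5, 6), c(6, 10)))
    expect_lte(contact_number_series(fr, topo, 1, 2, ct[1])$counts,
               contact_number_series(fr, topo, 1, 2, ct[2])$counts)
  expect_error(contact_number_series(fr, topo, 1, 1), "distinct")
})

test_that("fluctuating-pair selection returns exactly the designed pairs", {
  ens <- gen_two_state_ensemble(n_frames = 200, seed = 12)
  contacts <- intradomain_contacts(ens$frames, ens$topology, ens$ranges,
                                   domains = "WW")
  fl <- select_fluctuating_pairs(contacts)
  design <- ens$truth$contact_design
  expect_setequal(fl$pair, paste0(design$i, "-", design$j))
  expect_true(all(fl$domain == "WW"))
  expect_equal(unname(attr(fl, "domain_counts")["WW"]), nrow(design))
  # constant pairs are excluded, toggling pairs included, by construction
  expect_false("1-2" %in% fl$pair)
  expect_true(all(fl$variance > 0))
  expect_equal(fl$nonlocal, fl$sequence_separation >= 3)
})

test_that("hydrogen-bond occupancy applies both geometric cutoffs and sums to Pi", {
  # linear N-H...O at 2.9 A, angle 180: occupied in every frame
  topo <- mk_topo(c(1, 1, 2), c("N", "H", "O"), c("N", "H", "O"))
  topo$h_of[2] <- 1L
  topo$donor[1] <- TRUE
  topo$acceptor[c(1, 3)] <- TRUE
  geom <- function(dz) rbind(c(0, 0, 0), c(0, 0, -1), c(0, 0, -dz))
  fr <- mk_frames(geom(2.9), geom(2.9))
  hb <- hbond_occupancy(fr, topo)
  expect_equal(hb$bonds$occupancy, 1)
  expect_equal(hb$pairs$pi, 1)
  # same geometry at 3.5 A fails the distance cutoff
  expect_equal(nrow(hbond_occupancy(mk_frames(geom(3.5)), topo)$bonds), 0)
  # bent geometry: acceptor 2 A from H at a 120-degree D-H...A angle passes
  # the distance cutoff (D-A = 2.65 A) but fails the 135-degree angle rule
  bent_fr <- mk_frames(rbind(c(0, 0, 0), c(0, 0, -1),
                             c(0, 2 * sin(pi / 3), -1 + 2 * cos(2 * pi / 3))))
  expect_equal(nrow(hbond_occupancy(bent_fr, topo)$bonds), 0)

  # two distinct bonds between one residue pair: Pi is the occupancy sum
  topo2 <- mk_topo(c(1, 1, 1, 1, 2, 2), c("N", "H", "ND", "HD", "O", "OD"),
                   c("N", "H", "N", "H", "O", "O"))
  topo2$h_of[c(2, 4)] <- c(1L, 3L)
  topo2$donor[c(1, 3)] <- TRUE
  topo2$acceptor[c(1, 3, 5, 6)] <- TRUE
  g2 <- function(on2) rbind(
    c(0, 0, 0), c(0, 0, -1), c(10, 0, 0), c(10, 0, -1),
    c(0, 0, -2.9), if (on2) c(10, 0, -2.9) else c(10, 0, -9))
  fr2 <- mk_frames(g2(TRUE), g2(FALSE))
  hb2 <- hbond_occupancy(fr2, topo2)
  expect_equal(sort(hb2$bonds$occupancy), c(0.5, 1.0))
  expect_equal(hb2$pairs$pi, 1.5)
  # Pi is non-decreasing in the distance cutoff
  hb_wide <- hbond_occupancy(fr2, topo2, dist_cutoff = 8.95)
  expect_gte(hb_wide$pairs$pi, hb2$pairs$pi)
})

test_that("geometric observables are invariant under rigid transforms", {
  ens <- gen_two_state_ensemble(n_frames = 20, seed = 30)
  set.seed(99)
  for (rep in 1:3) {
    ft <- rigid_transform_frames(ens$frames)
    d0 <- distance_series(ens$frames, ens$topology, "com:1-20", "com:21-50")
    d1 <- distance_series(ft, ens$topology, "com:1-20", "com:21-50")
    expect_equal(d1$values, d0$values, tolerance = 1e-9)
    c0 <- contact_number_series(ens$frames, ens$topology, 5, 7)
    c1 <- contact_number_series(ft, ens$topology, 5, 7)
    expect_identical(c1$counts, c0$counts)
    h0 <- hbond_occupancy(ens$frames, ens$topology, residues = 1:20)
    h1 <- hbond_occupancy(ft, ens$topology, residues = 1:20)
    expect_equal(h1$bonds$occupancy, h0$bonds$occupancy, tolerance = 1e-12)
  }
})
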