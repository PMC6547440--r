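test_that("charge assignment reproduces formal charges", {
  tab <- charge_radius_table()
  # single internal thymidine with phosphate: net -1 e
  dt <- tab[tab$residue == "DT", ]
  res <- data.frame(name = dt$atom, element = substr(dt$atom, 1, 1),
                    x = rnorm(nrow(dt)), y = rnorm(nrow(dt)), z = 0,
                    occupancy = 1, altloc = "", bfactor = 0, resname = "DT",
                    seqid = 1L, icode = "", chain = "A", is_hetatm = FALSE)
  s <- new_structure(res, "thymidine")
  ch <- assign_charges_radii(s, tab)
  expect_equal(sum(ch$charge), -1, tolerance = 1e-3)
  expect_true(all(ch$radius > 0))
  # 16-bp duplex with 5'-OH ends: 15 phosphates per strand
  d <- build_duplex(alt_seq("ta", 16), preset_profile("ideal_b", 16))
  chd <- assign_charges_radii(d, tab)
  expect_equal(sum(chd$charge), -30, tolerance = 0.01)
  # empty selection
  empty <- assign_charges_radii(d, tab, atom_selection(polymer = "protein"))
  expect_equal(nrow(empty), 0L)
  # unknown keys are reported exhaustively
  bad <- d; bad$atoms$name[c(1, 5)] <- c("XX", "YY")
  err <- tryCatch(assign_charges_radii(bad, tab), error = conditionMessage)
  expect_match(err, "DT XX"); expect_match(err, "DT YY")
})

test_that("grid design follows scale, fill and centring rules", {
  ch <- point_charge()
  ch2 <- rbind(ch, ch); ch2$x <- c(0, 70); ch2$radius <- 1e-6
  class(ch2) <- c("charged_atoms", "data.frame")
  g <- make_grid(ch2, pb_params(scale = 1, fill = 70))
  edge <- (g$dims[1] - 1) * g$spacing
  expect_equal(g$spacing, 1)
  expect_equal(edge, 100, tolerance = 1)           # 70 Å extent / 0.70
  expect_true(all(g$dims %% 2 == 1))               # odd node counts
  centre <- g$origin + (g$dims - 1) / 2 * g$spacing
  expect_equal(centre[1], 35, tolerance = g$spacing)
  expect_equal(centre[2:3], c(0, 0), tolerance = g$spacing)
  # paper scale: 4 grids/Å -> 0.25 Å spacing
  expect_equal(make_grid(ch, pb_params(scale = 4))$spacing, 0.25)
  # node budget guard
  expect_error(make_grid(ch2, pb_params(scale = 4, node_budget = 1e5)),
               "coarser scale")
})

test_that("solver matches Coulomb and Debye-Hückel closed forms", {
  ch <- point_charge(-1)
  grid <- oracle_grid()
  # uniform dielectric, no salt
  g <- solve_pb(ch, pb_params(epsin = 80, epsout = 80, salt = 0,
                              probe = 0, stern = 0), grid = grid)
  for (r in c(5, 7, 10, 12, 15)) {
    expect_equal(sample_potential(g, c(r, 0, 0)), coulomb_phi(-1, r),
                 tolerance = 0.05)
    expect_equal(sample_potential(g, c(0, 0, -r)), coulomb_phi(-1, r),
                 tolerance = 0.05)
  }
  # screened case
  gs <- solve_pb(ch, pb_params(epsin = 80, epsout = 80, salt = 0.145,
                               probe = 0, stern = 0), grid = grid)
  expect_equal(1 / gs$kappa, 8.06, tolerance = 0.02)  # Debye length at 0.145 M
  for (r in c(5, 10, 15))
    expect_equal(sample_potential(gs, c(0, r, 0)),
                 yukawa_phi(-1, r, gs$kappa), tolerance = 0.10)
  # zero charge -> zero field
  g0 <- solve_pb(point_charge(0), pb_params(epsin = 80, epsout = 80,
                                            salt = 0.145, probe = 0,
                                            stern = 0), grid = grid)
  expect_equal(max(abs(g0$values)), 0)
  # linearity: doubling the charge doubles the potential
  g2 <- solve_pb(point_charge(-2), pb_params(epsin = 80, epsout = 80,
                                             salt = 0.145, probe = 0,
                                             stern = 0), grid = grid)
  expect_equal(g2$values, 2 * gs$values, tolerance = 0.01)
})

test_that("flux through a centred box recovers 4*pi*q (Gauss law)", {
  ch <- point_charge(-1)
  grid <- oracle_grid()
  g <- solve_pb(ch, pb_params(epsin = 80, epsout = 80, salt = 0, probe = 0,
                              stern = 0), grid = grid)
  phi <- g$values; h <- g$spacing
  idx <- function(v) round((v - g$origin[1]) / h) + 1
  a <- 10; ia <- idx(-a):idx(a)
  flux <- 0
  for (sgn in c(-1, 1)) {
    i0 <- idx(sgn * a)
    flux <- flux + sgn * 80 * h^2 * (
      sum((phi[i0 + 1, ia, ia] - phi[i0 - 1, ia, ia]) / (2 * h)) +
        sum((phi[ia, i0 + 1, ia] - phi[ia, i0 - 1, ia]) / (2 * h)) +
        sum((phi[ia, ia, i0 + 1] - phi[ia, ia, i0 - 1]) / (2 * h)))
  }
  lb <- minorgroove:::bjerrum_vacuum(298.15)
  expect_equal(abs(flux), 4 * pi * lb, tolerance = 0.05)
})

test_that("7-point sampler: constant and linear fields", {
  grid <- structure(list(origin = c(0, 0, 0), spacing = 0.5,
                         dims = c(11L, 11L, 11L),
                         values = array(3.25, c(11, 11, 11))),
                    class = "potential_grid")
  expect_equal(sample_potential(grid, c(2.5, 2.5, 2.5)), 3.25)
  # linear field: symmetric neighbours cancel, leaving the nodal value
  ax <- (0:10) * 0.5
  grid$values <- array(rep(2 * ax, times = 121), c(11, 11, 11))
  expect_equal(sample_potential(grid, c(2.5, 1.5, 3.5)), 2 * 2.5)
  expect_equal(sample_potential(grid, c(2.6, 1.4, 3.4)), 2 * 2.5) # nearest node
  expect_error(sample_potential(grid, c(0.1, 2.5, 2.5)), "outside")
  expect_error(sample_potential(grid, c(2.5, 2.5, 5.2)), "outside")
})

test_that("groove potentials: degenerate correlation and analytic sign", {
  s <- build_duplex(alt_seq("ta", 12), preset_profile("ideal_b", 12))
  prof <- minor_groove_widths(s, find_base_pairs(s))
  const_grid <- structure(list(origin = c(-60, -60, -60), spacing = 2,
                               dims = c(61L, 61L, 61L),
                               values = array(-1, c(61, 61, 61))),
                          class = "potential_grid")
  res <- groove_potential_profile(const_grid, prof)
  expect_true(is.na(res$correlation))
  expect_match(res$note, "undefined")
  expect_equal(res$mean_potential, -1)
  # monotone width profile in the analytic Yukawa field of its own charges:
  # narrower entries are more negative, so the correlation sign is positive
  n <- 14
  intra <- preset_profile("ideal_b", n)$intra
  intra$propeller <- seq(0, -18, length.out = n)
  sm <- build_duplex(alt_seq("ta", n),
                     helical_profile(intra, preset_profile("ideal_b", n)$step))
  pm <- minor_groove_widths(sm, find_base_pairs(sm))
  ch <- assign_charges_radii(sm)
  lb <- minorgroove:::bjerrum_vacuum(298.15)
  kap <- sqrt(4 * pi * lb * 2 * 0.145 * 6.02214076e-4 / 80)
  pot <- vapply(seq_len(nrow(pm)), function(k) {
    d <- sqrt((ch$x - pm$mid_x[k])^2 + (ch$y - pm$mid_y[k])^2 +
                (ch$z - pm$mid_z[k])^2)
    sum(lb * ch$charge * exp(-kap * d) / (80 * d))
  }, numeric(1))
  expect_gt(stats::cor(pm$width, pot), 0)
})

test_that("solver output is translation-equivariant and grid-stable", {
  s <- build_duplex(alt_seq("gc", 8), preset_profile("gc_like", 8))
  prof <- minor_groove_widths(s, find_base_pairs(s))
  ch <- assign_charges_radii(s)
  pp <- pb_params(scale = 2)
  g1 <- solve_pb(ch, pp)
  v1 <- vapply(seq_len(nrow(prof)), function(k)
    sample_potential(g1, c(prof$mid_x[k], prof$mid_y[k], prof$mid_z[k])),
    numeric(1))
  expect_true(all(v1 < 0))   # minor-groove midpoints are all negative
  # shift solute and grid together by a whole number of spacings
  sh <- c(3, -2, 5) * g1$spacing
  ch2 <- ch; ch2$x <- ch$x + sh[1]; ch2$y <- ch$y + sh[2]; ch2$z <- ch$z + sh[3]
  grid2 <- list(origin = g1$origin + sh, spacing = g1$spacing, dims = g1$dims)
  g2 <- solve_pb(ch2, pp, grid = grid2)
  v2 <- vapply(seq_len(nrow(prof)), function(k)
    sample_potential(g2, c(prof$mid_x[k] + sh[1], prof$mid_y[k] + sh[2],
                           prof$mid_z[k] + sh[3])), numeric(1))
  expect_equal(v2, v1, tolerance = 1e-6)
})

test_that("groove samples are stable from 2 to 4 grids/Å on a 10-bp duplex", {
  s <- build_duplex(alt_seq("ta", 10), preset_profile("ta_like", 10))
  prof <- minor_groove_widths(s, find_base_pairs(s))
  ch <- assign_charges_radii(s)
  p2 <- groove_potential_profile(solve_pb(ch, pb_params(scale = 2)),
                                 prof)$profile$potential
  p4 <- groove_potential_profile(solve_pb(ch, pb_params(scale = 4)),
                                 prof)$profile$potential
  expect_lt(max(abs(p2 - p4)), 0.3)
})

test_that("non-convergence raises an informative error", {
  ch <- point_charge(-1)
  expect_error(
    solve_pb(ch, pb_params(epsin = 80, epsout = 80, salt = 0, probe = 0,
                           stern = 0, maxit = 2L), grid = oracle_grid(10, 1)),
    "did not converge")
})

test_that("potential grids export to OpenDX", {
  ch <- point_charge(-1)
  g <- solve_pb(ch, pb_params(epsin = 80, epsout = 80, salt = 0, probe = 0,
                              stern = 0), grid = oracle_grid(5, 1))
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  lines <- readLines(f)
  expect_match(lines[2], "gridpositions counts 11 11 11")
  expect_match(lines, "object 3 class array", all = FALSE)
  start <- grep("data follows", lines) + 1L
  nums <- as.numeric(unlist(strsplit(trimws(paste(
    lines[start:(start + ceiling(prod(g$dims) / 3) - 1)], collapse = " ")),
    " +")))
  expect_equal(length(nums), prod(g$dims))
  # first data value corresponds to values[1,1,1] (x,y,z order, z fastest)
  expect_equal(nums[1], g$values[1, 1, 1], tolerance = 1e-5)
  expect_equal(nums[2], g$values[1, 1, 2], tolerance = 1e-5)
})
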