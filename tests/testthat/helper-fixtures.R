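# shared fixtures, all generated in code

alt_seq <- function(kind, n) {
  paste(rep(switch(kind, ta = c("T", "A"), gc = c("G", "C")),
            length.out = n), collapse = "")
}

# random helical profile inside the admissible B-form box
random_profile <- function(n) {
  intra <- data.frame(
    shear = runif(n, -0.3, 0.3), stretch = runif(n, -0.2, 0.2),
    stagger = runif(n, -0.3, 0.3), buckle = runif(n, -10, 10),
    propeller = runif(n, -20, 10), opening = runif(n, -4, 4))
  step <- data.frame(
    shift = runif(n - 1, -0.8, 0.8), slide = runif(n - 1, -0.8, 0.8),
    rise = runif(n - 1, 2.8, 4.0), tilt = runif(n - 1, -6, 6),
    roll = runif(n - 1, -8, 8), twist = runif(n - 1, 25, 45))
  helical_profile(intra, step)
}

random_sequence <- function(n) paste(sample(c("A", "T", "G", "C"), n,
                                            replace = TRUE), collapse = "")

# point-charge test fixture for the PB oracles
point_charge <- function(q = -1) {
  ch <- data.frame(x = 0, y = 0, z = 0, charge = q, radius = 0.1,
                   residue = "X", atom = "Q", stringsAsFactors = FALSE)
  class(ch) <- c("charged_atoms", "data.frame")
  ch
}

oracle_grid <- function(half = 22, h = 0.5) {
  nn <- as.integer(2 * half / h) + 1L
  list(origin = c(-half, -half, -half), spacing = h, dims = rep(nn, 3L))
}

# uniform-dielectric analytic forms, kT/e
coulomb_phi <- function(q, r, eps = 80, temperature = 298.15)
  minorgroove:::bjerrum_vacuum(temperature) * q / (eps * r)

yukawa_phi <- function(q, r, kappa, eps = 80, temperature = 298.15)
  minorgroove:::bjerrum_vacuum(temperature) * q * exp(-kappa * r) / (eps * r)

# a tiny synthetic protein chain: glycine backbone stubs at given centres
stub_protein_atoms <- function(centres, chain = "P") {
  do.call(rbind, lapply(seq_len(nrow(centres)), function(i)
    data.frame(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
               x = centres[i, 1] + c(0, 0.5, 1.0, 1.5),
               y = centres[i, 2], z = centres[i, 3],
               occupancy = 1, altloc = "", bfactor = 0, resname = "GLY",
               seqid = i, icode = "", chain = chain, is_hetatm = FALSE,
               is_water = FALSE, stringsAsFactors = FALSE)))
}

expect_rotation <- function(R, tol = 1e-8) {
  expect_lt(max(abs(crossprod(R) - diag(3))), tol)
  expect_equal(det(R), 1, tolerance = tol)
}
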