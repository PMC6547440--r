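# physical constants (SI)
.ELEM_CHARGE <- 1.602176634e-19
.EPS0 <- 8.8541878128e-12
.KBOLTZ <- 1.380649e-23
.AVOGADRO <- 6.02214076e23

# vacuum Bjerrum length e^2/(4 pi eps0 kT) in Å at temperature T
bjerrum_vacuum <- function(temperature) {
  .ELEM_CHARGE^2 / (4 * pi * .EPS0 * .KBOLTZ * temperature) * 1e10
}

#' Parameters for the linearized Poisson-Boltzmann solve
#'
#' Defaults follow the reproduction setting: interior dielectric 2, solvent
#' dielectric 80, 0.145 M 1:1 salt, 1.4 Å solvent probe, 2.0 Å Stern
#' (ion-exclusion) layer, 4 grids/Å, solute filling 70% of the box edge
#' (linear fill), 298.15 K. `fill_mode = "volumetric"` applies the literal
#' volumetric reading of the fill factor instead.
#'
#' @param epsin,epsout interior / exterior relative dielectric.
#' @param salt 1:1 ionic strength, mol/L.
#' @param probe solvent probe radius, Å.
#' @param stern Stern-layer thickness, Å.
#' @param scale grid scale, nodes per Å.
#' @param fill percent of the box edge occupied by the solute's largest
#'   linear extent (0-100, exclusive).
#' @param fill_mode "linear" or "volumetric".
#' @param temperature Kelvin.
#' @param tol max-residual convergence tolerance, kT/e.
#' @param maxit maximum SOR sweeps.
#' @param boundary boundary condition kind; only "dh_monopole" (Debye-Hückel
#'   monopole on the box faces) is implemented.
#' @param node_budget maximum number of lattice nodes before erroring.
#' @return list of class `pb_params`.
#' @export
pb_params <- function(epsin = 2, epsout = 80, salt = 0.145, probe = 1.4,
                      stern = 2.0, scale = 4, fill = 70,
                      fill_mode = c("linear", "volumetric"),
                      temperature = 298.15, tol = 1e-4, maxit = 10000L,
                      boundary = "dh_monopole", node_budget = 6.4e7) {
  fill_mode <- match.arg(fill_mode)
  stopifnot(epsin > 0, epsout > 0, salt >= 0, probe >= 0, stern >= 0,
            scale > 0, fill > 0, fill < 100, temperature > 0, tol > 0)
  boundary <- match.arg(boundary, "dh_monopole")
  structure(as.list(environment()), class = "pb_params")
}

#' Load the charge/radius table
#'
#' The shipped table is a synthetic AMBER-style reconstruction (see the
#' methods vignette): hydrogens are collapsed onto bonded heavy atoms, the
#' full -1 e phosphodiester charge is carried on P, and base+C1' groups are
#' neutral with a chemically realistic internal distribution. Protein
#' residues carry formal charges on Arg/Lys/Asp/Glu side-chain termini.
#'
#' @param path optional path to a TSV (residue, atom, charge_e, radius_A,
#'   provenance); defaults to the shipped fixture.
#' @return data.frame of class `charge_radius_table`.
#' @export
charge_radius_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "charges_synthetic_amberlike.tsv",
                        package = "minorgroove", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "atom", "charge_e", "radius_A") %in% names(tab)))
  if (any(tab$radius_A <= 0)) stop("charge table contains non-positive radii")
  class(tab) <- c("charge_radius_table", "data.frame")
  tab
}

#' Assign partial charges and radii to structure atoms
#'
#' Every selected non-water heavy atom must be present in the table;
#' unknown (residue, atom) keys raise one error listing all misses.
#' Hydrogens are skipped (their charges are collapsed in the table).
#'
#' @param s a structure.
#' @param table a [charge_radius_table()].
#' @param sel atoms to charge; default: nucleic-acid chains only (the shape
#'   comparison is between naked DNA molecules). Use
#'   `atom_selection()` to include everything or a protein selection to add
#'   the protein.
#' @return data.frame of class `charged_atoms` with columns x, y, z, charge,
#'   radius, residue, atom.
#' @export
assign_charges_radii <- function(s, table = charge_radius_table(),
                                 sel = atom_selection(polymer = "nucleic")) {
  a <- select_atoms(s, sel)
  a <- a[!a$is_water & a$element != "H", , drop = FALSE]
  if (!nrow(a)) {
    out <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      charge = numeric(), radius = numeric(),
                      residue = character(), atom = character())
    class(out) <- c("charged_atoms", "data.frame")
    return(out)
  }
  key <- paste(a$resname, a$name)
  tkey <- paste(table$residue, table$atom)
  hit <- match(key, tkey)
  if (anyNA(hit)) {
    miss <- sort(unique(key[is.na(hit)]))
    stop("no charge/radius entry for: ", paste(miss, collapse = ", "))
  }
  out <- data.frame(x = a$x, y = a$y, z = a$z,
                    charge = table$charge_e[hit], radius = table$radius_A[hit],
                    residue = a$resname, atom = a$name,
                    stringsAsFactors = FALSE)
  class(out) <- c("charged_atoms", "data.frame")
  out
}

#' Design the cubic lattice for a PB solve
#'
#' Spacing is 1/scale; the box is centred on the solute geometric centre and
#' sized so the solute's largest linear extent (including radii) occupies
#' `fill` percent of the box edge (or of the box volume for the volumetric
#' fill mode); node counts are rounded up to odd numbers.
#'
#' @param charged a `charged_atoms` table.
#' @param params a [pb_params()].
#' @return list with `origin`, `spacing`, `dims`.
#' @export
make_grid <- function(charged, params = pb_params()) {
  stopifnot(nrow(charged) >= 1)
  h <- 1 / params$scale
  lo <- c(min(charged$x - charged$radius), min(charged$y - charged$radius),
          min(charged$z - charged$radius))
  hi <- c(max(charged$x + charged$radius), max(charged$y + charged$radius),
          max(charged$z + charged$radius))
  extent <- max(hi - lo, h)   # largest linear dimension of the solute
  edge <- if (params$fill_mode == "linear") {
    extent / (params$fill / 100)
  } else {
    # literal reading: solute bounding volume = fill% of box volume
    (prod(pmax(hi - lo, h)) / (params$fill / 100))^(1 / 3)
  }
  edge <- max(edge, extent + 4 * h)   # always keep a halo
  center <- (lo + hi) / 2
  nn <- ceiling(edge / h) + 1L
  nn <- as.integer(nn + (1L - nn %% 2L))  # odd counts
  dims <- rep(nn, 3L)
  if (prod(dims) > params$node_budget)
    stop(sprintf("grid of %d^3 = %.3g nodes exceeds the node budget (%.3g); use a coarser scale",
                 nn, prod(dims), params$node_budget))
  origin <- center - (nn - 1L) / 2 * h
  list(origin = origin, spacing = h, dims = dims)
}

trilinear_spread <- function(charged, grid) {
  rho <- array(0, grid$dims)
  h <- grid$spacing
  for (k in seq_len(nrow(charged))) {
    f <- (c(charged$x[k], charged$y[k], charged$z[k]) - grid$origin) / h
    i0 <- floor(f); w <- f - i0; i0 <- as.integer(i0) + 1L  # 1-based
    if (any(i0 < 1L) || any(i0 + 1L > grid$dims))
      stop("charge outside the grid during spreading")
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      rho[i0[1] + dx, i0[2] + dy, i0[3] + dz] <-
        rho[i0[1] + dx, i0[2] + dy, i0[3] + dz] + wt * charged$charge[k]
    }
  }
  rho
}

dh_boundary <- function(grid, charged, params, kappa) {
  lb <- bjerrum_vacuum(params$temperature)
  Q <- sum(charged$charge)
  ctr <- c(sum(charged$x * abs(charged$charge)),
           sum(charged$y * abs(charged$charge)),
           sum(charged$z * abs(charged$charge)))
  denom <- sum(abs(charged$charge))
  ctr <- if (denom > 0) ctr / denom else
    c(mean(charged$x), mean(charged$y), mean(charged$z))
  phi <- array(0, grid$dims)
  if (Q == 0) return(phi)
  ax <- grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing
  ay <- grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing
  az <- grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing
  face <- function(ix, iy, iz) {
    dx <- ax[ix] - ctr[1]; dy <- ay[iy] - ctr[2]; dz <- az[iz] - ctr[3]
    g <- expand.grid(dx = dx, dy = dy, dz = dz)
    r <- pmax(sqrt(g$dx^2 + g$dy^2 + g$dz^2), grid$spacing)
    array(lb * Q * exp(-kappa * r) / (params$epsout * r),
          dim = c(length(ix), length(iy), length(iz)))
  }
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  phi[1, , ] <- face(1, seq_len(ny), seq_len(nz))
  phi[nx, , ] <- face(nx, seq_len(ny), seq_len(nz))
  phi[, 1, ] <- face(seq_len(nx), 1, seq_len(nz))
  phi[, ny, ] <- face(seq_len(nx), ny, seq_len(nz))
  phi[, , 1] <- face(seq_len(nx), seq_len(ny), 1)
  phi[, , nz] <- face(seq_len(nx), seq_len(ny), nz)
  phi
}

#' Solve the linearized Poisson-Boltzmann equation on a lattice
#'
#' Finite-difference solve of \eqn{\nabla\cdot(\epsilon\nabla\phi) -
#' \epsilon_{out}\bar\kappa^2\lambda\phi = -4\pi\lambda_B\rho} with the
#' molecular-surface dielectric assignment (probe-expanded then probe-eroded
#' lattice masks), Stern-layer ion exclusion, trilinear charge spreading,
#' Debye-Hückel monopole boundary values, and red-black SOR iteration with a
#' Chebyshev-estimated relaxation factor. The potential is returned in kT/e.
#'
#' @param charged a `charged_atoms` table from [assign_charges_radii()].
#' @param params a [pb_params()].
#' @param grid optional grid from [make_grid()]; computed if missing.
#' @return object of class `potential_grid`: `origin`, `spacing`, `dims`,
#'   `values` (3-D array, kT/e), `params`, solver diagnostics.
#' @export
solve_pb <- function(charged, params = pb_params(), grid = NULL) {
  stopifnot(inherits(params, "pb_params"), nrow(charged) >= 1)
  if (is.null(grid)) grid <- make_grid(charged, params)
  lb <- bjerrum_vacuum(params$temperature)
  nion <- 2 * params$salt * .AVOGADRO * 1e-27   # ions per Å^3 (1:1 salt)
  kap2 <- 4 * pi * lb * nion / params$epsout    # (1/Debye length)^2
  kappa <- sqrt(kap2)
  masks <- cpp_pb_masks(as.matrix(charged[, c("x", "y", "z")]),
                        charged$radius, grid$origin, grid$spacing,
                        as.integer(grid$dims), params$probe, params$stern)
  rho <- trilinear_spread(charged, grid)
  rho_term <- 4 * pi * lb * rho / grid$spacing
  phi <- dh_boundary(grid, charged, params, kappa)
  sol <- cpp_pb_sor(as.integer(grid$dims), masks$interior, masks$ion_excluded,
                    as.numeric(rho_term), phi, params$epsin, params$epsout,
                    kap2 * grid$spacing^2, params$tol, as.integer(params$maxit))
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 dims = grid$dims, values = phi, params = params,
                 kappa = kappa, iterations = sol$iterations,
                 residual = sol$residual, omega = sol$omega),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("<potential_grid %dx%dx%d, h=%.3g Å, range [%.2f, %.2f] kT/e, %d sweeps>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              min(x$values), max(x$values), x$iterations))
  invisible(x)
}

#' Seven-point average of the potential at a point
#'
#' Maps the point to the nearest lattice node and averages that node with its
#' six axis neighbours.
#'
#' @param grid a `potential_grid`.
#' @param point length-3 coordinate, Å.
#' @return potential in kT/e.
#' @export
sample_potential <- function(grid, point) {
  stopifnot(inherits(grid, "potential_grid"), length(point) == 3)
  i <- round((point - grid$origin) / grid$spacing) + 1
  if (any(i < 2) || any(i > grid$dims - 1))
    stop("point (with its one-node halo) lies outside the grid interior")
  v <- grid$values
  (v[i[1], i[2], i[3]] +
     v[i[1] - 1, i[2], i[3]] + v[i[1] + 1, i[2], i[3]] +
     v[i[1], i[2] - 1, i[3]] + v[i[1], i[2] + 1, i[3]] +
     v[i[1], i[2], i[3] - 1] + v[i[1], i[2], i[3] + 1]) / 7
}

#' Sample the potential at every groove midpoint
#'
#' @param grid a `potential_grid`.
#' @param profile a `groove_profile`.
#' @return list with the profile (gaining a `potential` column), the mean
#'   potential over entries, and the Pearson correlation between width and
#'   potential (NA with an explanatory note when degenerate).
#' @export
groove_potential_profile <- function(grid, profile) {
  stopifnot(inherits(profile, "groove_profile"))
  pot <- vapply(seq_len(nrow(profile)), function(k)
    sample_potential(grid, c(profile$mid_x[k], profile$mid_y[k],
                             profile$mid_z[k])), numeric(1))
  profile$potential <- pot
  corr <- NA_real_; note <- NULL
  if (nrow(profile) >= 3 &&
      stats::sd(profile$width) > 0 && stats::sd(pot) > 0) {
    corr <- stats::cor(profile$width, pot)
  } else {
    note <- "correlation undefined (fewer than 3 entries or zero variance)"
  }
  list(profile = profile, mean_potential = mean(pot),
       correlation = corr, note = note)
}

#' Write a potential grid in OpenDX scalar-field format
#'
#' @param grid a `potential_grid`.
#' @param path output path.
#' @export
write_dx <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$dims
  writeLines(c(
    "# OpenDX scalar field (potential, kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX order: z fastest
  vals <- aperm(grid$values, c(3, 2, 1))
  v <- as.vector(vals)
  pad <- (-length(v)) %% 3
  if (pad) v <- c(v, rep(NA, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "potential" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
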