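#' Helical parameter profile
#'
#' Container for the six intra-base-pair parameters per pair (shear, stretch,
#' stagger in Å; buckle, propeller, opening in degrees) and the six step
#' parameters per dinucleotide step (shift, slide, rise in Å; tilt, roll,
#' twist in degrees), indexed 5'->3' along the reference strand.
#'
#' @param intra data.frame (n rows) with columns shear, stretch, stagger,
#'   buckle, propeller, opening.
#' @param step data.frame (n-1 rows) with columns shift, slide, rise, tilt,
#'   roll, twist.
#' @return object of class `helical_profile`.
#' @export
helical_profile <- function(intra, step) {
  intra_cols <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening")
  step_cols <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  stopifnot(all(intra_cols %in% names(intra)), all(step_cols %in% names(step)))
  intra <- intra[intra_cols]; step <- step[step_cols]
  if (nrow(step) != nrow(intra) - 1L)
    stop("step profile must have exactly one fewer row than intra profile")
  if (any(step$rise <= 0)) stop("rise must be positive")
  structure(list(intra = intra, step = step, n_bp = nrow(intra)),
            class = "helical_profile")
}

#' Preset helical-parameter profiles
#'
#' `ideal_b` is canonical straight B-DNA (twist 36.0°, rise 3.4 Å, all other
#' parameters zero). `ta_like` encodes the narrow-minor-groove geometry typical
#' of TA-rich tracts (twist 37.1°, propeller −11.2°); `gc_like` the wider
#' groove of GC-rich DNA (twist 35.3°, propeller −7.3°). Remaining parameters
#' are zero unless configured afterwards.
#'
#' @param name one of "ideal_b", "ta_like", "gc_like".
#' @param n_bp number of base pairs (>= 2).
#' @return a [helical_profile()].
#' @export
preset_profile <- function(name = c("ideal_b", "ta_like", "gc_like"), n_bp) {
  name <- match.arg(name)
  if (n_bp < 2) stop("n_bp must be >= 2")
  p <- switch(name,
    ideal_b = list(twist = 36.0, propeller = 0),
    ta_like = list(twist = 37.1, propeller = -11.2),
    gc_like = list(twist = 35.3, propeller = -7.3))
  intra <- data.frame(shear = 0, stretch = 0, stagger = 0, buckle = 0,
                      propeller = rep(p$propeller, n_bp), opening = 0)
  step <- data.frame(shift = 0, slide = 0, rise = rep(3.4, n_bp - 1L),
                     tilt = 0, roll = 0, twist = p$twist)
  helical_profile(intra, step)
}

#' Build an all-atom B-form DNA duplex from a sequence and a profile
#'
#' Deterministically constructs two antiparallel chains (the second the
#' reverse complement of `sequence`) by placing idealized standard-frame base
#' templates according to the intra-base-pair parameters and chaining pair
#' frames by the mid-step-triad composition. The backbone is minimal: every
#' residue carries C1' and, except at each 5' terminus, the phosphate P placed
#' from an idealized position in the base frame. Chain A is numbered 1..n
#' 5'->3'; chain B is numbered 1..n along its own 5'->3' direction.
#'
#' @param sequence 5'->3' string over ATGC (reference strand).
#' @param profile a [helical_profile()] with matching length.
#' @return a `groove_structure` with chains "A" and "B".
#' @export
build_duplex <- function(sequence, profile) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq_chars) < 2) stop("sequence must have length >= 2")
  if (!all(seq_chars %in% c("A", "T", "G", "C")))
    stop("sequence must contain only A, T, G, C")
  stopifnot(inherits(profile, "helical_profile"))
  n <- length(seq_chars)
  if (profile$n_bp != n)
    stop("profile length (", profile$n_bp, ") does not match sequence length (",
         n, ")")
  tmpl <- base_templates()
  flipmat <- diag(c(1, -1, -1))

  # pair (mid) frames chained along the reference strand
  frames <- vector("list", n)
  frames[[1]] <- list(frame = diag(3), origin = c(0, 0, 0))
  for (k in seq_len(n - 1L)) {
    st <- profile$step[k, ]
    nxt <- step_compose(frames[[k]]$frame, frames[[k]]$origin,
                        c(st$shift, st$slide, st$rise,
                          st$tilt, st$roll, st$twist))
    frames[[k + 1L]] <- list(frame = nxt$frame, origin = nxt$origin)
  }

  rows_a <- vector("list", n)
  rows_b <- vector("list", n)
  for (k in seq_len(n)) {
    ip <- profile$intra[k, ]
    halves <- step_split(frames[[k]]$frame, frames[[k]]$origin,
                         c(ip$shear, ip$stretch, ip$stagger,
                           ip$buckle, ip$propeller, ip$opening))
    # strand I base frame is the first triad, flipped strand II the second
    fI <- halves$frame1; oI <- halves$origin1
    fIIf <- halves$frame2; oII <- halves$origin2
    fII <- fIIf %*% flipmat
    baseI <- seq_chars[k]
    baseII <- COMPLEMENT[[baseI]]
    place <- function(base, fr, o, has_p) {
      t <- tmpl[[base]]
      keep <- if (has_p) t else t[t$atom != "P", , drop = FALSE]
      xyz <- template_xyz(keep) %*% t(fr)
      data.frame(name = keep$atom,
                 element = substr(keep$atom, 1, 1),
                 x = xyz[, 1] + o[1], y = xyz[, 2] + o[2], z = xyz[, 3] + o[3],
                 occupancy = 1, altloc = "", bfactor = 0,
                 resname = paste0("D", base),
                 stringsAsFactors = FALSE)
    }
    ra <- place(baseI, fI, oI, has_p = k > 1L)       # 5' terminus of A is k=1
    ra$seqid <- k
    rb <- place(baseII, fII, oII, has_p = k < n)     # 5' terminus of B is k=n
    rb$seqid <- n + 1L - k                           # B numbered along its own 5'->3'
    rows_a[[k]] <- ra
    rows_b[[k]] <- rb
  }
  at_a <- do.call(rbind, rows_a)
  at_b <- do.call(rbind, rev(rows_b))  # B residues in its own 5'->3' order
  at_a$chain <- "A"; at_b$chain <- "B"
  atoms <- rbind(at_a, at_b)
  atoms$icode <- ""
  atoms$is_hetatm <- FALSE
  new_structure(atoms, identifier = sprintf("synthetic-duplex-%dbp", n))
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param s a structure.
#' @param sigma per-coordinate standard deviation, Å (>= 0).
#' @param seed integer seed; the perturbation is reproducible for a fixed seed.
#' @return perturbed structure.
#' @export
perturb_coordinates <- function(s, sigma, seed) {
  stopifnot(inherits(s, "groove_structure"), sigma >= 0)
  if (sigma == 0) return(s)
  n <- n_atoms(s)
  old <- .Random.seed_exists()
  rng <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  eps <- matrix(stats::rnorm(3L * n, sd = sigma), ncol = 3L)
  if (old) assign(".Random.seed", rng, envir = globalenv())
  s$atoms$x <- s$atoms$x + eps[, 1]
  s$atoms$y <- s$atoms$y + eps[, 2]
  s$atoms$z <- s$atoms$z + eps[, 3]
  s
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

#' Simulate a chemical-shift-perturbation titration series
#'
#' Generates observed combined shifts from the exact single-site binding
#' isotherm with receptor depletion,
#' \deqn{\Delta\delta(L) = \Delta\delta_{max}\,
#'   \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4 P L}}{2P},}
#' plus optional Gaussian noise.
#'
#' @param kd dissociation constant (M, > 0).
#' @param ddmax saturating shift change (ppm).
#' @param receptor_conc receptor concentration P (M, > 0).
#' @param ligand_concs non-negative, non-decreasing ligand concentrations (M).
#' @param noise_sd Gaussian noise standard deviation (ppm).
#' @param seed integer seed for the noise.
#' @return object of class `titration_series`: list with `P`, `L`, `dd`.
#' @export
synth_titration <- function(kd, ddmax, receptor_conc, ligand_concs,
                            noise_sd = 0, seed = 1) {
  stopifnot(kd > 0, receptor_conc > 0, all(ligand_concs >= 0),
            !is.unsorted(ligand_concs))
  dd <- binding_isotherm(ligand_concs, kd, ddmax, receptor_conc)
  if (noise_sd > 0) {
    old <- .Random.seed_exists()
    rng <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    dd <- dd + stats::rnorm(length(dd), sd = noise_sd)
    if (old) assign(".Random.seed", rng, envir = globalenv())
  }
  titration_series(receptor_conc, ligand_concs, dd)
}

#' Construct a titration series
#'
#' @param P receptor concentration (M).
#' @param L ligand concentrations (M, non-decreasing).
#' @param dd observed combined shifts (ppm).
#' @export
titration_series <- function(P, L, dd) {
  stopifnot(P > 0, length(L) == length(dd), all(is.finite(dd)),
            !is.unsorted(L))
  structure(list(P = P, L = as.numeric(L), dd = as.numeric(dd)),
            class = "titration_series")
}

binding_isotherm <- function(L, kd, ddmax, P) {
  s <- P + L + kd
  ddmax * (s - sqrt(s^2 - 4 * P * L)) / (2 * P)
}
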