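#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% x + t` onto `y` over paired coordinate rows. Reflections are never
#' returned: the smallest singular direction is negated when the optimal
#' orthogonal transform is improper.
#'
#' @param x,y n x 3 coordinate matrices (moving, target), paired by row.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (Å) and `n_atoms`; class `superposition_result`.
#' @export
kabsch_superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)) || ncol(x) != 3L)
    stop("x and y must be matching n x 3 matrices")
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 atom pairs for superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  sx <- svd(xc)$d   # planar sets are fine; only rank-1 (collinear) is not
  if (sx[2] < 1e-8 * max(sx[1], 1))
    stop("degenerate (collinear) coordinates: superposition is ill-defined")
  H <- crossprod(xc, yc)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(xc %*% t(R), 2, -cy)  # R x + t
  rmsd <- sqrt(mean(rowSums((fit - y)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n_atoms = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4f Å over %d atoms>\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' Match equivalent atoms between two structures
#'
#' Atoms are paired by (chain, author seqid, insertion code, atom name) within
#' the selection; residues present in only one structure are dropped and
#' reported in the `dropped` attribute.
#'
#' @param a,b structures.
#' @param sel an [atom_selection()] applied to both.
#' @param mode "ca_only" (protein C-alpha) or "backbone" (N, CA, C, O).
#' @return list with `xyz_a`, `xyz_b` (paired n x 3 matrices), `keys`,
#'   `dropped` (residue keys present on one side only); class
#'   `atom_correspondence`.
#' @export
match_equivalent_atoms <- function(a, b, sel = atom_selection(),
                                   mode = c("ca_only", "backbone")) {
  mode <- match.arg(mode)
  names_wanted <- switch(mode, ca_only = "CA", backbone = c("N", "CA", "C", "O"))
  ta <- select_atoms(a, sel); tb <- select_atoms(b, sel)
  ta <- ta[ta$name %in% names_wanted, , drop = FALSE]
  tb <- tb[tb$name %in% names_wanted, , drop = FALSE]
  ka <- paste(ta$chain, ta$seqid, ta$icode, ta$name, sep = "\r")
  kb <- paste(tb$chain, tb$seqid, tb$icode, tb$name, sep = "\r")
  common <- intersect(ka, kb)
  if (!length(common)) stop("no equivalent atoms matched")
  ia <- match(common, ka); ib <- match(common, kb)
  res_a <- unique(paste(ta$chain, ta$seqid, ta$icode, sep = "/"))
  res_b <- unique(paste(tb$chain, tb$seqid, tb$icode, sep = "/"))
  dropped <- c(setdiff(res_a, res_b), setdiff(res_b, res_a))
  structure(list(
    xyz_a = cbind(ta$x[ia], ta$y[ia], ta$z[ia]),
    xyz_b = cbind(tb$x[ib], tb$y[ib], tb$z[ib]),
    keys = gsub("\r", "/", common),
    mode = mode,
    dropped = dropped), class = "atom_correspondence")
}

#' Superpose structure b onto structure a over matched atoms
#'
#' @inheritParams match_equivalent_atoms
#' @return `superposition_result` with the correspondence attached.
#' @export
superpose_structures <- function(a, b, sel = atom_selection(),
                                 mode = c("ca_only", "backbone")) {
  corr <- match_equivalent_atoms(a, b, sel, mode)
  res <- kabsch_superpose(corr$xyz_b, corr$xyz_a)  # move b onto a
  res$correspondence <- corr
  res
}

#' Apply a rigid transform to all atoms of a structure
#' @keywords internal
transform_structure <- function(s, rotation, translation) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  out <- sweep(xyz %*% t(rotation), 2, -translation)
  s$atoms$x <- out[, 1]; s$atoms$y <- out[, 2]; s$atoms$z <- out[, 3]
  s
}
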