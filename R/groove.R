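#' Minor-groove width profile by the cross-strand phosphate method
#'
#' The width at reference-strand base i is the raw Euclidean distance between
#' the phosphate P of base i on strand I and the phosphate of the strand-II
#' residue four pairs away in the pairing register. Both candidate offsets
#' (+4 and -4 pairs) are evaluated and the one whose connecting vector crosses
#' the minor groove (checked against the pair-frame minor-groove direction,
#' the -x side of the standard frame) is kept. No phosphate-radius subtraction
#' is applied (set `subtract_radius` for the 5.8 Å-subtracted convention).
#' Entries whose phosphates are missing (chain termini) are omitted and listed
#' in the `omitted` attribute.
#'
#' @param s a structure.
#' @param pairs a `basepair_list` from [find_base_pairs()].
#' @param subtract_radius if TRUE subtract 5.8 Å (twice the phosphate group
#'   radius) from each width; default FALSE (raw distances, the scale used
#'   for narrow-groove readout work).
#' @return data.frame of class `groove_profile` with columns i, chainI,
#'   seqidI, chainII, seqidII, width, mid_x, mid_y, mid_z, bound, plus the
#'   phosphate coordinates used; attributes `omitted` and `subtract_radius`.
#' @export
minor_groove_widths <- function(s, pairs, subtract_radius = FALSE) {
  stopifnot(inherits(pairs, "basepair_list"))
  n <- length(pairs)
  if (n < 5L) {
    warning("fewer than 5 base pairs; empty groove profile")
    return(empty_groove_profile(subtract_radius))
  }
  p_of <- function(res) {
    xyz <- residue_xyz(res, "P")
    if (any(is.na(xyz))) NULL else as.vector(xyz)
  }
  entries <- list()
  omitted <- list()
  for (i in seq_len(n)) {
    pI <- p_of(pairs[[i]]$resI)
    if (is.null(pI)) {
      omitted[[length(omitted) + 1L]] <-
        data.frame(i = i, reason = "missing strand-I phosphate")
      next
    }
    best <- NULL
    for (off in c(4L, -4L)) {
      j <- i + off
      if (j < 1L || j > n) next
      pII <- p_of(pairs[[j]]$resII)
      if (is.null(pII)) next
      mid <- (pI + pII) / 2
      # midpoint must sit on the minor-groove side of the local pair frame
      m <- i + off %/% 2L
      fr <- pairs[[m]]$pair_frame; o <- pairs[[m]]$pair_origin
      side <- sum((mid - o) * fr[, 1])   # +x is the major groove
      if (side >= 0) next   # major-groove side: not a minor-groove span
      cand <- list(j = j, pII = pII, mid = mid, side = side)
      if (is.null(best) || cand$side < best$side) best <- cand
    }
    if (is.null(best)) {
      omitted[[length(omitted) + 1L]] <-
        data.frame(i = i,
                   reason = "no minor-groove cross-strand phosphate at +/-4 pairs")
      next
    }
    w <- vnorm(pI - best$pII)
    entries[[length(entries) + 1L]] <- data.frame(
      i = i,
      chainI = pairs[[i]]$frameI$chain, seqidI = pairs[[i]]$frameI$seqid,
      chainII = pairs[[best$j]]$frameII$chain,
      seqidII = pairs[[best$j]]$frameII$seqid,
      width = if (subtract_radius) w - 5.8 else w,
      mid_x = best$mid[1], mid_y = best$mid[2], mid_z = best$mid[3],
      bound = NA,
      pI_x = pI[1], pI_y = pI[2], pI_z = pI[3],
      pII_x = best$pII[1], pII_y = best$pII[2], pII_z = best$pII[3],
      stringsAsFactors = FALSE)
  }
  prof <- if (length(entries)) do.call(rbind, entries)
          else empty_groove_profile(subtract_radius)
  class(prof) <- c("groove_profile", "data.frame")
  attr(prof, "omitted") <- if (length(omitted)) do.call(rbind, omitted) else NULL
  attr(prof, "subtract_radius") <- subtract_radius
  prof
}

empty_groove_profile <- function(subtract_radius = FALSE) {
  prof <- data.frame(i = integer(), chainI = character(), seqidI = integer(),
                     chainII = character(), seqidII = integer(),
                     width = numeric(), mid_x = numeric(), mid_y = numeric(),
                     mid_z = numeric(), bound = logical(),
                     pI_x = numeric(), pI_y = numeric(), pI_z = numeric(),
                     pII_x = numeric(), pII_y = numeric(), pII_z = numeric(),
                     stringsAsFactors = FALSE)
  class(prof) <- c("groove_profile", "data.frame")
  attr(prof, "subtract_radius") <- subtract_radius
  prof
}

#' Annotate groove entries with a bound-protein footprint
#'
#' An entry is marked bound if any selected protein atom lies within `cutoff`
#' of either of its phosphates.
#'
#' @param profile a `groove_profile`.
#' @param s the structure holding the protein.
#' @param protein_sel selection of protein atoms (default: all protein
#'   residues).
#' @param cutoff heavy-atom distance cutoff, Å (default 5.0).
#' @return the profile with the `bound` column filled.
#' @export
annotate_footprint <- function(profile, s,
                               protein_sel = atom_selection(polymer = "protein"),
                               cutoff = 5.0) {
  stopifnot(inherits(profile, "groove_profile"))
  prot <- select_atoms(s, protein_sel)
  if (!nrow(prot)) {
    warning("empty protein selection; all groove entries marked free")
    profile$bound <- FALSE
    return(profile)
  }
  px <- prot$x; py <- prot$y; pz <- prot$z
  near <- function(x, y, z) {
    any((px - x)^2 + (py - y)^2 + (pz - z)^2 <= cutoff^2)
  }
  profile$bound <- vapply(seq_len(nrow(profile)), function(k) {
    near(profile$pI_x[k], profile$pI_y[k], profile$pI_z[k]) ||
      near(profile$pII_x[k], profile$pII_y[k], profile$pII_z[k])
  }, logical(1))
  attr(profile, "footprint_cutoff") <- cutoff
  profile
}

#' Global bend of the duplex axis
#'
#' Fits a straight axis segment (first principal direction of pair-frame
#' origins) to the first and last `window_bp` pairs; the bend is the angle
#' between the two directions (magnitude only), also normalized per window
#' from the number of steps separating the segment centres. This is an
#' axis-segment approximation, not a full curvilinear-axis reconstruction.
#'
#' @param pairs a `basepair_list`.
#' @param window_bp segment length in base pairs (default 6).
#' @return list of class `bend_estimate`: `window_bp`, `bend_total`
#'   (degrees over the full length), `bend_per_window` (degrees per
#'   `window_bp` pairs), and the two axis directions.
#' @export
global_bend <- function(pairs, window_bp = 6L) {
  stopifnot(inherits(pairs, "basepair_list"))
  n <- length(pairs)
  if (n < window_bp + 1L)
    stop("need at least window_bp + 1 = ", window_bp + 1L, " pairs, have ", n)
  origins <- t(vapply(pairs, function(p) p$pair_origin, numeric(3)))
  overall <- origins[n, ] - origins[1, ]
  seg_dir <- function(rows) {
    m <- origins[rows, , drop = FALSE]
    mc <- sweep(m, 2, colMeans(m))
    d <- svd(mc)$v[, 1]
    if (sum(d * overall) < 0) d <- -d
    d
  }
  d1 <- seg_dir(seq_len(window_bp))
  d2 <- seg_dir(seq(n - window_bp + 1L, n))
  ang <- ddeg(acos(max(-1, min(1, sum(d1 * d2)))))
  span <- n - window_bp            # steps between segment centres
  structure(list(window_bp = window_bp,
                 bend_total = ang,
                 bend_per_window = ang * window_bp / max(span, 1L),
                 axis_first = d1, axis_last = d2),
            class = "bend_estimate")
}

#' Write a groove profile as TSV
#'
#' @param profile a `groove_profile`.
#' @param path output path.
#' @export
write_groove_tsv <- function(profile, path) {
  cols <- c("i", "chainI", "seqidI", "chainII", "seqidII", "width",
            "mid_x", "mid_y", "mid_z", "bound")
  out <- as.data.frame(profile)[, cols]
  names(out)[names(out) == "width"] <- "width_A"
  names(out)[names(out) == "bound"] <- "bound_flag"
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
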