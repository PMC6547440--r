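# Watson-Crick edge donor/acceptor heavy-atom contacts, per pair type
WC_CONTACTS <- list(
  "A:T" = list(c("N1", "N3"), c("N6", "O4")),
  "G:C" = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")))

# pairing acceptance criteria (permissive for crystal-structure distortion,
# strict enough to reject stacked neighbours)
PAIR_CRITERIA <- list(
  c1c1_range = c(8.5, 12.0),
  max_contact_dist = 3.6,
  min_contacts = 2L,
  max_normal_angle = 65,      # degrees
  max_origin_dist = 2.5)      # Å between fitted frame origins

#' Fit the standard base reference frame to a residue
#'
#' Least-squares rigid superposition of the idealized standard-frame base
#' template onto the observed base ring atoms. The returned frame is the
#' image of the template frame (axes = rotation columns, origin = translated
#' template origin).
#'
#' @param res residue atom table (one residue's rows of a structure).
#' @param templates templates from [base_templates()].
#' @return list with `frame` (3x3), `origin`, `rmsd` (Å), `base` (letter),
#'   `chain`, `seqid`, `icode`.
#' @export
base_frame <- function(res, templates = base_templates()) {
  resname <- res$resname[1]
  base <- base_letter(resname)
  if (is.na(base))
    stop("residue ", resname, " ", res$seqid[1],
         " is not a canonical deoxynucleotide")
  ring <- RING_ATOMS[[base]]
  tmpl <- templates[[base]]
  common <- intersect(ring, intersect(tmpl$atom, res$name))
  if (length(common) < 6L)
    stop(sprintf("residue %s %s/%d: only %d of the template ring atoms present (need >= 6)",
                 resname, res$chain[1], res$seqid[1], length(common)))
  tx <- template_xyz(tmpl)[common, , drop = FALSE]
  ox <- residue_xyz(res, common)
  fit <- kabsch_superpose(tx, ox)
  list(frame = fit$rotation, origin = as.vector(fit$translation),
       rmsd = fit$rmsd, base = base,
       chain = res$chain[1], seqid = res$seqid[1], icode = res$icode[1])
}

residue_key <- function(res) paste(res$chain[1], res$seqid[1], res$icode[1])

pair_candidate <- function(ri, rj, fi, fj, crit = PAIR_CRITERIA) {
  # complementarity
  if (COMPLEMENT[[fi$base]] != fj$base) return(NULL)
  c1i <- residue_xyz(ri, "C1'"); c1j <- residue_xyz(rj, "C1'")
  if (any(is.na(c1i)) || any(is.na(c1j))) return(NULL)
  dc1 <- vnorm(c1i - c1j)
  if (dc1 < crit$c1c1_range[1] || dc1 > crit$c1c1_range[2]) return(NULL)
  # WC-edge hydrogen-bond-like contacts
  key <- if (fi$base %in% c("A", "G")) paste(fi$base, fj$base, sep = ":")
         else paste(fj$base, fi$base, sep = ":")
  contacts <- WC_CONTACTS[[key]]
  pu <- if (fi$base %in% c("A", "G")) ri else rj   # purine residue
  py <- if (fi$base %in% c("A", "G")) rj else ri
  nhits <- 0L
  for (ct in contacts) {
    pa <- residue_xyz(pu, ct[1]); pb <- residue_xyz(py, ct[2])
    if (any(is.na(pa)) || any(is.na(pb))) next
    if (vnorm(pa - pb) < crit$max_contact_dist) nhits <- nhits + 1L
  }
  if (nhits < crit$min_contacts) return(NULL)
  # base-plane normals (antiparallel pairing flips z; compare undirected)
  ang <- ddeg(acos(max(-1, min(1, abs(sum(fi$frame[, 3] * fj$frame[, 3]))))))
  if (ang > crit$max_normal_angle) return(NULL)
  dorig <- vnorm(fi$origin - fj$origin)
  if (dorig > crit$max_origin_dist) return(NULL)
  list(origin_dist = dorig, contacts = nhits)
}

#' Identify Watson-Crick base pairs in a structure
#'
#' All nucleotide residue pairs are screened against geometric criteria
#' (complementary bases; C1'-C1' distance 8.5-12 Å; at least two WC-edge
#' donor-acceptor contacts < 3.6 Å; base-plane normal angle < 65°; fitted
#' frame origins < 2.5 Å apart). Candidates are accepted greedily by
#' increasing frame-origin distance, each residue used at most once, and the
#' result is ordered 5'->3' along the reference strand.
#'
#' @param s a structure.
#' @param ref_chain reference (strand I) chain id; default: the first chain in
#'   structure order that contains a paired nucleotide.
#' @param templates base templates.
#' @return object of class `basepair_list`: list of pairs, each holding the
#'   two residue tables (`resI` on the reference strand), fitted frames, the
#'   pair (mid) frame and the six intra-base-pair parameters. Carries a
#'   `warnings` attribute; an empty structure yields an empty list plus a
#'   warning record, not an error.
#' @export
find_base_pairs <- function(s, ref_chain = NULL, templates = base_templates()) {
  residues <- split_residues(s)
  residues <- Filter(function(r) r$resname[1] %in% NT_CANON, residues)
  warnings <- character()
  if (length(residues) < 2L) {
    warnings <- "fewer than two nucleotide residues; no pairs searched"
    return(structure(list(), class = "basepair_list", warnings = warnings))
  }
  frames <- vector("list", length(residues))
  usable <- rep(TRUE, length(residues))
  for (i in seq_along(residues)) {
    f <- tryCatch(base_frame(residues[[i]], templates), error = function(e) e)
    if (inherits(f, "error")) {
      usable[i] <- FALSE
      warnings <- c(warnings, conditionMessage(f))
    } else frames[[i]] <- f
  }
  cand <- list()
  idx <- which(usable)
  for (a in seq_along(idx)) {
    for (b in seq_len(a - 1L)) {
      i <- idx[a]; j <- idx[b]
      hit <- pair_candidate(residues[[i]], residues[[j]],
                            frames[[i]], frames[[j]])
      if (!is.null(hit))
        cand[[length(cand) + 1L]] <- list(i = i, j = j,
                                          origin_dist = hit$origin_dist)
    }
  }
  if (!length(cand)) {
    warnings <- c(warnings, "no base pairs found")
    return(structure(list(), class = "basepair_list", warnings = warnings))
  }
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "origin_dist"))]
  used <- rep(FALSE, length(residues))
  accepted <- list()
  for (cd in cand) {
    if (used[cd$i] || used[cd$j]) next
    used[cd$i] <- used[cd$j] <- TRUE
    accepted[[length(accepted) + 1L]] <- cd
  }
  # reference strand: first structure-order chain with a paired nucleotide
  paired_idx <- unlist(lapply(accepted, function(cd) c(cd$i, cd$j)))
  chain_of <- vapply(residues, function(r) r$chain[1], character(1))
  chain_order <- unique(vapply(split_residues(s), function(r) r$chain[1],
                               character(1)))
  ref <- if (is.null(ref_chain))
    chain_order[chain_order %in% chain_of[paired_idx]][1] else ref_chain
  pairs <- lapply(accepted, function(cd) {
    on_ref <- chain_of[cd$i] == ref
    iI <- if (on_ref) cd$i else cd$j
    iII <- if (on_ref) cd$j else cd$i
    make_basepair(residues[[iI]], residues[[iII]],
                  frames[[iI]], frames[[iII]], order_index = iI)
  })
  ord <- order(vapply(pairs, function(p) attr(p, "order_index"), numeric(1)))
  structure(pairs[ord], class = "basepair_list",
            warnings = warnings, ref_chain = ref)
}

make_basepair <- function(resI, resII, frameI, frameII, order_index = NA) {
  flip <- diag(c(1, -1, -1))
  dec <- step_decompose(frameI$frame, frameI$origin,
                        frameII$frame %*% flip, frameII$origin)
  p <- structure(list(
    resI = resI, resII = resII,
    frameI = frameI, frameII = frameII,
    pair_frame = dec$mid_frame, pair_origin = dec$mid_origin,
    params = stats::setNames(dec$par, c("shear", "stretch", "stagger",
                                        "buckle", "propeller", "opening"))),
    class = "basepair")
  attr(p, "order_index") <- order_index
  p
}

#' Intra-base-pair parameters
#'
#' Decomposes the rigid transform from the strand-I base frame to the
#' 180°-flipped strand-II frame through the mean (pair) frame: shear,
#' stretch, stagger (Å) and buckle, propeller, opening (degrees), with the
#' standard sign convention (negative propeller is B-DNA-typical).
#'
#' @param p a `basepair` from [find_base_pairs()].
#' @return named numeric vector of the six parameters.
#' @export
intra_bp_params <- function(p) {
  stopifnot(inherits(p, "basepair"))
  p$params
}

#' Base-pair step parameters
#'
#' Mid-step-triad decomposition of the transform between consecutive pair
#' frames: shift, slide, rise (Å) and tilt, roll, twist (degrees). Also
#' reports `h_twist`, the rotation angle about the true screw axis of the
#' step (the helical-axis variant of twist).
#'
#' @param p1,p2 consecutive `basepair`s along the reference strand.
#' @return named numeric vector (shift, slide, rise, tilt, roll, twist,
#'   h_twist).
#' @export
step_params <- function(p1, p2) {
  stopifnot(inherits(p1, "basepair"), inherits(p2, "basepair"))
  dec <- step_decompose(p1$pair_frame, p1$pair_origin,
                        p2$pair_frame, p2$pair_origin)
  out <- stats::setNames(dec$par, c("shift", "slide", "rise",
                                    "tilt", "roll", "twist"))
  R <- crossprod(p1$pair_frame, p2$pair_frame)
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  h <- ddeg(acos(ct))
  # sign the screw rotation by its axis relative to the mean helical
  # direction, both expressed in frame-1 coordinates
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(ax) > 1e-9) {
    zm <- c(0, 0, 1) + R[, 3]
    if (sum(ax * zm) < 0) h <- -h
  } else if (out["twist"] < 0) h <- -h
  c(out, h_twist = h)
}

#' Tables of intra and step parameters for a pair list
#'
#' @param pairs a `basepair_list`.
#' @return list with `intra` (one row per pair, with residue ids and fit
#'   RMSDs) and `step` (one row per consecutive step).
#' @export
basepair_tables <- function(pairs) {
  stopifnot(inherits(pairs, "basepair_list"))
  if (!length(pairs)) return(list(intra = NULL, step = NULL))
  intra <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    data.frame(i = k,
               chainI = p$frameI$chain, seqidI = p$frameI$seqid,
               chainII = p$frameII$chain, seqidII = p$frameII$seqid,
               baseI = p$frameI$base, baseII = p$frameII$base,
               t(p$params),
               fit_rmsd_I = p$frameI$rmsd, fit_rmsd_II = p$frameII$rmsd,
               stringsAsFactors = FALSE)
  }))
  step <- NULL
  if (length(pairs) > 1L)
    step <- do.call(rbind, lapply(seq_len(length(pairs) - 1L), function(k) {
      data.frame(i = k, t(step_params(pairs[[k]], pairs[[k + 1L]])))
    }))
  list(intra = intra, step = step)
}

#' Average helical parameters with acceptance filtering
#'
#' Arithmetic means over accepted pairs (per-base fit RMSD < 0.5 Å,
#' |propeller| < 90°) and accepted steps (rise in (1, 6) Å). Excluded rows
#' are listed with reasons.
#'
#' @param intra,step tables from [basepair_tables()].
#' @return list with `summary` (parameter, mean, sd, n) and `excluded`.
#' @export
average_params <- function(intra, step = NULL) {
  if (is.null(intra) || !nrow(intra)) stop("no base pairs to average")
  excluded <- list()
  ok_pair <- intra$fit_rmsd_I < 0.5 & intra$fit_rmsd_II < 0.5 &
    abs(intra$propeller) < 90
  if (any(!ok_pair))
    excluded$pairs <- data.frame(i = intra$i[!ok_pair],
                                 reason = "fit_rmsd >= 0.5 or |propeller| >= 90")
  intra_cols <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening")
  rows <- lapply(intra_cols, function(cl) {
    v <- intra[[cl]][ok_pair]
    data.frame(parameter = cl, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v))
  })
  if (!is.null(step) && nrow(step)) {
    ok_step <- step$rise > 1 & step$rise < 6
    if (any(!ok_step))
      excluded$steps <- data.frame(i = step$i[!ok_step],
                                   reason = "rise outside (1, 6) Å")
    step_cols <- c("shift", "slide", "rise", "tilt", "roll", "twist", "h_twist")
    rows <- c(rows, lapply(step_cols, function(cl) {
      v <- step[[cl]][ok_step]
      data.frame(parameter = cl, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v))
    }))
  }
  list(summary = do.call(rbind, rows), excluded = excluded)
}
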