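#' @useDynLib minorgroove, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE", "SEC", "PYL")
NT_CANON <- c("DA", "DT", "DG", "DC")
WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")

# deposited files use a zoo of aliases for deoxynucleotides
NT_ALIASES <- c(
  DA = "DA", A = "DA", ADE = "DA", `+A` = "DA",
  DT = "DT", T = "DT", THY = "DT", `+T` = "DT",
  DG = "DG", G = "DG", GUA = "DG", `+G` = "DG",
  DC = "DC", C = "DC", CYT = "DC", `+C` = "DC")

normalize_resname <- function(x) {
  hit <- NT_ALIASES[x]
  ifelse(is.na(hit), x, hit)
}

#' Create a structure object from an atom table
#'
#' The coordinate model is a flat atom table (one row per atom, in file order)
#' plus an identifier, in the style of the field's PDB toolkits. Chains are
#' ordered by first appearance; residues within a chain by (seqid, icode).
#'
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`,
#'   `occupancy`, `altloc`, `bfactor`, `resname`, `seqid`, `icode`, `chain`,
#'   `is_hetatm`, `is_water`.
#' @param identifier free-text structure id.
#' @return object of class `groove_structure`.
#' @export
new_structure <- function(atoms, identifier = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "element", "x", "y", "z", "occupancy", "altloc",
            "bfactor", "resname", "seqid", "icode", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$is_hetatm)) atoms$is_hetatm <- FALSE
  atoms$is_water <- atoms$resname %in% WATER_NAMES
  structure(list(identifier = identifier, atoms = atoms),
            class = "groove_structure")
}

#' @export
print.groove_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<groove_structure '%s': %d atoms, %d chains (%s), %d residues>\n",
              x$identifier, nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              nrow(unique(a[, c("chain", "seqid", "icode")]))))
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

guess_format <- function(path) {
  lx <- tolower(path)
  if (grepl("\\.(cif|mmcif)$", lx)) return("mmcif")
  if (grepl("\\.(pdb|ent)$", lx)) return("pdb")
  head <- readLines(path, n = 20L, warn = FALSE)
  if (any(grepl("^(data_|loop_|_atom_site\\.)", head))) "mmcif" else "pdb"
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Reads the first model only. Alternate locations are resolved by keeping
#' the highest-occupancy location (ties broken by the lexicographically
#' smallest altloc code). Waters are retained but flagged; hydrogens are
#' retained if present. DNA residue-name aliases (A/ADE/...) are normalized
#' to DA/DT/DG/DC.
#'
#' @param path file path.
#' @param format one of "pdb", "mmcif", "auto".
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  atoms <- switch(format,
                  pdb = parse_pdb(path),
                  mmcif = parse_mmcif(path))
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms parsed from ", path)
  atoms <- resolve_altlocs(atoms)
  atoms$resname <- normalize_resname(atoms$resname)
  new_structure(atoms, identifier = sub("\\.[^.]*$", "", basename(path)))
}

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  sel <- grepl("^(ATOM  |HETATM)", lines)
  rec <- lines[sel]
  if (!length(rec)) return(empty_atom_table())
  rec <- formatC(rec, width = -80)  # pad short lines
  fw <- function(from, to) trimws(substring(rec, from, to))
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(fw(from, to)))
    bad <- which(!is.finite(v))
    if (what %in% c("x", "y", "z") && length(bad))
      stop(sprintf("PDB format error: unreadable %s coordinate at record %d (line '%s')",
                   what, bad[1], substr(rec[bad[1]], 1, 30)))
    v
  }
  elem <- fw(77, 78)
  name <- fw(13, 16)
  # infer element from the atom name when column 77-78 is absent
  fallback <- sub("^[0-9']*", "", name)
  fallback <- ifelse(substr(fallback, 1, 2) %in%
                       c("CL", "BR", "FE", "MG", "ZN", "MN", "NA"),
                     substr(fallback, 1, 2), substr(fallback, 1, 1))
  elem <- ifelse(elem == "", fallback, elem)
  occ <- num(55, 60, "occupancy"); occ[!is.finite(occ)] <- 1
  bf <- num(61, 66, "bfactor"); bf[!is.finite(bf)] <- 0
  data.frame(
    name = name,
    element = toupper(elem),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = occ,
    altloc = fw(17, 17),
    bfactor = bf,
    resname = fw(18, 21),
    seqid = as.integer(suppressWarnings(as.numeric(fw(23, 26)))),
    icode = fw(27, 27),
    chain = fw(22, 22),
    is_hetatm = substring(rec, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
}

empty_atom_table <- function() {
  data.frame(name = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), altloc = character(),
             bfactor = numeric(), resname = character(),
             seqid = integer(), icode = character(), chain = character(),
             is_hetatm = logical(), stringsAsFactors = FALSE)
}

# minimal mmCIF reader: the atom_site loop only
parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  atab <- NULL
  for (ls in loop_starts) {
    i <- ls + 1L
    fields <- character()
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      fields <- c(fields, trimws(lines[i])); i <- i + 1L
    }
    if (!length(fields) || !all(grepl("^_atom_site\\.", fields))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- lines[i]
      if (grepl("^\\s*(#|loop_|_|data_)", ln) || !nzchar(trimws(ln))) break
      rows[[length(rows) + 1L]] <- cif_tokens(ln)
      i <- i + 1L
    }
    if (!length(rows)) next
    nf <- length(fields)
    ok <- vapply(rows, function(r) length(r) == nf, logical(1))
    if (!all(ok))
      stop("mmCIF format error: atom_site row with wrong token count at data line ",
           which(!ok)[1])
    m <- do.call(rbind, rows)
    colnames(m) <- fields
    atab <- as.data.frame(m, stringsAsFactors = FALSE)
    break
  }
  if (is.null(atab)) return(empty_atom_table())
  if ("pdbx_PDB_model_num" %in% names(atab)) {
    first <- atab$pdbx_PDB_model_num[1]
    atab <- atab[atab$pdbx_PDB_model_num == first, , drop = FALSE]
  }
  get <- function(...) {
    for (k in c(...)) if (k %in% names(atab)) return(atab[[k]])
    rep(NA_character_, nrow(atab))
  }
  blank <- function(v) ifelse(v %in% c(".", "?") | is.na(v), "", v)
  data.frame(
    name = blank(get("auth_atom_id", "label_atom_id")),
    element = toupper(blank(get("type_symbol"))),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occupancy = {
      o <- suppressWarnings(as.numeric(blank(get("occupancy"))))
      ifelse(is.finite(o), o, 1)
    },
    altloc = blank(get("label_alt_id")),
    bfactor = {
      b <- suppressWarnings(as.numeric(blank(get("B_iso_or_equiv"))))
      ifelse(is.finite(b), b, 0)
    },
    resname = blank(get("auth_comp_id", "label_comp_id")),
    seqid = as.integer(suppressWarnings(as.numeric(
      blank(get("auth_seq_id", "label_seq_id"))))),
    icode = blank(get("pdbx_PDB_ins_code")),
    chain = blank(get("auth_asym_id", "label_asym_id")),
    is_hetatm = blank(get("group_PDB")) == "HETATM",
    stringsAsFactors = FALSE)
}

cif_tokens <- function(line) {
  # whitespace-separated tokens; honour single/double quoting
  out <- character()
  s <- line
  while (nzchar(s <- sub("^\\s+", "", s))) {
    ch <- substr(s, 1, 1)
    if (ch == "'" || ch == '"') {
      m <- regexpr(paste0("^", ch, "([^", ch, "]*)", ch), s)
      tok <- substr(s, 2, attr(m, "match.length") - 1L)
      s <- substring(s, attr(m, "match.length") + 1L)
    } else {
      m <- regexpr("^\\S+", s)
      tok <- substr(s, 1, attr(m, "match.length"))
      s <- substring(s, attr(m, "match.length") + 1L)
    }
    out <- c(out, tok)
  }
  out
}

resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$seqid, atoms$icode, atoms$resname,
               atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[atoms$altloc != ""])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    best <- idx[order(-atoms$occupancy[idx], atoms$altloc[idx])][1]
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Build an atom selection
#'
#' All filters are conjunctive; an unset (NULL) filter matches everything.
#'
#' @param chains character vector of chain ids, or NULL.
#' @param seqid_range length-2 integer vector, inclusive author-seqid range,
#'   or NULL.
#' @param atom_names character vector of atom names, or NULL.
#' @param polymer "protein", "nucleic" or NULL.
#' @return object of class `atom_selection`.
#' @export
atom_selection <- function(chains = NULL, seqid_range = NULL,
                           atom_names = NULL, polymer = NULL) {
  if (!is.null(polymer)) polymer <- match.arg(polymer, c("protein", "nucleic"))
  if (!is.null(seqid_range) && length(seqid_range) != 2L)
    stop("seqid_range must be length 2")
  structure(list(chains = chains, seqid_range = seqid_range,
                 atom_names = atom_names, polymer = polymer),
            class = "atom_selection")
}

selection_mask <- function(s, sel) {
  a <- s$atoms
  m <- rep(TRUE, nrow(a))
  if (!is.null(sel$chains)) m <- m & a$chain %in% sel$chains
  if (!is.null(sel$seqid_range))
    m <- m & a$seqid >= sel$seqid_range[1] & a$seqid <= sel$seqid_range[2]
  if (!is.null(sel$atom_names)) m <- m & a$name %in% sel$atom_names
  if (!is.null(sel$polymer)) {
    m <- m & switch(sel$polymer,
                    protein = a$resname %in% AA3,
                    nucleic = a$resname %in% NT_CANON)
  }
  m
}

#' Select atoms from a structure
#'
#' @param s a structure.
#' @param sel an [atom_selection()]; defaults to everything.
#' @return data.frame of matching atom rows, in structure order.
#' @export
select_atoms <- function(s, sel = atom_selection()) {
  stopifnot(inherits(s, "groove_structure"), inherits(sel, "atom_selection"))
  s$atoms[selection_mask(s, sel), , drop = FALSE]
}

#' Split a structure into residues
#'
#' @return list of data.frames, one per residue, ordered by chain appearance
#'   then (seqid, icode).
#' @keywords internal
split_residues <- function(s, chains = NULL) {
  a <- s$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (!nrow(a)) return(list())
  chain_order <- unique(a$chain)
  out <- list()
  for (ch in chain_order) {
    ai <- a[a$chain == ch, , drop = FALSE]
    key <- paste(ai$seqid, ai$icode, sep = "\r")
    for (k in unique(key[order(ai$seqid, ai$icode)]))
      out[[length(out) + 1L]] <- ai[key == k, , drop = FALSE]
  }
  out
}

residue_xyz <- function(res, names) {
  idx <- match(names, res$name)
  m <- cbind(res$x[idx], res$y[idx], res$z[idx])
  rownames(m) <- names
  m
}

#' Write a structure as PDB
#'
#' Coordinates are written at 0.001 Å precision (the PDB fixed-width field).
#' Coordinates or counts that overflow the fixed-width fields raise an error
#' rather than being truncated.
#'
#' @param s a structure.
#' @param path output file path.
#' @param format only "pdb" is supported.
#' @export
write_structure <- function(s, path, format = "pdb") {
  stopifnot(inherits(s, "groove_structure"))
  format <- match.arg(format, "pdb")
  a <- s$atoms
  if (!nrow(a)) stop("refusing to write an empty structure")
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("coordinate overflow: |coordinate| must be < 10000 Å for PDB fields")
  if (nrow(a) > 99999) stop("atom count overflows PDB serial field")
  name_fmt <- ifelse(nchar(a$name) < 4 & !grepl("^[0-9]", a$name),
                     sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  rec <- ifelse(a$is_hetatm, "HETATM", "ATOM  ")
  lines <- character(0)
  serial <- 0L
  chains <- unique(a$chain)
  for (ch in chains) {
    idx <- which(a$chain == ch)
    serials <- serial + seq_along(idx)
    lines <- c(lines, sprintf(
      "%s%5d %s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec[idx], serials, name_fmt[idx], a$altloc[idx], a$resname[idx],
      ch, a$seqid[idx], a$icode[idx], a$x[idx], a$y[idx], a$z[idx],
      a$occupancy[idx], a$bfactor[idx], a$element[idx]))
    serial <- serial + length(idx)
    last <- idx[length(idx)]
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %-4s%1s%4d",
                              serial, a$resname[last], ch, a$seqid[last]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
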