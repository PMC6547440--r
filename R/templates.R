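# Idealized base geometry in the standard base reference frame
# (origin between the paired bases, x toward the major groove, y toward the
# reference-strand backbone, z along the helix toward the 3' end of the
# reference strand). Shipped as a plain-text fixture; cached per session.

.template_cache <- new.env(parent = emptyenv())

#' Load the idealized base templates
#'
#' Each template holds the heavy atoms of the base plus C1' in the standard
#' base reference frame, and the idealized backbone phosphate position used
#' by the duplex builder.
#'
#' @param path optional path to a template table (columns base, atom, x, y, z);
#'   defaults to the fixture shipped with the package.
#' @return named list (A, T, G, C) of data.frames with columns atom, x, y, z.
#' @export
base_templates <- function(path = NULL) {
  key <- if (is.null(path)) "default" else path
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  if (is.null(path))
    path <- system.file("extdata", "base_templates.tsv",
                        package = "minorgroove", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$base), function(d)
    data.frame(atom = d$atom, x = d$x, y = d$y, z = d$z,
               stringsAsFactors = FALSE))
  .template_cache[[key]] <- out
  out
}

template_xyz <- function(tmpl) {
  m <- cbind(tmpl$x, tmpl$y, tmpl$z)
  rownames(m) <- tmpl$atom
  m
}

# base ring atoms used for reference-frame fitting
RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"))

COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

base_letter <- function(resname) {
  l <- c(DA = "A", DT = "T", DG = "G", DC = "C")[resname]
  unname(l)
}
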