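#' Run the full groove-readout analysis on one structure
#'
#' Stage sequence: read (or accept) the structure, identify base pairs and
#' fit frames, compute intra/step helical parameters, measure the
#' minor-groove width profile, annotate the bound-protein footprint, estimate
#' the global bend, optionally solve the linearized PB equation for the DNA
#' and sample the potential at the groove midpoints, and correlate width with
#' potential. Deterministic given its options; every parameter used is
#' recorded in the report's provenance block.
#'
#' @param x a structure or a file path (PDB/mmCIF).
#' @param pb run the Poisson-Boltzmann stage (default TRUE).
#' @param pb_opts a [pb_params()]; tests and quick passes typically lower
#'   `scale` to 2.
#' @param ref_chain reference strand chain id (default: auto).
#' @param footprint_cutoff Å (default 5).
#' @param include_protein include protein atoms in the PB charge set
#'   (default FALSE: the comparison is between naked DNA shapes).
#' @param subtract_radius report groove widths with the 5.8 Å phosphate
#'   convention subtracted (default FALSE: raw P-P distances).
#' @return object of class `analysis_report`.
#' @export
analyze <- function(x, pb = TRUE, pb_opts = pb_params(), ref_chain = NULL,
                    footprint_cutoff = 5.0, include_protein = FALSE,
                    subtract_radius = FALSE) {
  s <- if (inherits(x, "groove_structure")) x else read_structure(x)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  pairs <- stage("find_base_pairs", find_base_pairs(s, ref_chain = ref_chain))
  if (length(pairs) < 5L)
    stop("[find_base_pairs] structure contains fewer than 5 DNA base pairs")
  tabs <- stage("basepair_tables", basepair_tables(pairs))
  avg <- stage("average_params", average_params(tabs$intra, tabs$step))
  profile <- stage("minor_groove_widths",
                   minor_groove_widths(s, pairs,
                                       subtract_radius = subtract_radius))
  profile <- stage("annotate_footprint",
                   suppressWarnings(
                     annotate_footprint(profile, s, cutoff = footprint_cutoff)))
  bend <- if (length(pairs) >= 7L)
    stage("global_bend", global_bend(pairs)) else NULL
  pbres <- NULL
  if (pb) {
    sel <- if (include_protein) atom_selection() else
      atom_selection(polymer = "nucleic")
    charged <- stage("assign_charges_radii",
                     assign_charges_radii(s, sel = sel))
    grid <- stage("solve_pb", solve_pb(charged, pb_opts))
    pbres <- stage("groove_potential_profile",
                   groove_potential_profile(grid, profile))
    profile <- pbres$profile
  }
  bound <- profile$bound %in% TRUE
  region_means <- list(
    all = mean(profile$width),
    bound = if (any(bound)) mean(profile$width[bound]) else NA_real_,
    free = if (any(!bound)) mean(profile$width[!bound]) else NA_real_)
  structure(list(
    id = s$identifier,
    n_pairs = length(pairs),
    pairs = pairs,
    basepair_table = tabs$intra,
    step_table = tabs$step,
    averages = avg,
    groove_profile = profile,
    region_means = region_means,
    bend = bend,
    mean_groove_potential = if (!is.null(pbres)) pbres$mean_potential else NA_real_,
    width_potential_correlation = if (!is.null(pbres)) pbres$correlation else NA_real_,
    warnings = attr(pairs, "warnings"),
    provenance = list(
      pb = pb, pb_params = if (pb) unclass(pb_opts)[
        c("epsin", "epsout", "salt", "probe", "stern", "scale", "fill",
          "fill_mode", "temperature", "tol", "maxit", "boundary")] else NULL,
      ref_chain = attr(pairs, "ref_chain"),
      footprint_cutoff = footprint_cutoff,
      include_protein = include_protein,
      subtract_radius = subtract_radius,
      package_version = as.character(utils::packageVersion("minorgroove")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  sm <- x$averages$summary
  g <- function(p) sm$mean[sm$parameter == p]
  cat(sprintf("<analysis_report '%s'>\n", x$id))
  cat(sprintf("  base pairs: %d   mean propeller: %.1f deg   mean twist: %.1f deg\n",
              x$n_pairs, g("propeller"), if (length(g("twist"))) g("twist") else NA))
  cat(sprintf("  minor-groove width (Å): all %.2f  bound %.2f  free %.2f\n",
              x$region_means$all, x$region_means$bound, x$region_means$free))
  if (!is.null(x$bend))
    cat(sprintf("  bend: %.2f deg per %d bp (%.2f deg total)\n",
                x$bend$bend_per_window, x$bend$window_bp, x$bend$bend_total))
  if (is.finite(x$mean_groove_potential))
    cat(sprintf("  mean groove potential: %.2f kT/e   width-potential r: %.3f\n",
                x$mean_groove_potential, x$width_potential_correlation))
  invisible(x)
}

#' Compare two analysis reports
#'
#' Paired differences (A minus B) of the averaged helical parameters, groove
#' widths, bend and mean groove potential; when both structures contain
#' protein, the C-alpha superposition RMSD is included.
#'
#' @param a,b `analysis_report`s.
#' @param structure_a,structure_b optional structures for the superposition
#'   row.
#' @return data.frame of class `comparison_table` with quantity, value_a,
#'   value_b, difference.
#' @export
compare_reports <- function(a, b, structure_a = NULL, structure_b = NULL) {
  stopifnot(inherits(a, "analysis_report"), inherits(b, "analysis_report"))
  avg <- function(r, p) {
    sm <- r$averages$summary
    v <- sm$mean[sm$parameter == p]
    if (length(v)) v else NA_real_
  }
  rows <- list()
  push <- function(q, va, vb)
    rows[[length(rows) + 1L]] <<- data.frame(quantity = q, value_a = va,
                                             value_b = vb,
                                             difference = va - vb)
  for (p in c("propeller", "twist", "h_twist", "rise", "roll"))
    push(paste0("mean_", p), avg(a, p), avg(b, p))
  push("mean_width", a$region_means$all, b$region_means$all)
  push("mean_width_bound", a$region_means$bound, b$region_means$bound)
  push("mean_width_free", a$region_means$free, b$region_means$free)
  if (!is.null(a$bend) && !is.null(b$bend))
    push("bend_per_window", a$bend$bend_per_window, b$bend$bend_per_window)
  push("mean_groove_potential", a$mean_groove_potential,
       b$mean_groove_potential)
  out <- do.call(rbind, rows)
  if (!is.null(structure_a) && !is.null(structure_b)) {
    sup <- tryCatch(
      superpose_structures(structure_a, structure_b,
                           atom_selection(polymer = "protein")),
      error = function(e) NULL)
    if (!is.null(sup)) {
      out <- rbind(out, data.frame(quantity = "protein_ca_rmsd",
                                   value_a = sup$rmsd, value_b = sup$rmsd,
                                   difference = 0))
      attr(out, "superposition") <- sup
    }
  }
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write an analysis report as JSON (with TSV side tables)
#'
#' @param report an `analysis_report`.
#' @param path JSON output path; `<path>_basepairs.tsv`, `<path>_steps.tsv`
#'   and `<path>_groove.tsv` are written alongside when `tables = TRUE`.
#' @param tables write the TSV side tables.
#' @export
write_report <- function(report, path, tables = TRUE) {
  stopifnot(inherits(report, "analysis_report"))
  out <- list(
    id = report$id,
    n_pairs = report$n_pairs,
    averages = report$averages$summary,
    region_means = report$region_means,
    bend = if (!is.null(report$bend)) unclass(report$bend) else NULL,
    mean_groove_potential = report$mean_groove_potential,
    width_potential_correlation = report$width_potential_correlation,
    warnings = report$warnings,
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (tables) {
    stem <- sub("\\.json$", "", path)
    utils::write.table(report$basepair_table,
                       paste0(stem, "_basepairs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(report$step_table))
      utils::write.table(report$step_table, paste0(stem, "_steps.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    write_groove_tsv(report$groove_profile, paste0(stem, "_groove.tsv"))
  }
  invisible(path)
}
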