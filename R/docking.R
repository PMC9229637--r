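# Docking free-energy bookkeeping: Ki conversion, ranking, halogen trend.

#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
R_KCAL <- 1.98720425864e-3

#' Inhibition constant from docking free energy
#'
#' The standard docking relation `Ki = exp(dG / (R T))` with
#' R = 1.98720425864e-3 kcal mol^-1 K^-1. A ΔG of −11.94 kcal/mol at 298.15 K
#' gives ~1.78 nM. Strictly increasing in `dg`.
#'
#' @param dg binding free energy, kcal/mol (negative = favorable). Vectorized.
#' @param temperature Kelvin, default 298.15.
#' @return Ki in mol/L.
#' @seealso [dg_from_ki()], [format_ki()]
#' @export
ki_from_binding_energy <- function(dg, temperature = 298.15) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("temperature must be positive (Kelvin)")
  exp(dg / (R_KCAL * temperature))
}

#' Docking free energy from an inhibition constant
#'
#' Log inversion of [ki_from_binding_energy()].
#'
#' @param ki_molar Ki in mol/L (> 0).
#' @param temperature Kelvin.
#' @return ΔG in kcal/mol.
#' @export
dg_from_ki <- function(ki_molar, temperature = 298.15) {
  if (any(ki_molar <= 0)) stop("ki_molar must be positive")
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("temperature must be positive (Kelvin)")
  R_KCAL * temperature * log(ki_molar)
}

#' Human-readable Ki with auto-scaled units
#'
#' @param ki_molar Ki in mol/L. Vectorized.
#' @param digits significant digits.
#' @return character, e.g. `"1.78 nM"`.
#' @export
format_ki <- function(ki_molar, digits = 3) {
  units <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  vapply(ki_molar, function(k) {
    u <- "pM"
    for (cand in names(units)) if (k >= units[[cand]]) { u <- cand; break }
    paste(signif(k / units[[u]], digits), u)
  }, character(1))
}

#' Rank docked ligands by binding free energy
#'
#' Most negative (strongest) first; ties broken lexicographically by
#' `compound_id`, so the ordering is deterministic.
#'
#' @param records data.frame with columns `compound_id`, `binding_energy`.
#' @return the same data.frame, reordered, with a `rank` column prepended.
#' @export
rank_ligands <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("compound_id", "binding_energy") %in% names(records)))
    stop("records must have columns compound_id and binding_energy")
  if (nrow(records) == 0L) stop("no docking records to rank")
  o <- order(records$binding_energy, as.character(records$compound_id))
  out <- records[o, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Mean binding energy per halogen class and series trend
#'
#' Tests the expected potency ordering of a halogen series: the trend flag is
#' TRUE iff mean ΔG satisfies F > Cl > Br > I in signed kcal/mol (iodine most
#' negative, i.e. strongest binder). With any class absent the flag is NA.
#'
#' @param records data.frame with columns `binding_energy` and `halogen`
#'   (values among `none, F, Cl, Br, I`; `none` rows are ignored for the
#'   trend).
#' @return list with `means` (named numeric, F/Cl/Br/I order), `trend`
#'   (TRUE/FALSE/NA) and `missing` (character).
#' @export
halogen_trend <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("binding_energy", "halogen") %in% names(records)))
    stop("records must have columns binding_energy and halogen")
  series <- c("F", "Cl", "Br", "I")
  means <- vapply(series, function(h) {
    v <- records$binding_energy[records$halogen == h]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  missing <- series[is.na(means)]
  trend <- if (length(missing)) NA else all(diff(means) < 0)
  list(means = means, trend = trend, missing = missing)
}

#' Read a docking-score table
#'
#' Tab-separated with header; required columns `compound_id`,
#' `binding_energy`; optional `halogen`, `n_substitutions`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_docking_tsv <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("compound_id", "binding_energy")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("docking TSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  x
}

#' Annotate docking records with inhibition constants
#'
#' Adds `ki_molar` and a formatted `ki` column; the temperature used is
#' recorded as an attribute and column.
#'
#' @param records docking data.frame with `binding_energy`.
#' @param temperature Kelvin.
#' @return data.frame with `ki_molar`, `ki`, `temperature_K` columns.
#' @export
annotate_ki <- function(records, temperature = 298.15) {
  records$ki_molar <- ki_from_binding_energy(records$binding_energy, temperature)
  records$ki <- format_ki(records$ki_molar)
  records$temperature_K <- temperature
  records
}
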