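#' Conversion constant: electron-volts per hartree
#'
#' Orbital energies must be supplied in eV; divide-and-multiply with this
#' constant to pre-convert hartree output from quantum-chemistry codes.
#'
#' @export
EV_PER_HARTREE <- 27.211386

#' Global reactivity descriptors from frontier-orbital energies
#'
#' Computes the conceptual-DFT global reactivity descriptors from HOMO/LUMO
#' eigenvalues under the Koopmans approximation: ionization energy
#' \eqn{IE = -\epsilon_{HOMO}}, electron affinity \eqn{EA = -\epsilon_{LUMO}},
#' chemical potential \eqn{\mu = (\epsilon_{HOMO}+\epsilon_{LUMO})/2},
#' electronegativity \eqn{\chi = -\mu}, global hardness
#' \eqn{\eta = (\epsilon_{LUMO}-\epsilon_{HOMO})/2}, global softness
#' \eqn{S = 1/(IE-EA)}, electrophilicity index \eqn{\omega = \mu^2/(2\eta)},
#' and the HOMO-LUMO gap \eqn{E_g = 2\eta}.
#'
#' All energies are in eV (softness in 1/eV). Full precision is retained; use
#' [write_descriptors_tsv()] for 2-decimal text output.
#'
#' @param homo_ev HOMO eigenvalue(s), eV.
#' @param lumo_ev LUMO eigenvalue(s), eV; must exceed `homo_ev` element-wise.
#' @param compound_id optional character labels, recycled to length.
#' @return A data.frame with one row per input and columns
#'   `ie, ea, chi, mu, eta, softness, omega, gap` (preceded by `compound_id`
#'   when supplied).
#' @examples
#' descriptors_from_orbitals(-6, -2)
#' @seealso [descriptors_from_ie_ea()], [descriptor_table()]
#' @export
descriptors_from_orbitals <- function(homo_ev, lumo_ev, compound_id = NULL) {
  homo_ev <- as.numeric(homo_ev)
  lumo_ev <- as.numeric(lumo_ev)
  if (length(homo_ev) != length(lumo_ev))
    stop("homo_ev and lumo_ev must have equal length")
  if (length(homo_ev) == 0L)
    stop("no orbital energies supplied")
  if (!all(is.finite(homo_ev)) || !all(is.finite(lumo_ev)))
    stop("orbital energies must be finite")
  bad <- lumo_ev <= homo_ev
  if (any(bad))
    stop("invalid orbital ordering: lumo_ev must be strictly greater than ",
         "homo_ev (gap must be positive; softness is undefined at zero gap)")

  ie  <- -homo_ev
  ea  <- -lumo_ev
  eta <- (lumo_ev - homo_ev) / 2
  mu  <- (lumo_ev + homo_ev) / 2
  out <- data.frame(
    ie = ie, ea = ea, chi = -mu, mu = mu, eta = eta,
    softness = 1 / (ie - ea), omega = mu^2 / (2 * eta),
    gap = lumo_ev - homo_ev
  )
  if (!is.null(compound_id))
    out <- cbind(data.frame(compound_id = as.character(compound_id)), out)
  out
}

#' Global reactivity descriptors from ionization energy and electron affinity
#'
#' Identical to [descriptors_from_orbitals()] applied to
#' `homo_ev = -ie, lumo_ev = -ea`.
#'
#' @param ie ionization energy, eV; must exceed `ea`.
#' @param ea electron affinity, eV.
#' @inheritParams descriptors_from_orbitals
#' @return See [descriptors_from_orbitals()].
#' @export
descriptors_from_ie_ea <- function(ie, ea, compound_id = NULL) {
  descriptors_from_orbitals(-as.numeric(ie), -as.numeric(ea),
                            compound_id = compound_id)
}

#' Descriptor table for a compound series
#'
#' Materializes the per-compound descriptor table: input orbital energies plus
#' all derived descriptors, one row per compound, preserving input order.
#'
#' @param orbitals data.frame with columns `compound_id`, `homo_ev`, `lumo_ev`.
#' @return data.frame with columns `compound_id, homo_ev, lumo_ev, ie, ea,
#'   chi, mu, eta, softness, omega, gap`.
#' @export
descriptor_table <- function(orbitals) {
  need <- c("compound_id", "homo_ev", "lumo_ev")
  if (!is.data.frame(orbitals) || !all(need %in% names(orbitals)))
    stop("orbitals must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(orbitals) == 0L) {
    out <- data.frame(compound_id = character(), homo_ev = numeric(),
                      lumo_ev = numeric(), ie = numeric(), ea = numeric(),
                      chi = numeric(), mu = numeric(), eta = numeric(),
                      softness = numeric(), omega = numeric(), gap = numeric())
    return(out)
  }
  if (anyDuplicated(orbitals$compound_id))
    stop("duplicate compound_id: ",
         paste(unique(orbitals$compound_id[duplicated(orbitals$compound_id)]),
               collapse = ", "))
  d <- descriptors_from_orbitals(orbitals$homo_ev, orbitals$lumo_ev)
  cbind(data.frame(compound_id = as.character(orbitals$compound_id),
                   homo_ev = as.numeric(orbitals$homo_ev),
                   lumo_ev = as.numeric(orbitals$lumo_ev)),
        d)
}

#' Read an orbital-energy table
#'
#' Tab-separated, header required (`compound_id`, `homo_ev`, `lumo_ev`),
#' `#` comment lines ignored. Energies in eV.
#'
#' @param path file path.
#' @return data.frame of orbital energies.
#' @export
read_orbitals_tsv <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("compound_id", "homo_ev", "lumo_ev")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("orbital TSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  x[need]
}

#' Write a descriptor table as TSV
#'
#' Numeric columns are rounded for display (default 2 decimals, matching the
#' precision descriptors are conventionally reported at); the in-memory table
#' keeps full precision.
#'
#' @param x descriptor table from [descriptor_table()].
#' @param path output file path.
#' @param digits decimals for numeric columns.
#' @return `path`, invisibly.
#' @export
write_descriptors_tsv <- function(x, path, digits = 2) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
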