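#' Gibbs free energy from a dissociation constant
#'
#' \code{dg_from_kd} applies the standard-state relation
#' \eqn{\Delta G = RT \ln(K_D / c^\circ)} with \eqn{c^\circ = 1} M, the
#' relation used to tabulate binding free energies from ITC-fitted
#' dissociation constants. \code{kd_from_dg} is its exact inverse.
#'
#' @param K_D dissociation constant(s) in molar.
#' @param dG free energy in kJ/mol.
#' @param temperature absolute temperature in K (default 298.15).
#' @return \code{dg_from_kd}: \eqn{\Delta G} in kJ/mol (negative for
#'   sub-molar \eqn{K_D}); \code{kd_from_dg}: \eqn{K_D} in molar.
#' @examples
#' dg_from_kd(1.75e-6)          # approx -32.9 kJ/mol
#' kd_from_dg(dg_from_kd(2e-5)) # 2e-5
#' @export
dg_from_kd <- function(K_D, temperature = 298.15) {
  if (any(!is.finite(K_D)) || any(K_D <= 0)) stop("K_D must be finite and > 0")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be > 0")
  .GAS_CONSTANT * temperature * log(K_D) / 1000
}

#' @rdname dg_from_kd
#' @export
kd_from_dg <- function(dG, temperature = 298.15) {
  if (any(!is.finite(dG))) stop("dG must be finite")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be > 0")
  exp(dG * 1000 / (.GAS_CONSTANT * temperature))
}

#' Entropic term from the Gibbs relation
#'
#' Returns \eqn{-T\Delta S = \Delta G - \Delta H}, the entropy column of a
#' thermodynamic table stored with the sign convention that negative values
#' are favourable.
#'
#' @param dG,dH free energy and enthalpy in kJ/mol.
#' @return \eqn{-T\Delta S} in kJ/mol.
#' @examples
#' entropy_term(-32.9, -14.6)  # -18.3
#' @export
entropy_term <- function(dG, dH) {
  if (any(!is.finite(dG)) || any(!is.finite(dH))) stop("inputs must be finite")
  dG - dH
}

#' Interaction energy of a complex
#'
#' Difference between the electronic energy of the complex and the energies
#' of host and guest frozen at their in-complex geometries. Pure
#' bookkeeping over supplied energies; no electronic structure is computed
#' here.
#'
#' @param E_complex,E_host,E_guest energies in a common unit.
#' @return interaction energy, same unit.
#' @export
interaction_energy <- function(E_complex, E_host, E_guest) {
  if (any(!is.finite(c(E_complex, E_host, E_guest)))) stop("inputs must be finite")
  E_complex - (E_host + E_guest)
}

#' Deformation energy of a binding partner
#'
#' Energy of a monomer at its in-complex geometry minus its energy at the
#' relaxed unbound geometry. Since the unbound geometry is a minimum, the
#' result should be non-negative; a negative value triggers a warning
#' (it usually means the two energies were swapped or computed at
#' different levels).
#'
#' @param E_in_complex energy at the geometry adopted inside the complex.
#' @param E_unbound energy at the optimized unbound geometry.
#' @return deformation energy, same unit as the inputs.
#' @export
deformation_energy <- function(E_in_complex, E_unbound) {
  if (any(!is.finite(c(E_in_complex, E_unbound)))) stop("inputs must be finite")
  out <- E_in_complex - E_unbound
  if (any(out < 0))
    warning("negative deformation energy: unbound geometry should be a minimum")
  out
}

#' Total SAPT0 interaction energy
#'
#' Sums the seven components of a SAPT0 decomposition: electrostatics,
#' exchange, response induction and its exchange counterpart, dispersion
#' and its exchange counterpart, and the delta-HF correction.
#'
#' @param components named list or named numeric vector with entries
#'   \code{elst}, \code{exch}, \code{ind_resp}, \code{exch_ind_resp},
#'   \code{disp}, \code{exch_disp}, \code{delta_HF} (kJ/mol).
#' @return total SAPT0 energy in kJ/mol.
#' @export
sapt0_total <- function(components) {
  need <- c("elst", "exch", "ind_resp", "exch_ind_resp",
            "disp", "exch_disp", "delta_HF")
  components <- as.list(components)
  missing <- setdiff(need, names(components))
  if (length(missing))
    stop("missing SAPT0 component(s): ", paste(missing, collapse = ", "))
  vals <- unlist(components[need])
  if (any(!is.finite(vals))) stop("SAPT0 components must be finite")
  sum(vals)
}

#' Assemble a calculated binding free energy from six energy terms
#'
#' The additive estimate of the binding free energy used for CB[7]
#' complexes sums six contributions: the host-guest interaction energy,
#' the two-body (SAPT) dispersion energy, the solvation free energy, the
#' entropic term \eqn{-T\Delta S} (from restraint-based MD), and the host
#' and guest deformation energies. All terms in kJ/mol.
#'
#' Vectorised over conformer rows; the sum is exact and linear in every
#' argument.
#'
#' @param e_int interaction energy.
#' @param e_disp two-body dispersion energy.
#' @param g_solv solvation free energy.
#' @param minus_tds entropic term, stored as \eqn{-T\Delta S} (negative =
#'   favourable).
#' @param e_def_host,e_def_guest deformation energies.
#' @return calculated binding free energy in kJ/mol.
#' @examples
#' hostas_assemble(-274.2, -173.9, 262.5, -52.4, 145.6, 19.0)  # -73.4
#' @export
hostas_assemble <- function(e_int, e_disp, g_solv, minus_tds,
                            e_def_host, e_def_guest) {
  args <- list(e_int = e_int, e_disp = e_disp, g_solv = g_solv,
               minus_tds = minus_tds, e_def_host = e_def_host,
               e_def_guest = e_def_guest)
  for (nm in names(args)) {
    if (length(args[[nm]]) == 0 || any(!is.finite(args[[nm]])))
      stop("term '", nm, "' must be present and finite")
  }
  e_int + e_disp + g_solv + minus_tds + e_def_host + e_def_guest
}

#' Combine conformer free energies into one binding free energy
#'
#' When a guest binds in \eqn{N} distinguishable conformations the
#' effective binding constants add, so the combined free energy is
#' \deqn{\Delta G_{tot} = -RT \ln \sum_{i=1}^{N} e^{-\Delta G_i / RT}.}
#' The result is never above the most favourable conformer; it equals the
#' minimum in the \eqn{T \to 0} limit and \eqn{g - RT\ln N} when all
#' entries equal \eqn{g}. Evaluated with a log-sum-exp shift so widely
#' separated conformers do not underflow.
#'
#' @param dG numeric vector of per-conformer free energies, kJ/mol.
#' @param temperature absolute temperature in K.
#' @return combined free energy in kJ/mol.
#' @examples
#' boltzmann_combine(c(-73.4, -68.3))  # approx -73.70
#' @export
boltzmann_combine <- function(dG, temperature = 298.15) {
  if (length(dG) < 1) stop("need at least one conformer")
  if (any(!is.finite(dG))) stop("dG values must be finite")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be > 0")
  RT <- .GAS_CONSTANT * temperature / 1000
  m <- min(dG)
  m - RT * log(sum(exp(-(dG - m) / RT)))
}

#' Assemble and combine a per-conformer energy-term table
#'
#' Takes a table with one row per (complex, conformer) carrying the six
#' energy-term columns, fills terms reported once per complex (typically
#' the solvation free energy) down to all conformers of that complex,
#' assembles the per-conformer free energy, and Boltzmann-combines it per
#' complex.
#'
#' @param terms data frame with columns \code{complex_id},
#'   \code{conformer}, \code{e_int}, \code{e_disp}, \code{g_solv},
#'   \code{minus_tds}, \code{e_def_host}, \code{e_def_guest} (kJ/mol);
#'   \code{NA} in a term means "inherit the complex-level value".
#' @param temperature absolute temperature in K.
#' @return list with \code{conformers}, the input table plus a
#'   \code{dg_calcd} column and an \code{inherited} flag, and
#'   \code{combined}, one row per complex with the Boltzmann-combined
#'   \code{dg_combined} and conformer count \code{n_conformers}.
#' @export
assemble_energy_table <- function(terms, temperature = 298.15) {
  need <- c("complex_id", "e_int", "e_disp", "g_solv", "minus_tds",
            "e_def_host", "e_def_guest")
  missing <- setdiff(need, names(terms))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  terms <- as.data.frame(terms)
  term_cols <- setdiff(need, "complex_id")
  terms$inherited <- FALSE
  for (id in unique(terms$complex_id)) {
    idx <- which(terms$complex_id == id)
    for (col in term_cols) {
      vals <- terms[[col]][idx]
      if (all(is.na(vals)))
        stop("term '", col, "' missing for complex ", id,
             " with no complex-level fallback")
      if (any(is.na(vals))) {
        fill <- vals[!is.na(vals)][1]
        terms[[col]][idx[is.na(vals)]] <- fill
        terms$inherited[idx[is.na(vals)]] <- TRUE
      }
    }
  }
  terms$dg_calcd <- hostas_assemble(terms$e_int, terms$e_disp, terms$g_solv,
                                    terms$minus_tds, terms$e_def_host,
                                    terms$e_def_guest)
  ids <- unique(terms$complex_id)
  combined <- data.frame(
    complex_id = ids,
    n_conformers = vapply(ids, function(id)
      sum(terms$complex_id == id), integer(1)),
    dg_combined = vapply(ids, function(id)
      boltzmann_combine(terms$dg_calcd[terms$complex_id == id], temperature),
      numeric(1)),
    stringsAsFactors = FALSE)
  rownames(combined) <- NULL
  list(conformers = terms, combined = combined)
}

#' Check thermodynamic self-consistency of an ITC results table
#'
#' Every row of a thermodynamic table should satisfy
#' \eqn{\Delta G = \Delta H + (-T\Delta S)} up to the rounding of the
#' printed values. Rows that violate the relation beyond \code{tol} are
#' flagged; rows with missing enthalpy/entropy (weak binders fitted with
#' fixed stoichiometry) are skipped.
#'
#' @param thermo data frame with columns \code{dG}, \code{dH},
#'   \code{minus_tds} in kJ/mol.
#' @param tol allowed discrepancy in kJ/mol (default 0.15, the worst case
#'   from rounding three one-decimal columns).
#' @return the input with columns \code{gibbs_residual} and
#'   \code{gibbs_flag}.
#' @export
check_thermo_consistency <- function(thermo, tol = 0.15) {
  need <- c("dG", "dH", "minus_tds")
  missing <- setdiff(need, names(thermo))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  thermo <- as.data.frame(thermo)
  res <- thermo$dG - (thermo$dH + thermo$minus_tds)
  thermo$gibbs_residual <- res
  thermo$gibbs_flag <- !is.na(res) & abs(res) > tol
  thermo
}
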