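#' Local kinetic energy density from the virial relation
#'
#' At a bond critical point the local virial theorem ties the Laplacian of
#' the electron density to the kinetic and potential energy densities; in
#' atomic units \eqn{\frac{1}{4}\nabla^2\rho = 2G + V}, so
#' \eqn{G = (\frac{1}{4}\nabla^2\rho - V)/2}. \eqn{G} is positive by
#' construction of the kinetic energy; a negative result (possible only
#' from inconsistent inputs) triggers a warning.
#'
#' @param lap Laplacian of the electron density at the BCP, atomic units.
#' @param V local potential energy density at the BCP, atomic units.
#' @return local kinetic energy density G, atomic units.
#' @examples
#' virial_g(35.62e-3, -5.20e-3)  # approx 7.05e-3
#' @export
virial_g <- function(lap, V) {
  if (any(!is.finite(lap)) || any(!is.finite(V))) stop("inputs must be finite")
  G <- (0.25 * lap - V) / 2
  if (any(G < 0))
    warning("negative kinetic energy density: check input units/signs")
  G
}

#' Local total energy density (Cremer-Kraka)
#'
#' \eqn{H(r_c) = V(r_c) + G(r_c)}: the sign of the total energy density at
#' a bond critical point separates interactions with (H < 0) and without
#' (H > 0) a stabilising potential-energy excess.
#'
#' @param V,G local potential and kinetic energy densities, atomic units.
#' @return local energy density H, same unit.
#' @export
local_h <- function(V, G) {
  if (any(!is.finite(V)) || any(!is.finite(G))) stop("inputs must be finite")
  V + G
}

#' Empirical interaction energy from the potential energy density
#'
#' The Afonin correlation maps the potential energy density at a hydrogen
#' bond critical point to an interaction energy:
#' \eqn{E = -172.5 V_{BCP} + 0.33} with \eqn{V} in atomic units and
#' \eqn{E} in kcal/mol, returned here in kJ/mol (x 4.184). The mapping is
#' affine and strictly decreasing in \eqn{V}; attractive BCPs have
#' \eqn{V < 0}, so a positive \eqn{V} triggers a warning. The correlation
#' was calibrated on hydrogen bonds; applying it to other closed-shell
#' contacts (e.g. organic fluorine contacts) is an extrapolation, which
#' this function permits but does not hide.
#'
#' @param V local potential energy density in atomic units.
#' @return interaction energy in kJ/mol.
#' @examples
#' afonin_energy(-23.90e-3)  # approx 18.63
#' @export
afonin_energy <- function(V) {
  if (any(!is.finite(V))) stop("V must be finite")
  if (any(V > 0)) warning("positive V at a BCP: expected V <= 0 for attractive contacts")
  (-172.5 * V + 0.33) * .KCAL_TO_KJ
}

#' Hayashi classification of a bond critical point
#'
#' Classifies an interaction from the signs of the Laplacian and the local
#' energy density: positive Laplacian with positive \eqn{H} is a pure
#' closed-shell (pCS) interaction, positive Laplacian with non-positive
#' \eqn{H} a regular closed-shell (rCS) interaction with partial covalent
#' character, and a non-positive Laplacian a shared-shell (SS) covalent
#' bond.
#'
#' @param lap Laplacian of the density at the BCP (any common unit).
#' @param H local energy density at the BCP (same unit family).
#' @return character vector in \code{c("pCS", "rCS", "SS")}.
#' @examples
#' hayashi_class(35.62e-3, 1.86e-3)   # "pCS"
#' hayashi_class(92.25e-3, -0.40e-3)  # "rCS"
#' @export
hayashi_class <- function(lap, H) {
  if (any(!is.finite(lap)) || any(!is.finite(H))) stop("inputs must be finite")
  ifelse(lap <= 0, "SS", ifelse(H > 0, "pCS", "rCS"))
}

#' Jeffrey geometric classification of a hydrogen bond
#'
#' Distance-based strength bands on the H...acceptor contact: strong below
#' 1.5 A, moderate in [1.5, 2.2) A, weak in [2.2, 3.2] A. Contacts longer
#' than 3.2 A are still labelled weak but flagged (attribute
#' \code{"beyond_range"}), since they fall outside the usual hydrogen-bond
#' window. Boundary values join the class whose lower edge they sit on.
#'
#' @param d_HA H...A contact distance in Angstrom.
#' @param angle X-H...A angle in degrees (validated, not used in the
#'   banding).
#' @return character vector in \code{c("Strong", "Moderate", "Weak")} with
#'   attribute \code{beyond_range} marking contacts past 3.2 A.
#' @export
jeffrey_geometric <- function(d_HA, angle) {
  if (any(!is.finite(d_HA)) || any(d_HA <= 0)) stop("d must be finite and > 0")
  if (any(!is.finite(angle)) || any(angle < 0) || any(angle > 180))
    stop("angle must lie in [0, 180] degrees")
  out <- ifelse(d_HA < 1.5, "Strong", ifelse(d_HA < 2.2, "Moderate", "Weak"))
  attr(out, "beyond_range") <- d_HA > 3.2
  out
}

#' Jeffrey energetic classification of a hydrogen bond
#'
#' Energy-based strength bands: weak below 16.7 kJ/mol, moderate in
#' [16.7, 62.8) kJ/mol, strong at or above 62.8 kJ/mol (the classical 4
#' and 15 kcal/mol boundaries).
#'
#' @param E interaction energy in kJ/mol (positive magnitude).
#' @return character vector in \code{c("Strong", "Moderate", "Weak")}.
#' @export
jeffrey_energetic <- function(E) {
  if (any(!is.finite(E))) stop("E must be finite")
  ifelse(E < 16.7, "Weak", ifelse(E < 62.8, "Moderate", "Strong"))
}

.ELEMENTS <- c("H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA",
               "MG", "AL", "SI", "P", "S", "CL", "AR", "K", "CA", "BR",
               "I", "SE", "FE", "ZN", "CU", "MN")

#' Type an intermolecular contact from its participating atoms
#'
#' Rule-based typing of the interaction inventory: X-H...O/N contacts are
#' hydrogen bonds (ionic hydrogen bonds when the donor is the protonated
#' piperazinium nitrogen), any contact involving fluorine is a fluorine
#' contact, H...H contacts are dihydrogen bonds, and O...C contacts
#' without a mediating hydrogen are n->pi* interactions (oxygen lone pair
#' into a carbonyl or aromatic pi* system).
#'
#' @param donor_element,acceptor_element element symbols.
#' @param h_involved logical; does a hydrogen mediate the contact?
#' @param context character vector of context labels; the label
#'   \code{"piperazinium"} marks a protonated piperazine nitrogen donor.
#' @return one of \code{"ionic_hbond"}, \code{"hbond"},
#'   \code{"dihydrogen"}, \code{"fluorine_contact"}, \code{"n_pi_star"},
#'   \code{"other"}.
#' @export
type_interaction <- function(donor_element, h_involved, acceptor_element,
                             context = character(0)) {
  de <- toupper(donor_element)
  ae <- toupper(acceptor_element)
  if (!de %in% .ELEMENTS) stop("unknown element symbol: ", donor_element)
  if (!ae %in% .ELEMENTS) stop("unknown element symbol: ", acceptor_element)
  if (de == "F" || ae == "F") return("fluorine_contact")
  if (de == "H" && ae == "H") return("dihydrogen")
  if (isTRUE(h_involved) && ae %in% c("O", "N")) {
    if (de == "N" && "piperazinium" %in% context) return("ionic_hbond")
    return("hbond")
  }
  if (!isTRUE(h_involved) && de == "O" && ae == "C") return("n_pi_star")
  if (!isTRUE(h_involved) && de == "C" && ae == "O") return("n_pi_star")
  "other"
}

#' Annotate a bond-critical-point table
#'
#' Pipeline composition over a BCP table in the layout of a QTAIM
#' interaction inventory: derives the kinetic energy density \eqn{G} from
#' the virial relation, the total energy density \eqn{H}, the Afonin
#' interaction energy \eqn{E}, and the geometric (GC), energetic (EC) and
#' Hayashi (HC) classifications, plus the interaction type when element
#' columns are present. Idempotent: derived columns are recomputed from
#' \code{rho}, \code{lap}, \code{V} on every call.
#'
#' If a \code{G} column is supplied it is checked against the virial
#' identity and rows violating it beyond \code{tol_virial} are flagged in
#' \code{virial_flag}.
#'
#' @param records data frame with columns \code{rho}, \code{lap}, \code{V}
#'   in au x 10^3 (the usual printed scale; set \code{units = "au"} for
#'   plain atomic units); optional \code{d} (Angstrom), \code{angle_XHX}
#'   (degrees), \code{G}, and element columns \code{donor_element},
#'   \code{h_involved}, \code{acceptor_element}, \code{context}.
#' @param tol_virial tolerance for the virial check, in au.
#' @param units unit of the density columns, \code{"au1e3"} or
#'   \code{"au"}.
#' @return the input with derived columns \code{G}, \code{H} (same unit as
#'   input), \code{E} (kJ/mol), \code{GC}, \code{EC}, \code{HC},
#'   \code{itype}, \code{virial_flag}.
#' @export
annotate_bcp <- function(records, tol_virial = 5e-5,
                         units = c("au1e3", "au")) {
  units <- match.arg(units)
  records <- as.data.frame(records)
  need <- c("rho", "lap", "V")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  if (any(records$rho < 0)) stop("rho must be non-negative")
  scale <- if (units == "au1e3") 1e-3 else 1

  lap_au <- records$lap * scale
  V_au <- records$V * scale
  G_au <- virial_g(lap_au, V_au)
  if ("G" %in% names(records)) {
    viol <- abs(0.25 * lap_au - (2 * records$G * scale + V_au)) > tol_virial
    records$virial_flag <- viol
  } else records$virial_flag <- FALSE
  records$G <- G_au / scale
  records$H <- local_h(V_au, G_au) / scale
  records$E <- afonin_energy(V_au)
  records$HC <- hayashi_class(lap_au, local_h(V_au, G_au))
  records$EC <- jeffrey_energetic(records$E)
  if (all(c("d", "angle_XHX") %in% names(records))) {
    gc <- jeffrey_geometric(records$d, records$angle_XHX)
    records$GC <- as.character(gc)
    records$GC_flag_long <- attr(gc, "beyond_range")
  }
  if (all(c("donor_element", "h_involved", "acceptor_element") %in%
          names(records))) {
    ctx <- if ("context" %in% names(records)) records$context else
      rep("", nrow(records))
    records$itype <- vapply(seq_len(nrow(records)), function(i)
      type_interaction(records$donor_element[i], records$h_involved[i],
                       records$acceptor_element[i],
                       strsplit(ctx[i], ";")[[1]]), character(1))
  }
  records
}

#' Summarise an annotated BCP table into an interaction inventory
#'
#' Counts interactions per complex/conformer and type, the human-readable
#' digest of a QTAIM analysis.
#'
#' @param annotated output of \code{\link{annotate_bcp}} with an
#'   \code{itype} column.
#' @return data frame of counts per \code{complex_id}, \code{conformer},
#'   \code{itype}.
#' @export
interaction_inventory <- function(annotated) {
  if (!"itype" %in% names(annotated))
    stop("annotated table has no itype column; supply element columns")
  keys <- c(intersect(c("complex_id", "conformer"), names(annotated)), "itype")
  agg <- stats::aggregate(list(count = rep(1L, nrow(annotated))),
                          by = annotated[keys], FUN = sum)
  agg[do.call(order, agg[keys]), , drop = FALSE]
}
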