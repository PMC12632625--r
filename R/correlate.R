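#' Closed-form ordinary least-squares line
#'
#' Deterministic simple linear regression of \code{y} on \code{x} via the
#' normal equations, reporting slope, intercept and
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param x,y equal-length numeric vectors, \code{x} not constant.
#' @return object of class \code{ols_fit}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n_points},
#'   \code{residuals}, \code{fitted}.
#' @examples
#' ols_fit(1:5, 2 * (1:5) + 1)
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant: slope undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_points = length(x), residuals = res, fitted = fitted),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4f x %+.4f, R^2 = %.2f\n",
              x$n_points, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Join computed and experimental binding free energies
#'
#' Matches per-complex Boltzmann-combined computed free energies with the
#' corresponding experimental values. The experimental source is
#' selectable: \code{"paired"} uses the experimental column carried
#' alongside the computed table (the decomposition table's own pairing),
#' \code{"itc"} looks the complexes up in an ITC thermodynamics table.
#' Unmatched complexes are reported via the \code{"unmatched"} attribute;
#' duplicate complex ids within a source are an error.
#'
#' @param combined data frame with \code{complex_id}, \code{dg_combined}
#'   and (for the paired policy) \code{dg_exp}.
#' @param thermo optional ITC table with \code{complex_id} and \code{dG}
#'   (needed for \code{source_policy = "itc"}).
#' @param source_policy \code{"paired"} or \code{"itc"}.
#' @return data frame sorted by \code{complex_id} with columns
#'   \code{complex_id}, \code{dg_combined}, \code{dg_exp}; attribute
#'   \code{unmatched} lists ids missing from either side.
#' @export
assemble_comparison <- function(combined, thermo = NULL,
                                source_policy = c("paired", "itc")) {
  source_policy <- match.arg(source_policy)
  combined <- as.data.frame(combined)
  if (anyDuplicated(combined$complex_id))
    stop("duplicate complex_id in computed table")
  if (source_policy == "paired") {
    if (!"dg_exp" %in% names(combined))
      stop("paired policy needs a dg_exp column in the computed table")
    out <- combined[, c("complex_id", "dg_combined", "dg_exp")]
    unmatched <- out$complex_id[is.na(out$dg_exp)]
    out <- out[!is.na(out$dg_exp), , drop = FALSE]
  } else {
    if (is.null(thermo)) stop("itc policy needs a thermo table")
    thermo <- as.data.frame(thermo)
    if (anyDuplicated(thermo$complex_id))
      stop("duplicate complex_id in experimental table")
    idx <- match(combined$complex_id, thermo$complex_id)
    out <- data.frame(complex_id = combined$complex_id,
                      dg_combined = combined$dg_combined,
                      dg_exp = thermo$dG[idx],
                      stringsAsFactors = FALSE)
    unmatched <- c(combined$complex_id[is.na(idx)],
                   setdiff(thermo$complex_id, combined$complex_id))
    out <- out[!is.na(out$dg_exp), , drop = FALSE]
  }
  out <- out[order(out$complex_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Human-readable pipeline report
#'
#' Assembles a plain-text summary of whatever pipeline artifacts are
#' supplied: the experimental thermodynamics with Gibbs-relation
#' consistency flags, the assembled/combined energy table, the
#' computed-vs-experimental regression, the annotated QTAIM inventory,
#' pose descriptors, and any discrepancy between experimental free-energy
#' sources.
#'
#' @param thermo optional ITC thermodynamics table (columns as in
#'   \code{\link{cb7_thermo}}, with \code{dG}, \code{dH},
#'   \code{minus_tds}).
#' @param energy optional output of \code{\link{assemble_energy_table}}.
#' @param regression optional \code{\link{ols_fit}}.
#' @param bcp optional output of \code{\link{annotate_bcp}}.
#' @param poses optional output of \code{\link{pose_descriptors}}.
#' @param exp_sources optional data frame with \code{complex_id} and two
#'   experimental \code{dG} columns to cross-check (e.g. the pairing in
#'   the decomposition table vs the ITC table).
#' @param file optional path; the report is written there as well.
#' @return character vector of report lines, invisibly.
#' @export
hg_report <- function(thermo = NULL, energy = NULL, regression = NULL,
                      bcp = NULL, poses = NULL, exp_sources = NULL,
                      file = NULL) {
  if (is.null(thermo) && is.null(energy) && is.null(regression) &&
      is.null(bcp) && is.null(poses) && is.null(exp_sources))
    stop("nothing to report: supply at least one artifact")
  fmt_df <- function(df) utils::capture.output(print(df, row.names = FALSE))
  lines <- c("Host-guest binding analysis report",
             strrep("=", 34), "")
  if (!is.null(thermo)) {
    chk <- check_thermo_consistency(thermo)
    lines <- c(lines, "## Experimental thermodynamics", fmt_df(chk), "")
    nflag <- sum(chk$gibbs_flag, na.rm = TRUE)
    lines <- c(lines, sprintf(
      "Gibbs-relation check (|dG - dH - (-TdS)| > 0.15 kJ/mol): %d row(s) flagged%s",
      nflag,
      if (nflag) paste0(": ", paste(which(chk$gibbs_flag), collapse = ", "))
      else ""), "")
  }
  if (!is.null(energy)) {
    lines <- c(lines, "## Energy decomposition (per conformer)",
               fmt_df(energy$conformers), "",
               "## Boltzmann-combined free energies (per complex)",
               fmt_df(energy$combined), "")
  }
  if (!is.null(regression)) {
    lines <- c(lines, "## Computed vs experimental regression",
               sprintf("y = %.4f x %+.4f, R^2 = %.2f (n = %d)",
                       regression$slope, regression$intercept,
                       regression$r_squared, regression$n_points), "")
  }
  if (!is.null(bcp)) {
    lines <- c(lines, "## QTAIM interaction inventory", fmt_df(bcp), "")
    if ("itype" %in% names(bcp))
      lines <- c(lines, "## Interaction counts",
                 fmt_df(interaction_inventory(bcp)), "")
    if (any(bcp$virial_flag))
      lines <- c(lines, sprintf(
        "WARNING: %d row(s) violate the local virial identity",
        sum(bcp$virial_flag)), "")
  }
  if (!is.null(poses)) {
    lines <- c(lines, "## Binding-pose descriptors", fmt_df(poses), "")
  }
  if (!is.null(exp_sources)) {
    cols <- setdiff(names(exp_sources), "complex_id")
    if (length(cols) >= 2) {
      diff <- exp_sources[[cols[1]]] - exp_sources[[cols[2]]]
      flagged <- which(!is.na(diff) & abs(diff) > 0.15)
      lines <- c(lines, "## Experimental-source cross-check")
      if (length(flagged)) {
        lines <- c(lines, sprintf(
          "DISCREPANCY %s: %s = %.1f vs %s = %.1f kJ/mol",
          exp_sources$complex_id[flagged],
          cols[1], exp_sources[[cols[1]]][flagged],
          cols[2], exp_sources[[cols[2]]][flagged]))
      } else lines <- c(lines, "sources agree within 0.15 kJ/mol")
      lines <- c(lines, "")
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
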