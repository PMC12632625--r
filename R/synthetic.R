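# Synthetic-data generators. Each generator stands in for an instrument
# or quantum-chemistry code: it produces the table the pipeline consumes
# plus the ground truth that produced it, so every downstream stage can be
# tested by round trip. One integer seed per artifact; each generator
# draws from its own substream (fixed offset) so adding one generator
# never changes another's output.

#' Generate a synthetic one-site ITC titration
#'
#' Simulates integrated per-injection heats from the same forward model
#' the fitter uses (\code{\link{predict_injection_heats}}), plus additive
#' i.i.d. Gaussian noise. The default noise scale is 1\% of the magnitude
#' of the first-injection heat, a typical integrated-heat reproducibility
#' for a modern power-compensation calorimeter.
#'
#' @param truth list with \code{n} (sites), \code{K_D} (molar) and
#'   \code{dH} (kJ/mol).
#' @param protocol a \code{\link{titration_protocol}}.
#' @param noise_sd Gaussian noise standard deviation in J; \code{NULL}
#'   for the 1\%-of-first-heat default; 0 for noiseless data.
#' @param seed integer seed.
#' @return list with \code{heats} (J), \code{truth}, \code{protocol},
#'   \code{noise_sd}.
#' @examples
#' prot <- titration_protocol(200, 1e-3, 1e-2, rep(2, 20))
#' sim <- gen_titration(list(n = 1, K_D = 2e-5, dH = -15), prot, 0, seed = 1)
#' @export
gen_titration <- function(truth, protocol, noise_sd = NULL, seed = 1) {
  stopifnot(inherits(protocol, "titration_protocol"))
  if (is.null(truth$n) || is.null(truth$K_D) || is.null(truth$dH))
    stop("truth must supply n, K_D and dH")
  if (!is.finite(truth$K_D) || truth$K_D <= 0) stop("K_D must be > 0")
  clean <- predict_injection_heats(
    list(n = truth$n, K_a = 1 / truth$K_D, dH = truth$dH), protocol)
  if (is.null(noise_sd)) noise_sd <- 0.01 * abs(clean[1])
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  heats <- .with_seed(seed, clean + stats::rnorm(length(clean), 0, noise_sd),
                      offset = 1L)
  list(heats = heats, truth = truth, protocol = protocol,
       noise_sd = noise_sd)
}

#' Generate a synthetic conformer energy-term table
#'
#' Emulates the per-conformer energy decomposition table of a host-guest
#' free-energy study: each row carries the six additive terms, and the
#' embedded ground truth records the per-conformer assembled free energy
#' (their exact sum) and the per-complex Boltzmann-combined value, so the
#' assembly/combination pipeline can be checked by round trip.
#'
#' @param n_complexes number of complexes.
#' @param n_conformers conformers per complex (scalar or per-complex
#'   vector).
#' @param term_ranges named list of \code{c(min, max)} ranges (kJ/mol)
#'   for \code{e_int}, \code{e_disp}, \code{g_solv}, \code{minus_tds},
#'   \code{e_def_host}, \code{e_def_guest}; defaults span the magnitudes
#'   typical of CB[7] complexes.
#' @param seed integer seed.
#' @param temperature temperature in K for the ground-truth combination.
#' @return list with \code{table} (the term table; \code{g_solv} given on
#'   the first conformer of each complex only, to exercise inheritance)
#'   and \code{truth} (\code{dg_calcd} per row, \code{combined} per
#'   complex).
#' @export
gen_energy_table <- function(n_complexes = 5, n_conformers = 2,
                             term_ranges = NULL, seed = 1,
                             temperature = 298.15) {
  if (n_complexes < 1) stop("n_complexes must be >= 1")
  if (any(n_conformers < 1)) stop("n_conformers must be >= 1")
  if (length(n_conformers) == 1)
    n_conformers <- rep(n_conformers, n_complexes)
  defaults <- list(e_int = c(-290, -220), e_disp = c(-185, -150),
                   g_solv = c(260, 285), minus_tds = c(-80, 45),
                   e_def_host = c(120, 160), e_def_guest = c(10, 25))
  if (is.null(term_ranges)) term_ranges <- defaults
  for (nm in names(defaults))
    if (is.null(term_ranges[[nm]])) term_ranges[[nm]] <- defaults[[nm]]
  for (nm in names(term_ranges))
    if (length(term_ranges[[nm]]) != 2)
      stop("term range '", nm, "' must be c(min, max)")

  .with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_complexes)) {
      id <- sprintf("complex_%02d", i)
      g_solv_complex <- stats::runif(1, term_ranges$g_solv[1],
                                     term_ranges$g_solv[2])
      for (j in seq_len(n_conformers[i])) {
        draw <- function(nm) stats::runif(1, term_ranges[[nm]][1],
                                          term_ranges[[nm]][2])
        rows[[length(rows) + 1]] <- data.frame(
          complex_id = id, conformer = j,
          e_int = draw("e_int"), e_disp = draw("e_disp"),
          g_solv = g_solv_complex,
          minus_tds = draw("minus_tds"),
          e_def_host = draw("e_def_host"),
          e_def_guest = draw("e_def_guest"),
          stringsAsFactors = FALSE)
      }
    }
    full <- do.call(rbind, rows)
    dg <- hostas_assemble(full$e_int, full$e_disp, full$g_solv,
                          full$minus_tds, full$e_def_host, full$e_def_guest)
    ids <- unique(full$complex_id)
    combined <- data.frame(
      complex_id = ids,
      dg_combined = vapply(ids, function(id)
        boltzmann_combine(dg[full$complex_id == id], temperature),
        numeric(1)),
      stringsAsFactors = FALSE)
    rownames(combined) <- NULL
    # published-style table: complex-level solvation printed once
    tab <- full
    tab$g_solv[duplicated(tab$complex_id)] <- NA
    list(table = tab,
         truth = list(dg_calcd = dg, combined = combined,
                      temperature = temperature))
  }, offset = 2L)
}

#' Generate a synthetic bond-critical-point table
#'
#' Constructs BCP rows that satisfy the local virial identity
#' \eqn{\frac{1}{4}\nabla^2\rho = 2G + V} exactly by drawing
#' \eqn{(\nabla^2\rho, H)} inside the target class region and solving for
#' \eqn{V = 2H - \frac{1}{4}\nabla^2\rho} and \eqn{G = \frac{1}{4}
#' \nabla^2\rho - H}. Every planted label (Hayashi class, Jeffrey
#' geometric band, interaction type) is recoverable by the classifier.
#'
#' @param n_rows number of rows.
#' @param class_mix named proportions over \code{pCS}, \code{rCS},
#'   \code{SS} summing to 1.
#' @param seed integer seed.
#' @return list with \code{table} (columns \code{rho}, \code{lap},
#'   \code{V}, \code{G}, \code{d}, \code{angle_XHX}, element columns; all
#'   densities in au x 10^3) and \code{truth} (planted \code{HC},
#'   \code{GC}, \code{EC}, \code{itype} labels).
#' @export
gen_bcp_table <- function(n_rows = 100,
                          class_mix = c(pCS = 0.6, rCS = 0.3, SS = 0.1),
                          seed = 1) {
  if (n_rows < 1) stop("n_rows must be >= 1")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% c("pCS", "rCS", "SS")))
    stop("class_mix must be named with pCS/rCS/SS")
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix proportions must sum to 1")

  .with_seed(seed, {
    hc <- sample(names(class_mix), n_rows, replace = TRUE, prob = class_mix)
    lap <- H <- numeric(n_rows)          # au x 10^3
    for (i in seq_len(n_rows)) {
      if (hc[i] == "pCS") {
        lap[i] <- stats::runif(1, 20, 100)
        H[i] <- stats::runif(1, 0.05, 0.25 * lap[i] * 0.5)   # 0 < H < lap/8
      } else if (hc[i] == "rCS") {
        lap[i] <- stats::runif(1, 20, 100)
        H[i] <- stats::runif(1, -3, -0.05)
      } else {
        lap[i] <- stats::runif(1, -100, -20)
        H[i] <- stats::runif(1, 0.25 * lap[i] - 5, 0.25 * lap[i] - 0.5)
      }
    }
    V <- 2 * H - 0.25 * lap              # virial identity, exact
    G <- 0.25 * lap - H
    rho <- stats::runif(n_rows, 4, 30)

    # plant Jeffrey geometric bands away from the boundaries
    gc <- sample(c("Strong", "Moderate", "Weak"), n_rows, replace = TRUE,
                 prob = c(0.1, 0.4, 0.5))
    d <- ifelse(gc == "Strong", stats::runif(n_rows, 1.0, 1.45),
         ifelse(gc == "Moderate", stats::runif(n_rows, 1.55, 2.15),
                stats::runif(n_rows, 2.25, 3.15)))
    angle <- stats::runif(n_rows, 90, 180)

    types <- data.frame(
      itype = c("ionic_hbond", "hbond", "dihydrogen", "fluorine_contact",
                "n_pi_star"),
      donor_element = c("N", "O", "H", "C", "O"),
      h_involved = c(TRUE, TRUE, FALSE, TRUE, FALSE),
      acceptor_element = c("O", "N", "H", "F", "C"),
      context = c("piperazinium", "", "", "", ""),
      stringsAsFactors = FALSE)
    pick <- sample(nrow(types), n_rows, replace = TRUE)

    tab <- data.frame(
      complex_id = sprintf("synthetic_%02d", (seq_len(n_rows) - 1) %% 4 + 1),
      conformer = (seq_len(n_rows) - 1) %% 2 + 1,
      rho = rho, lap = lap, V = V, G = G,
      d = d, angle_XHX = angle,
      donor_element = types$donor_element[pick],
      h_involved = types$h_involved[pick],
      acceptor_element = types$acceptor_element[pick],
      context = types$context[pick],
      stringsAsFactors = FALSE)
    truth <- data.frame(HC = hc, GC = gc,
                        EC = jeffrey_energetic(afonin_energy(V * 1e-3)),
                        itype = types$itype[pick],
                        stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  }, offset = 3L)
}

#' Generate a toy host-guest complex with known pose descriptors
#'
#' Builds a 7-fold-symmetric pseudo-host mimicking the CB[7] geometry -
#' two portal-oxygen rings (upper labelled \code{O1..O7}, lower
#' \code{O1B..O7B}) flanking an equatorial carbon ring
#' (\code{C1..C14}) - and places, per requested disorder group, a guest
#' consisting of the charged piperazinium nitrogen \code{N29} and a
#' phenyl ring \code{C1P..C6P}, positioned so the pose descriptors take
#' exactly the requested ground-truth values. By default the whole
#' assembly then receives a seeded random rigid-body transform, under
#' which the descriptors are invariant.
#'
#' @param portal_radius portal-oxygen ring radius, Angstrom.
#' @param equatorial_radius equatorial carbon ring radius, Angstrom.
#' @param guests list of guest specs, one per disorder group, each a list
#'   with \code{n29_height} (distance of N29 above the portal plane, A),
#'   \code{axial_angle} (angle Cen1-Cen2-N29, degrees),
#'   \code{phenyl_tilt} (phenyl vs equatorial plane, degrees, [0, 90]),
#'   \code{occupancy}, and optionally \code{halogen_dist} (distance of a
#'   para-halogen from the far portal centroid, A).
#' @param portal_height distance of each portal plane from the equator, A.
#' @param seed integer seed (drives the rigid transform only).
#' @param rigid_transform apply a random rotation + translation.
#' @return list with \code{structure} (a
#'   \code{\link{structure_model}}), \code{selections} (ready for
#'   \code{\link{pose_descriptors}}) and \code{truth} (the planted
#'   descriptor table).
#' @export
gen_toy_complex <- function(portal_radius = 3.0, equatorial_radius = 4.0,
                            guests = list(list(n29_height = 0.5,
                                               axial_angle = 10,
                                               phenyl_tilt = 78.66,
                                               occupancy = 1)),
                            portal_height = 3.05, seed = 1,
                            rigid_transform = TRUE) {
  if (portal_radius <= 0 || equatorial_radius <= 0 || portal_height <= 0)
    stop("radii and portal height must be > 0")
  occ <- vapply(guests, function(g) g$occupancy %||% 1, numeric(1))
  if (any(occ <= 0) || any(occ > 1)) stop("occupancies must lie in (0, 1]")
  if (sum(occ) > 1 + 1e-9)
    stop("disorder-group occupancies must sum to <= 1")

  ring <- function(k, r, z) {
    th <- 2 * pi * (seq_len(k) - 1) / k
    cbind(r * cos(th), r * sin(th), rep(z, k))
  }
  up <- ring(7, portal_radius, portal_height)
  lo <- ring(7, portal_radius, -portal_height)
  eq <- ring(14, equatorial_radius, 0)
  host <- data.frame(
    label = c(sprintf("O%d", 1:7), sprintf("O%dB", 1:7),
              sprintf("C%d", 1:14)),
    element = c(rep("O", 14), rep("C", 14)),
    x = c(up[, 1], lo[, 1], eq[, 1]),
    y = c(up[, 2], lo[, 2], eq[, 2]),
    z = c(up[, 3], lo[, 3], eq[, 3]),
    occupancy = 1, disorder_group = 0L,
    stringsAsFactors = FALSE)

  guest_rows <- list()
  truth_rows <- list()
  for (g in seq_along(guests)) {
    sp <- guests[[g]]
    for (nm in c("n29_height", "axial_angle", "phenyl_tilt"))
      if (is.null(sp[[nm]])) stop("guest spec missing ", nm)
    if (sp$phenyl_tilt < 0 || sp$phenyl_tilt > 90)
      stop("phenyl_tilt must lie in [0, 90]")
    z_n <- portal_height + sp$n29_height
    r_xy <- z_n * tan(sp$axial_angle * pi / 180)
    n29 <- c(r_xy, 0, z_n)

    tilt <- sp$phenyl_tilt * pi / 180
    e1 <- c(cos(tilt), 0, -sin(tilt))     # phenyl in-plane basis
    e2 <- c(0, 1, 0)                      # normal = (sin tilt, 0, cos tilt)
    ctr <- c(0, 0, -0.5)
    th <- 2 * pi * (0:5) / 6
    phen <- t(vapply(th, function(t)
      ctr + 1.39 * (cos(t) * e1 + sin(t) * e2), numeric(3)))

    rows <- data.frame(
      label = c("N29", sprintf("C%dP", 1:6)),
      element = c("N", rep("C", 6)),
      x = c(n29[1], phen[, 1]), y = c(n29[2], phen[, 2]),
      z = c(n29[3], phen[, 3]),
      occupancy = occ[g], disorder_group = g,
      stringsAsFactors = FALSE)
    tr <- data.frame(group = g, occupancy = occ[g],
                     d_N29_plane1 = sp$n29_height,
                     angle_cen1_cen2_N29 = sp$axial_angle,
                     angle_phenyl_plane2 = sp$phenyl_tilt)
    if (!is.null(sp$halogen_dist)) {
      # para halogen on the far-portal axis, halogen_dist from Cen1'
      rows <- rbind(rows, data.frame(
        label = "X1", element = "CL",
        x = 0, y = 0, z = -portal_height + sp$halogen_dist,
        occupancy = occ[g], disorder_group = g, stringsAsFactors = FALSE))
      tr$d_cen1prime_halogen <- sp$halogen_dist
    }
    guest_rows[[g]] <- rows
    truth_rows[[g]] <- tr
  }
  atoms <- rbind(host, do.call(rbind, guest_rows))
  struct <- structure_model(atoms)
  if (rigid_transform) {
    struct <- .with_seed(seed, transform_structure(
      struct, .random_rotation(), stats::runif(3, -20, 20)), offset = 4L)
  }
  # column padding when only some groups carry a halogen
  has_hal <- vapply(truth_rows, function(x)
    "d_cen1prime_halogen" %in% names(x), logical(1))
  if (any(has_hal)) {
    truth_rows <- lapply(truth_rows, function(x) {
      if (!"d_cen1prime_halogen" %in% names(x))
        x$d_cen1prime_halogen <- NA_real_
      x
    })
  }
  truth <- do.call(rbind, truth_rows)
  selections <- list(portal_O = sprintf("O%d", 1:7),
                     portal_O_prime = sprintf("O%dB", 1:7),
                     equatorial_C = sprintf("C%d", 1:14),
                     n29 = "N29", phenyl = sprintf("C%dP", 1:6))
  if (any(atoms$label == "X1")) selections$halogen <- "X1"
  list(structure = struct, selections = selections, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
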