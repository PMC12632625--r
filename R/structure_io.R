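#' Build a structure model from an atom table
#'
#' Internal container for occupancy-aware atom sites: Cartesian
#' coordinates in Angstrom with a label, element symbol, occupancy and
#' optional disorder group per atom. Host atoms normally carry
#' \code{disorder_group = 0}; alternative guest conformers carry distinct
#' positive groups whose occupancies sum to at most 1.
#'
#' @param atoms data frame with columns \code{label}, \code{element},
#'   \code{x}, \code{y}, \code{z}, and optionally \code{occupancy}
#'   (default 1) and \code{disorder_group} (default 0).
#' @param cell optional named list/vector \code{a, b, c, alpha, beta,
#'   gamma} (Angstrom, degrees) retained for round-tripping fractional
#'   input.
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, cell = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("label", "element", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing))
    stop("missing atom column(s): ", paste(missing, collapse = ", "))
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"disorder_group" %in% names(atoms)) atoms$disorder_group <- 0L
  if (any(!is.finite(atoms$occupancy)) ||
      any(atoms$occupancy <= 0) || any(atoms$occupancy > 1))
    stop("occupancies must lie in (0, 1]")
  for (g in unique(atoms$disorder_group)) {
    lab <- atoms$label[atoms$disorder_group == g]
    if (anyDuplicated(lab))
      stop("duplicate atom label within disorder group ", g, ": ",
           lab[duplicated(lab)][1])
  }
  structure(list(atoms = atoms, cell = cell), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d disorder group(s)%s\n",
              nrow(x$atoms), length(unique(x$atoms$disorder_group)),
              if (is.null(x$cell)) "" else ", with cell"))
  invisible(x)
}

# Standard crystallographic fractional -> Cartesian matrix (a along x,
# b in the xy plane).
.frac_to_cart_matrix <- function(cell) {
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  al <- cell[["alpha"]] * pi / 180
  be <- cell[["beta"]] * pi / 180
  ga <- cell[["gamma"]] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

#' Read a crystal/toy structure file
#'
#' Two plain-text dialects are supported. \code{cif_min} is a minimal CIF
#' subset: the six cell parameters plus one \code{loop_} with
#' \code{_atom_site_label}, \code{_atom_site_type_symbol}, fractional
#' coordinates, and optional occupancy and disorder group; fractional
#' coordinates are converted to Cartesian Angstrom exactly once on read.
#' \code{labeled_xyz} is an XYZ file whose atom lines carry
#' \code{label element x y z [occupancy [disorder_group]]} with Cartesian
#' coordinates passed through unchanged.
#'
#' @param path file path.
#' @param dialect \code{"auto"} (by extension), \code{"cif_min"} or
#'   \code{"labeled_xyz"}.
#' @return a \code{\link{structure_model}}.
#' @export
read_structure <- function(path, dialect = c("auto", "cif_min", "labeled_xyz")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif_min"
               else "labeled_xyz"
  if (dialect == "cif_min") .read_cif_min(path) else .read_labeled_xyz(path)
}

.read_cif_min <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    val <- sub(paste0("^\\s*", tag, "\\s+"), "", hit[1])
    as.numeric(sub("\\(.*\\)", "", val))   # strip esd parentheses
  }
  cell <- list(a = grab("_cell_length_a"), b = grab("_cell_length_b"),
               c = grab("_cell_length_c"), alpha = grab("_cell_angle_alpha"),
               beta = grab("_cell_angle_beta"), gamma = grab("_cell_angle_gamma"))

  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  atom_loop <- NULL
  for (ls in loop_starts) {
    i <- ls + 1
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (any(grepl("^_atom_site_fract_x$", tags))) {
      atom_loop <- list(tags = tags, first_row = i)
      break
    }
  }
  if (is.null(atom_loop)) stop("no _atom_site loop found in ", path)
  if (any(is.na(unlist(cell))))
    stop("fractional coordinates require a complete unit cell in ", path)

  tags <- atom_loop$tags
  rows <- list()
  i <- atom_loop$first_row
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(_|loop_|data_|#)", ln)) break
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) != length(tags))
      stop("malformed atom_site row at line ", i, " of ", path,
           ": expected ", length(tags), " fields, got ", length(fields))
    rows[[length(rows) + 1]] <- fields
    i <- i + 1
  }
  if (!length(rows)) stop("empty atom_site loop in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  getcol <- function(tag, default = NULL) {
    if (tag %in% tags) m[, tag] else default
  }
  num <- function(x) as.numeric(sub("\\(.*\\)", "", x))
  frac <- cbind(num(getcol("_atom_site_fract_x")),
                num(getcol("_atom_site_fract_y")),
                num(getcol("_atom_site_fract_z")))
  cart <- frac %*% t(.frac_to_cart_matrix(cell))
  occ <- getcol("_atom_site_occupancy")
  grp <- getcol("_atom_site_disorder_group")
  atoms <- data.frame(
    label = getcol("_atom_site_label"),
    element = getcol("_atom_site_type_symbol",
                     default = getcol("_atom_site_label")),
    x = cart[, 1], y = cart[, 2], z = cart[, 3],
    occupancy = if (is.null(occ)) 1 else num(occ),
    disorder_group = if (is.null(grp)) 0L
                     else as.integer(ifelse(grp %in% c(".", "?"), 0, grp)),
    stringsAsFactors = FALSE)
  structure_model(atoms, cell = cell)
}

.read_labeled_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("labeled_xyz file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("labeled_xyz first line must be the atom count")
  body <- lines[3:(2 + n)]
  rows <- lapply(seq_along(body), function(k) {
    fields <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(fields) < 5)
      stop("malformed atom line ", k + 2, " in ", path)
    fields
  })
  atoms <- data.frame(
    label = vapply(rows, `[`, "", 1),
    element = vapply(rows, `[`, "", 2),
    x = as.numeric(vapply(rows, `[`, "", 3)),
    y = as.numeric(vapply(rows, `[`, "", 4)),
    z = as.numeric(vapply(rows, `[`, "", 5)),
    occupancy = vapply(rows, function(r)
      if (length(r) >= 6) as.numeric(r[6]) else 1, numeric(1)),
    disorder_group = vapply(rows, function(r)
      if (length(r) >= 7) as.integer(r[7]) else 0L, integer(1)),
    stringsAsFactors = FALSE)
  structure_model(atoms)
}

#' Write a structure model
#'
#' Writes either dialect accepted by \code{\link{read_structure}}. For
#' \code{cif_min}, Cartesian coordinates are expressed as fractions of the
#' stored cell, or of a padded orthorhombic box when the model has no
#' cell.
#'
#' @param x a \code{\link{structure_model}}.
#' @param path output path.
#' @param dialect \code{"labeled_xyz"} or \code{"cif_min"}.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(x, path, dialect = c("labeled_xyz", "cif_min")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "structure_model"))
  a <- x$atoms
  if (dialect == "labeled_xyz") {
    lines <- c(as.character(nrow(a)), "labeled_xyz written by hgbind",
               sprintf("%s %s %.8f %.8f %.8f %.4f %d",
                       a$label, a$element, a$x, a$y, a$z,
                       a$occupancy, a$disorder_group))
    writeLines(lines, path)
  } else {
    cell <- x$cell
    if (is.null(cell)) {
      pad <- 10
      cell <- list(a = diff(range(a$x)) + pad, b = diff(range(a$y)) + pad,
                   c = diff(range(a$z)) + pad,
                   alpha = 90, beta = 90, gamma = 90)
      a$x <- a$x - min(a$x) + pad / 2
      a$y <- a$y - min(a$y) + pad / 2
      a$z <- a$z - min(a$z) + pad / 2
    }
    frac <- cbind(a$x, a$y, a$z) %*% t(solve(.frac_to_cart_matrix(cell)))
    lines <- c("data_hgbind",
               sprintf("_cell_length_a %.6f", cell$a),
               sprintf("_cell_length_b %.6f", cell$b),
               sprintf("_cell_length_c %.6f", cell$c),
               sprintf("_cell_angle_alpha %.6f", cell$alpha),
               sprintf("_cell_angle_beta %.6f", cell$beta),
               sprintf("_cell_angle_gamma %.6f", cell$gamma),
               "loop_",
               "_atom_site_label",
               "_atom_site_type_symbol",
               "_atom_site_fract_x",
               "_atom_site_fract_y",
               "_atom_site_fract_z",
               "_atom_site_occupancy",
               "_atom_site_disorder_group",
               sprintf("%s %s %.8f %.8f %.8f %.4f %d",
                       a$label, a$element, frac[, 1], frac[, 2], frac[, 3],
                       a$occupancy, a$disorder_group))
    writeLines(lines, path)
  }
  invisible(path)
}
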