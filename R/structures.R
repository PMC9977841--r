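# Domain types: molecular structures, atom-mapped reactions, bond-change
# classification, linear interpolation, and multi-frame XYZ I/O.

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"
)

#' Atomic masses (amu) for supported elements
#'
#' @param z Integer vector of atomic numbers.
#' @return Numeric vector of standard atomic masses in amu.
#' @export
atomic_mass <- function(z) {
  masses <- c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
              18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06,
              35.45, 39.948)
  if (any(z < 1L | z > length(masses)))
    stop("atomic number outside supported range 1..", length(masses))
  masses[z]
}

symbol_to_z <- function(sym) {
  z <- match(sym, ELEMENT_SYMBOLS)
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(unique(sym[is.na(z)]), collapse = ", "))
  z
}

#' Construct a molecular structure
#'
#' A structure is one conformation: atomic numbers plus Cartesian coordinates
#' in Angstrom, optionally tagged with its role in a reaction.
#'
#' @param atomic_numbers Integer vector of element numbers Z (all >= 1).
#' @param coordinates Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param label Optional role tag: one of "reactant", "product",
#'   "interpolated", "ts", or NULL.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atomic_numbers, coordinates, label = NULL) {
  atomic_numbers <- as.integer(atomic_numbers)
  coordinates <- as.matrix(coordinates)
  if (length(atomic_numbers) < 1L) stop("structure needs at least one atom")
  if (any(atomic_numbers < 1L)) stop("atomic numbers must be >= 1")
  if (!is.numeric(coordinates) || ncol(coordinates) != 3L ||
      nrow(coordinates) != length(atomic_numbers))
    stop("coordinates must be a numeric N x 3 matrix matching atomic_numbers")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (!is.null(label))
    label <- match.arg(label, c("reactant", "product", "interpolated", "ts"))
  dimnames(coordinates) <- NULL
  out <- list(atomic_numbers = atomic_numbers, coordinates = coordinates,
              label = label)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d: %d atoms (%s)%s>\n", n_atoms(x),
              paste(ELEMENT_SYMBOLS[x$atomic_numbers], collapse = ""),
              if (is.null(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s A `structure3d`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) length(s$atomic_numbers)

#' Pairwise interatomic distance matrix
#'
#' @param s A `structure3d` or an N x 3 coordinate matrix.
#' @return Symmetric hollow N x N matrix of distances in Angstrom.
#' @export
distance_matrix <- function(s) {
  x <- if (inherits(s, "structure3d")) s$coordinates else as.matrix(s)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- NULL
  d
}

# strict-upper-triangle pair index (i > j, column-major over j < i),
# matching the canonical ordering used throughout the package
strict_pairs <- function(n) {
  if (n < 2L) return(list(i = integer(0), j = integer(0)))
  j <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  # reorder to (j fixed, i ascending) by construction above: j blocks ascending
  list(i = i, j = j)
}

#' Strict-pair distances of a structure
#'
#' Distances for all unordered atom pairs i > j in the package's canonical
#' pair order (j ascending, then i).
#'
#' @param s A `structure3d`.
#' @param unit "angstrom" or "pm".
#' @return Numeric vector of length N(N-1)/2.
#' @export
pair_distances <- function(s, unit = c("angstrom", "pm")) {
  unit <- match.arg(unit)
  dm <- distance_matrix(s)
  idx <- strict_pairs(n_atoms(s))
  d <- dm[cbind(idx$i, idx$j)]
  if (unit == "pm") d <- d * 100
  d
}

#' Assemble a full distance matrix from strict-pair values
#'
#' @param d Numeric vector of strict-pair distances (canonical order).
#' @param n Number of atoms.
#' @return Symmetric hollow n x n matrix.
#' @export
pair_vector_to_matrix <- function(d, n) {
  idx <- strict_pairs(n)
  if (length(d) != length(idx$i)) stop("pair vector length != n(n-1)/2")
  m <- matrix(0, n, n)
  m[cbind(idx$i, idx$j)] <- d
  m[cbind(idx$j, idx$i)] <- d
  m
}

#' Construct an atom-mapped reaction
#'
#' Atom mapping is positional: atom i of the reactant is atom i of the
#' product (and of the reference TS if present). All frames must share
#' element order.
#'
#' @param reactant,product `structure3d` objects with identical atoms.
#' @param ts_ref Optional reference TS `structure3d`.
#' @param properties Optional named list keyed by role ("reactant",
#'   "product", "ts") of named numeric vectors with any of `E` (kcal/mol),
#'   `S_vib`, `S_rot`.
#' @param id Reaction identifier string.
#' @return An object of class `reaction`.
#' @export
reaction <- function(reactant, product, ts_ref = NULL, properties = NULL,
                     id = "rxn") {
  stopifnot(inherits(reactant, "structure3d"), inherits(product, "structure3d"))
  if (!identical(reactant$atomic_numbers, product$atomic_numbers))
    stop("reactant and product must share atom count and element order")
  if (!is.null(ts_ref)) {
    stopifnot(inherits(ts_ref, "structure3d"))
    if (!identical(reactant$atomic_numbers, ts_ref$atomic_numbers))
      stop("ts_ref must share atom count and element order with reactant")
    ts_ref$label <- "ts"
  }
  reactant$label <- "reactant"
  product$label <- "product"
  out <- list(reactant = reactant, product = product, ts_ref = ts_ref,
              properties = properties, id = as.character(id))
  class(out) <- "reaction"
  out
}

#' @export
print.reaction <- function(x, ...) {
  cat(sprintf("<reaction %s: %d atoms (%s), ts_ref %s%s>\n", x$id,
              n_atoms(x$reactant),
              paste(ELEMENT_SYMBOLS[x$reactant$atomic_numbers], collapse = ""),
              if (is.null(x$ts_ref)) "absent" else "present",
              if (is.null(x$properties)) "" else ", labelled"))
  invisible(x)
}

#' Reverse a reaction
#'
#' Swaps reactant and product; the reference TS (if any) is unchanged.
#'
#' @param r A `reaction`.
#' @return The reversed `reaction`.
#' @export
reverse_reaction <- function(r) {
  stopifnot(inherits(r, "reaction"))
  props <- r$properties
  if (!is.null(props)) {
    nm <- names(props)
    nm[nm == "reactant"] <- ".tmp"
    nm[nm == "product"] <- "reactant"
    nm[nm == ".tmp"] <- "product"
    names(props) <- nm
  }
  reaction(r$product, r$reactant, ts_ref = r$ts_ref, properties = props,
           id = r$id)
}

#' Linearly interpolated structure between reactant and product
#'
#' Coordinates are the convex combination (1-f) X_R + f X_P, optionally after
#' rigid (Kabsch) alignment of the product onto the reactant. Pre-aligned
#' databases should use `align = FALSE` (the default) so that endpoints are
#' reproduced exactly.
#'
#' @param r A `reaction`.
#' @param fraction Interpolation fraction in [0, 1]; 0.5 gives the midpoint.
#' @param align If TRUE, Kabsch-align the product onto the reactant first.
#' @return A `structure3d` labelled "interpolated".
#' @export
interpolate_structure <- function(r, fraction = 0.5, align = FALSE) {
  stopifnot(inherits(r, "reaction"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a single number in [0, 1]")
  xp <- r$product$coordinates
  if (align) xp <- align_structures(r$product, r$reactant)$structure$coordinates
  xr <- r$reactant$coordinates
  structure3d(r$reactant$atomic_numbers,
              (1 - fraction) * xr + fraction * xp, label = "interpolated")
}

#' Classify atom pairs by bond change
#'
#' Each unordered pair i > j is categorized by whether its distance is below
#' the bond threshold (default 156.6 pm) in the reactant and in the product:
#' bonded in neither (`none_none`), only in the product (`formation`), only
#' in the reactant (`breakage`), or in both (`bond_bond`).
#'
#' @param r A `reaction`.
#' @param theta_bond Bond-distance threshold in pm.
#' @return Data frame with columns i, j, d_r_pm, d_p_pm and factor `category`.
#' @export
classify_pairs <- function(r, theta_bond = 156.6) {
  stopifnot(inherits(r, "reaction"))
  d_r <- pair_distances(r$reactant, unit = "pm")
  d_p <- pair_distances(r$product, unit = "pm")
  idx <- strict_pairs(n_atoms(r$reactant))
  br <- d_r < theta_bond
  bp <- d_p < theta_bond
  cat_ <- ifelse(br & bp, "bond_bond",
          ifelse(!br & bp, "formation",
          ifelse(br & !bp, "breakage", "none_none")))
  data.frame(i = idx$i, j = idx$j, d_r_pm = d_r, d_p_pm = d_p,
             category = factor(cat_, levels = c("none_none", "formation",
                                                "breakage", "bond_bond")))
}

# ---- XYZ I/O ----------------------------------------------------------------

parse_xyz_frames <- function(lines, path = "<xyz>") {
  frames <- list()
  pos <- 1L
  nl <- length(lines)
  while (pos <= nl) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("%s: line %d: expected atom count, got '%s'",
                   path, pos, lines[pos]))
    if (pos + 1L + nat > nl)
      stop(sprintf("%s: line %d: truncated frame (%d atoms declared)",
                   path, pos, nat))
    comment <- lines[pos + 1L]
    syms <- character(nat)
    xyz <- matrix(NA_real_, nat, 3L)
    for (k in seq_len(nat)) {
      ln <- pos + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop(sprintf("%s: line %d: malformed atom record", path, ln))
      syms[k] <- tok[1]
      co <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(co))
        stop(sprintf("%s: line %d: non-numeric coordinate", path, ln))
      xyz[k, ] <- co
    }
    frames[[length(frames) + 1L]] <-
      list(symbols = syms, coordinates = xyz, comment = comment)
    pos <- pos + 2L + nat
  }
  frames
}

parse_properties_comment <- function(comment) {
  # comment lines may carry "E=... S_vib=... S_rot=..." key=value fields
  m <- regmatches(comment, gregexpr("(E|S_vib|S_rot)=([-0-9.eE+]+)", comment))[[1]]
  if (length(m) == 0L) return(NULL)
  kv <- strsplit(m, "=")
  out <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Read an atom-mapped reaction from a multi-frame XYZ file
#'
#' The file must contain 2 frames (reactant, product) or 3 frames (reactant,
#' TS, product) as declared by `frames`. Comment lines may carry
#' `E=... S_vib=... S_rot=...` property fields.
#'
#' @param path Path to the XYZ file.
#' @param frames Frame layout declaration: "RP" or "RTP".
#' @param id Reaction identifier.
#' @return A `reaction`.
#' @export
read_reaction_xyz <- function(path, frames = c("RP", "RTP"), id = NULL) {
  frames <- match.arg(frames)
  if (is.null(id)) id <- sub("\\.xyz$", "", basename(path))
  fr <- parse_xyz_frames(readLines(path, warn = FALSE), path = path)
  want <- if (frames == "RP") 2L else 3L
  if (length(fr) != want)
    stop(sprintf("%s: declared %s (%d frames) but file has %d",
                 path, frames, want, length(fr)))
  syms <- fr[[1]]$symbols
  for (k in seq_along(fr))
    if (!identical(fr[[k]]$symbols, syms))
      stop(sprintf("%s: element sequence of frame %d differs from frame 1",
                   path, k))
  z <- symbol_to_z(syms)
  mk <- function(f, lab) structure3d(z, f$coordinates, label = lab)
  roles <- if (frames == "RP") c("reactant", "product")
           else c("reactant", "ts", "product")
  props <- list()
  for (k in seq_along(fr)) {
    p <- parse_properties_comment(fr[[k]]$comment)
    if (!is.null(p)) props[[roles[k]]] <- p
  }
  if (length(props) == 0L) props <- NULL
  if (frames == "RP")
    reaction(mk(fr[[1]], "reactant"), mk(fr[[2]], "product"),
             properties = props, id = id)
  else
    reaction(mk(fr[[1]], "reactant"), mk(fr[[3]], "product"),
             ts_ref = mk(fr[[2]], "ts"), properties = props, id = id)
}

format_xyz_frame <- function(s, comment = "") {
  c(sprintf("%d", n_atoms(s)), comment,
    sprintf("%-2s %18.10f %18.10f %18.10f", ELEMENT_SYMBOLS[s$atomic_numbers],
            s$coordinates[, 1], s$coordinates[, 2], s$coordinates[, 3]))
}

#' Write a structure to an XYZ file
#'
#' @param s A `structure3d`.
#' @param path Output path.
#' @param comment Comment line content.
#' @param append Append a frame instead of overwriting.
#' @return Invisibly, the path.
#' @export
write_structure_xyz <- function(s, path, comment = "", append = FALSE) {
  stopifnot(inherits(s, "structure3d"))
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(format_xyz_frame(s, comment), con)
  invisible(path)
}

property_comment <- function(props, role) {
  p <- props[[role]]
  if (is.null(p)) return("")
  paste(sprintf("%s=%.10g", names(p), p), collapse = " ")
}

#' Write a reaction as a multi-frame XYZ file
#'
#' Frames are written reactant, [TS,] product; property labels go on the
#' comment lines as key=value fields.
#'
#' @param r A `reaction`.
#' @param path Output path.
#' @return Invisibly, the frame layout string ("RP" or "RTP").
#' @export
write_reaction_xyz <- function(r, path) {
  stopifnot(inherits(r, "reaction"))
  frames <- if (is.null(r$ts_ref)) "RP" else "RTP"
  lines <- format_xyz_frame(r$reactant, property_comment(r$properties, "reactant"))
  if (!is.null(r$ts_ref))
    lines <- c(lines, format_xyz_frame(r$ts_ref, property_comment(r$properties, "ts")))
  lines <- c(lines, format_xyz_frame(r$product, property_comment(r$properties, "product")))
  writeLines(lines, path)
  invisible(frames)
}

#' Read a reaction dataset from a JSON-lines manifest
#'
#' Each manifest line is a JSON record `{id, path, frames}` with `path`
#' relative to the manifest's directory (or absolute).
#'
#' @param manifest Path to the manifest (.jsonl) file.
#' @return List of `reaction` objects.
#' @export
read_reactions <- function(manifest) {
  lines <- readLines(manifest, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  base <- dirname(manifest)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    p <- rec$path
    if (!file.exists(p)) p <- file.path(base, rec$path)
    read_reaction_xyz(p, frames = rec$frames, id = rec$id)
  })
}

#' Write a reaction dataset (XYZ files plus JSON-lines manifest)
#'
#' @param reactions List of `reaction` objects.
#' @param dir Output directory (created if needed).
#' @param manifest Manifest file name within `dir`.
#' @return Invisibly, the manifest path.
#' @export
write_reactions <- function(reactions, dir, manifest = "manifest.jsonl") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- character(length(reactions))
  for (k in seq_along(reactions)) {
    r <- reactions[[k]]
    fn <- paste0(r$id, ".xyz")
    frames <- write_reaction_xyz(r, file.path(dir, fn))
    recs[k] <- jsonlite::toJSON(list(id = r$id, path = fn, frames = frames),
                                auto_unbox = TRUE)
  }
  mp <- file.path(dir, manifest)
  writeLines(recs, mp)
  invisible(mp)
}
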