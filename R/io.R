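#' Write ribbon coordinates as (multi-frame) XYZ
#'
#' Uses a label-carrying XYZ dialect: the comment line records
#' `frame=<i> units=nm`, and the atom-name field encodes the lattice tags
#' as `<U|L><column>_<segment>_<residue>`, so that a read/write round trip
#' preserves both positions and labels.
#'
#' @param coords A `ribbon_coords` tibble, or a list of them (one per frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(coords, path) {
  frames <- if (inherits(coords, "data.frame")) list(coords) else coords
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("frame=%d units=nm", i), con)
    name <- sprintf("%s%02d_%03d_%d",
                    ifelse(fr$leaflet == "upper", "U", "L"),
                    fr$column, fr$segment, fr$residue)
    writeLines(sprintf("%s %.6f %.6f %.6f", name, fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

parse_xyz_frame <- function(lines, start) {
  n <- suppressWarnings(as.integer(trimws(lines[start])))
  if (is.na(n) || n < 1L) {
    rlang::abort(sprintf("XYZ parse error at line %d: expected an atom count.",
                         start), class = "ribbonhelix_parse_error")
  }
  if (start + 1L + n > length(lines)) {
    rlang::abort(sprintf(
      "XYZ parse error: file truncated, frame starting at line %d needs %d atom lines.",
      start, n), class = "ribbonhelix_parse_error")
  }
  body <- lines[(start + 2L):(start + 1L + n)]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    rlang::abort(sprintf("XYZ parse error at line %d: expected 'name x y z'.",
                         start + 1L + bad[1]), class = "ribbonhelix_parse_error")
  }
  name <- vapply(parts, `[[`, character(1), 1L)
  m <- regmatches(name, regexec("^([UL])([0-9]+)_([0-9]+)_([0-9]+)$", name))
  bad <- which(lengths(m) != 5L)
  if (length(bad)) {
    rlang::abort(sprintf(
      "XYZ labelling error at line %d: atom name '%s' does not encode <U|L><column>_<segment>_<residue>.",
      start + 1L + bad[1], name[bad[1]]), class = "ribbonhelix_label_error")
  }
  num <- function(k) as.numeric(vapply(parts, `[[`, character(1), k))
  fr <- tibble::tibble(
    leaflet = ifelse(vapply(m, `[[`, character(1), 2L) == "U", "upper", "lower"),
    column = as.integer(vapply(m, `[[`, character(1), 3L)),
    segment = as.integer(vapply(m, `[[`, character(1), 4L)),
    residue = as.integer(vapply(m, `[[`, character(1), 5L)),
    x = num(2L), y = num(3L), z = num(4L)
  )
  n_w <- max(fr$column)
  n_l <- max(fr$segment)
  fr$monomer_id <- monomer_ids(fr$leaflet, fr$column, fr$segment, n_w, n_l)
  fr <- dplyr::select(fr, "monomer_id", "leaflet", "column", "segment",
                      "residue", "x", "y", "z")
  list(frame = structure(fr, class = c("ribbon_coords", class(fr))),
       next_start = start + 2L + n)
}

#' Read (multi-frame) XYZ ribbon coordinates
#'
#' @param path Path to an XYZ file written by [write_xyz()] (or following
#'   the same label dialect).
#' @return A single `ribbon_coords` tibble if the file holds one frame,
#'   otherwise a list of frames.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) {
    rlang::abort("XYZ parse error: empty file.", class = "ribbonhelix_parse_error")
  }
  frames <- list()
  at <- 1L
  while (at <= length(lines)) {
    parsed <- parse_xyz_frame(lines, at)
    frames[[length(frames) + 1L]] <- parsed$frame
    at <- parsed$next_start
  }
  if (length(frames) == 1L) frames[[1]] else frames
}

#' Write / read ribbon coordinates as PDB
#'
#' Thin wrappers over the bio3d PDB reader/writer. Coordinates are stored
#' in Angstrom (the PDB convention; nm x 10) and the lattice labels are
#' encoded as: chain ID = leaflet (`U`/`L`), residue number = monomer id,
#' B-factor = column index, occupancy = segment index, atom name =
#' `R<residue>`.
#'
#' @param coords A `ribbon_coords` tibble.
#' @param path File path.
#' @return `path` (write) or a `ribbon_coords` tibble (read).
#' @export
write_pdb_ribbon <- function(coords, path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    rlang::abort("PDB support needs the 'bio3d' package.")
  }
  n <- nrow(coords)
  xyz <- as.numeric(t(as.matrix(coords[, c("x", "y", "z")]))) * 10
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", n),
    resno = coords$monomer_id,
    resid = rep("RIB", n),
    chain = ifelse(coords$leaflet == "upper", "U", "L"),
    eleno = seq_len(n),
    elety = paste0("R", coords$residue),
    o = coords$segment,
    b = coords$column
  )
  invisible(path)
}

#' @rdname write_pdb_ribbon
#' @export
read_pdb_ribbon <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    rlang::abort("PDB support needs the 'bio3d' package.")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  residue <- as.integer(sub("^R", "", at$elety))
  if (any(is.na(residue)) || !all(at$chain %in% c("U", "L"))) {
    rlang::abort("PDB labelling error: file does not carry ribbon lattice tags.",
                 class = "ribbonhelix_label_error")
  }
  fr <- tibble::tibble(
    monomer_id = as.integer(at$resno),
    leaflet = ifelse(at$chain == "U", "upper", "lower"),
    column = as.integer(round(at$b)),
    segment = as.integer(round(at$o)),
    residue = residue,
    x = at$x / 10, y = at$y / 10, z = at$z / 10
  )
  structure(fr, class = c("ribbon_coords", class(fr)))
}

#' Export a twist profile (or any result tibble) to CSV
#'
#' @param x A tibble (e.g. a [twist_profile()] series or its summary).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
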