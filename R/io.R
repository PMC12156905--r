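## Readers and writers: GRO (fixed-column, nm), XYZ (free-format, box from
## config), whitespace-columnar time series with '#'/'@' comment lines, and
## the flat key-value run configuration.

#' Read a GRO coordinate file
#'
#' Parses the fixed-column GROMACS GRO layout (positions in nm) with a
#' trailing box line.  Molecule ids are taken as residue number minus one;
#' atom roles are left unassigned (`other`) and are assigned afterwards with
#' [apply_role_map()].
#'
#' @param path Path to a `.gro` file.
#' @return List with elements `topology` (an [hb_topology()] skeleton,
#'   `strict = FALSE`) and `frame` (an [hb_frame()]).
#' @seealso [write_gro()], [apply_role_map()]
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO file too short: ", path, call. = FALSE)
  title <- lines[1]
  n_atoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n_atoms) || n_atoms < 1) {
    stop("GRO line 2: invalid atom count", call. = FALSE)
  }
  if (length(lines) < 2 + n_atoms + 1) {
    stop("GRO file truncated: expected ", n_atoms, " atom lines plus box line",
         call. = FALSE)
  }
  atom_lines <- lines[3:(2 + n_atoms)]
  parse_field <- function(s, from, to) substr(s, from, to)
  resid <- suppressWarnings(as.integer(parse_field(atom_lines, 1, 5)))
  resname <- trimws(parse_field(atom_lines, 6, 10))
  name <- trimws(parse_field(atom_lines, 11, 15))
  x <- suppressWarnings(as.numeric(parse_field(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(parse_field(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(parse_field(atom_lines, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z) | name == "")
  if (length(bad)) {
    stop(sprintf("GRO parse error at line %d: '%s'", bad[1] + 2L,
                 atom_lines[bad[1]]), call. = FALSE)
  }
  box_fields <- suppressWarnings(as.numeric(strsplit(
    trimws(lines[3 + n_atoms]), "\\s+")[[1]]))
  if (!length(box_fields) || anyNA(box_fields)) {
    stop("GRO box line missing or malformed", call. = FALSE)
  }
  if (any(box_fields[seq_len(min(3, length(box_fields)))] <= 0)) {
    stop("GRO box line has non-positive edge length", call. = FALSE)
  }
  box <- hb_box(box_fields)
  time <- 0
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
  element <- ifelse(grepl("^H", name), "H",
             ifelse(grepl("^O", name), "O",
             ifelse(grepl("^C", name), "C", substr(name, 1, 1))))
  atoms <- data.frame(atom_id = seq_along(name) - 1L,
                      molecule_id = resid - 1L,
                      name = name, element = element,
                      role = "other", stringsAsFactors = FALSE)
  list(topology = hb_topology(atoms, species_label = resname[1],
                              n_separation = 0L, strict = FALSE),
       frame = hb_frame(time, cbind(x, y, z), box))
}

#' Write a GRO coordinate file
#'
#' @param frame An [hb_frame()].
#' @param topology An [hb_topology()] (names and molecule grouping).
#' @param path Output path.
#' @param title Title line; the frame time is appended as `t= <ps>`.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, topology, path, title = "hbondnet") {
  atoms <- topology$atoms
  n <- nrow(atoms)
  stopifnot(nrow(frame$coordinates) == n)
  resname <- substr(toupper(topology$species_label), 1, 5)
  if (!nzchar(resname)) resname <- "MOL"
  lines <- c(sprintf("%s t= %.4f", title, frame$time), sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     (atoms$molecule_id %% 100000L) + 1L, resname,
                     substr(atoms$name, 1, 5),
                     (atoms$atom_id %% 100000L) + 1L,
                     frame$coordinates[, 1], frame$coordinates[, 2],
                     frame$coordinates[, 3]),
             sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file (single- or multi-frame)
#'
#' Free-format XYZ with coordinates in nm.  XYZ carries no box, so one must
#' be supplied (typically from the run configuration).  Frame times are read
#' from `t= <ps>` in the comment line when present, otherwise frames are
#' numbered `0, dt, 2 dt, ...`.
#'
#' @param path Path to the file.
#' @param box An [hb_box()] (required; XYZ has no box record).
#' @param dt Frame spacing in ps used when comment lines carry no times.
#' @return An [hb_trajectory()].
#' @export
read_xyz <- function(path, box, dt = 1) {
  if (missing(box) || is.null(box)) {
    stop("XYZ input requires a box from the configuration", call. = FALSE)
  }
  if (!inherits(box, "hb_box")) box <- hb_box(box)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error at line ", i, call. = FALSE)
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(coords)) stop("XYZ coordinate parse error near line ", i,
                            call. = FALSE)
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else k * dt
    frames[[length(frames) + 1L]] <- hb_frame(time, coords, box)
    i <- i + 2L + n
    k <- k + 1L
  }
  hb_trajectory(frames)
}

#' Write an XYZ file
#'
#' @param trajectory An [hb_trajectory()].
#' @param topology An [hb_topology()] supplying element symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- topology$atoms$element
  for (f in trajectory$frames) {
    writeLines(c(sprintf("%d", nrow(f$coordinates)),
                 sprintf("t= %.4f (nm)", f$time),
                 sprintf("%-3s %12.6f %12.6f %12.6f", el,
                         f$coordinates[, 1], f$coordinates[, 2],
                         f$coordinates[, 3])), con)
  }
  invisible(path)
}

#' Read a whitespace-columnar time series
#'
#' Accepts the GROMACS xvg dialect: lines starting with `#` or `@` are
#' comments; remaining lines are whitespace-separated numbers whose first
#' column is time (ps).
#'
#' @param path Path to the file.
#' @param col_names Optional column names for the non-time columns.
#' @return An [hb_series()].
#' @export
read_series <- function(path, col_names = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("series file has no data rows: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  ncols <- length(parts[[1]])
  mat <- t(vapply(parts, function(p) as.numeric(p[seq_len(ncols)]),
                  numeric(ncols)))
  if (anyNA(mat)) stop("series file has malformed rows: ", path, call. = FALSE)
  cols <- as.data.frame(mat[, -1, drop = FALSE])
  names(cols) <- if (!is.null(col_names)) col_names else
    paste0("V", seq_len(ncol(cols)))
  hb_series(mat[, 1], cols)
}

#' Write a time series in xvg-compatible form
#'
#' @param series An [hb_series()].
#' @param path Output path.
#' @param comment Comment placed on a leading `#` line.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, comment = "hbondnet series") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#", comment),
               paste("#", paste(names(series), collapse = " "))), con)
  utils::write.table(series, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Assign hydrogen-bonding roles by atom name
#'
#' @param topology_skeleton An [hb_topology()] as returned by [read_gro()]
#'   (roles still `other`).
#' @param role_map Named character vector mapping atom names to roles, e.g.
#'   `c(OA = "OH_oxygen", HO = "OH_hydrogen", OE = "OE_oxygen",
#'   CT = "terminal_carbon")`.  Unmapped names stay `other`.
#' @param n_separation Carbon count between hydroxyl and ether oxygens.
#' @param species_label Optional species label override.
#' @return A validated [hb_topology()].
#' @export
apply_role_map <- function(topology_skeleton, role_map, n_separation = 0L,
                           species_label = NULL) {
  stopifnot(inherits(topology_skeleton, "hb_topology"))
  bad <- setdiff(unname(role_map), HB_ROLES)
  if (length(bad)) stop("role_map contains unknown roles: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  atoms <- topology_skeleton$atoms
  mapped <- role_map[atoms$name]
  atoms$role <- ifelse(is.na(mapped), "other", unname(mapped))
  hb_topology(atoms,
              species_label = species_label %||% topology_skeleton$species_label,
              n_separation = n_separation, strict = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a flat key-value run configuration
#'
#' Format: `key = value` lines, `#` comments, optional `[section]` headers
#' that prefix keys as `section.key`.  The role map is given as
#' `role_map = OA:OH_oxygen, HO:OH_hydrogen, ...`.
#'
#' @param path Path to the config file.
#' @return Named list of character values; `role_map` parsed to a named
#'   vector; numeric-looking scalars converted to numeric.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("config parse error: '", ln, "'", call. = FALSE)
    key <- trimws(kv[2])
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    val <- trimws(kv[3])
    if (key == "role_map" || grepl("\\.role_map$", key)) {
      pairs <- strsplit(strsplit(val, ",")[[1]], ":")
      rm <- vapply(pairs, function(p) trimws(p[2]), character(1))
      names(rm) <- vapply(pairs, function(p) trimws(p[1]), character(1))
      out[[key]] <- rm
    } else if (grepl("^[-+0-9.eE ]+$", val) &&
               !anyNA(suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]])))) {
      num <- as.numeric(strsplit(val, "\\s+")[[1]])
      out[[key]] <- num
    } else {
      out[[key]] <- val
    }
  }
  out
}
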