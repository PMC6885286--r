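# Structure and trajectory I/O: GRO (nm), PDB (Angstrom, fixed-column, with
# a CRYST1 box record and one MODEL per frame), and multi-frame XYZ
# (Angstrom). Parsers report the offending line on malformed input.

.known_resnames <- function() {
  ox <- enumerate_oxidized_cl()
  c("PLPC", "SLPE", "POPC", "TLCL", "DYE", ox$resname)
}

# Rebuild a topology data.frame from residue names, atom names and residue
# ids as read from a file. Leaflets are reassigned from the z sign relative
# to the phosphate midplane of the first frame.
.topology_from_names <- function(resname, name, resid, z1) {
  ox <- enumerate_oxidized_cl()
  known <- .known_resnames()
  bad <- setdiff(unique(resname), known)
  if (length(bad)) {
    stop("unknown residue name(s) on read: ", paste(bad, collapse = ", "))
  }
  species <- resname
  ppos <- rep(NA_integer_, length(resname))
  for (k in seq_len(nrow(ox))) {
    hit <- resname == ox$resname[k]
    species[hit] <- ox$label[k]
    ppos[hit] <- ox$position[k]
  }
  dm <- .dye_markers()
  group <- character(length(name))
  for (i in seq_along(name)) {
    if (resname[i] == "DYE") {
      j <- match(name[i], dm$name)
      if (is.na(j)) stop("unknown dye atom name on read: ", name[i])
      group[i] <- dm$group[j]
    } else {
      group[i] <- .marker_group(name[i])
    }
  }
  pid <- which(name == "P" & resname != "DYE")
  mid <- if (length(pid)) mean(z1[pid]) else 0
  mol_z <- stats::ave(z1, resid, FUN = function(v) mean(v))
  data.frame(
    name = name, group = group, species = species, resname = resname,
    resid = resid,
    leaflet = ifelse(mol_z >= mid, "upper", "lower"),
    mol = resid,
    mass = unname(.marker_mass[name]),
    dye_off = ifelse(resname == "DYE", dm$off[match(name, dm$name)], 0),
    peroxide_position = ppos,
    stringsAsFactors = FALSE
  )
}

.as_traj <- function(x) {
  if (inherits(x, "synthetic_traj")) return(x)
  if (inherits(x, "bilayer_config")) {
    return(synthetic_traj(x$topology, x$xyz, x$box,
                          depth_model = x$depth_model, seed = x$seed))
  }
  stop("expected a synthetic_traj or bilayer_config")
}

#' Write a configuration or trajectory to GRO, PDB, or XYZ
#'
#' GRO files are written in nm with 3 decimals (multi-frame files are
#' concatenated blocks); PDB files in Angstrom with 3 decimals, one MODEL
#' per frame and a CRYST1 record carrying the box; XYZ files in Angstrom
#' with one block per frame. XYZ carries only atom names: reading it back
#' needs the original topology to restore residue labels.
#'
#' @param x A `synthetic_traj` or `bilayer_config`.
#' @param path Output file path.
#' @param format "gro", "pdb", or "xyz".
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("gro", "pdb", "xyz")) {
  format <- match.arg(format)
  traj <- .as_traj(x)
  top <- traj$topology
  F <- n_frames(traj)
  switch(format,
    gro = {
      con <- file(path, "w"); on.exit(close(con))
      for (f in seq_len(F)) {
        xyz <- traj$coords[, , f] / 10   # Angstrom -> nm
        writeLines(sprintf("synthetic membrane frame %d", f - 1L), con)
        writeLines(sprintf("%5d", nrow(top)), con)
        writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                           top$resid %% 100000, top$resname, top$name,
                           seq_len(nrow(top)) %% 100000,
                           xyz[, 1], xyz[, 2], xyz[, 3]), con)
        writeLines(sprintf("%10.5f%10.5f%10.5f",
                           traj$box[1] / 10, traj$box[2] / 10,
                           traj$box[3] / 10), con)
      }
    },
    pdb = {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        traj$box[1], traj$box[2], traj$box[3], 90, 90, 90), con)
      # PDB convention: names shorter than 4 characters start in column 14
      name4 <- ifelse(nchar(top$name) < 4,
                      sprintf(" %-3s", top$name), top$name)
      for (f in seq_len(F)) {
        writeLines(sprintf("MODEL     %4d", f), con)
        writeLines(sprintf(
          "ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          seq_len(nrow(top)) %% 100000, name4, top$resname,
          top$resid %% 10000, traj$coords[, 1, f], traj$coords[, 2, f],
          traj$coords[, 3, f], 1, 0), con)
        writeLines("ENDMDL", con)
      }
      writeLines("END", con)
    },
    xyz = {
      con <- file(path, "w"); on.exit(close(con))
      for (f in seq_len(F)) {
        writeLines(sprintf("%d", nrow(top)), con)
        writeLines(sprintf("frame %d", f - 1L), con)
        writeLines(sprintf("%-6s %12.6f %12.6f %12.6f",
                           top$name, traj$coords[, 1, f],
                           traj$coords[, 2, f], traj$coords[, 3, f]), con)
      }
    }
  )
  invisible(path)
}

#' Read a structure or trajectory written by [write_structure()]
#'
#' @param path Input file.
#' @param format "gro", "pdb", or "xyz"; default guessed from the extension.
#' @param topology Optional topology data.frame to attach (required to
#'   restore residue-level labels from XYZ, which stores only atom names).
#' @param box Optional box vector (Angstrom) for formats that do not carry
#'   one (XYZ); inferred from coordinate extents with a warning if absent.
#' @return A `synthetic_traj`.
#' @export
read_structure <- function(path, format = NULL, topology = NULL, box = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  if (!format %in% c("gro", "pdb", "xyz")) {
    stop("unknown structure format: ", format)
  }
  switch(format,
    gro = .read_gro(path, topology),
    pdb = .read_pdb(path, topology, box),
    xyz = .read_xyz(path, topology, box)
  )
}

.num_or_stop <- function(s, path, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) {
    stop(sprintf("%s: malformed %s at line %d", path, what, lineno))
  }
  v
}

.read_gro <- function(path, topology) {
  lines <- readLines(path)
  frames <- list(); ln <- 1L
  resname <- name <- NULL; resid <- NULL; box <- NULL
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln])) && ln == length(lines)) break
    if (ln + 1L > length(lines)) {
      stop(sprintf("%s: truncated frame header at line %d", path, ln))
    }
    nat <- suppressWarnings(as.integer(trimws(lines[ln + 1L])))
    if (is.na(nat) || nat < 1) {
      stop(sprintf("%s: malformed atom count at line %d", path, ln + 1L))
    }
    if (ln + 1L + nat + 1L > length(lines)) {
      stop(sprintf("%s: truncated frame starting at line %d", path, ln))
    }
    al <- lines[(ln + 2L):(ln + 1L + nat)]
    rid <- .num_or_stop(substr(al, 1, 5), path, ln + 2L, "residue id")
    rnm <- trimws(substr(al, 6, 10))
    anm <- trimws(substr(al, 11, 15))
    x <- .num_or_stop(substr(al, 21, 28), path, ln + 2L, "x coordinate")
    y <- .num_or_stop(substr(al, 29, 36), path, ln + 2L, "y coordinate")
    z <- .num_or_stop(substr(al, 37, 44), path, ln + 2L, "z coordinate")
    bl <- ln + 2L + nat
    bv <- .num_or_stop(strsplit(trimws(lines[bl]), "\\s+")[[1]][1:3],
                       path, bl, "box line")
    if (is.null(resname)) {
      resname <- rnm; name <- anm; resid <- as.integer(rid); box <- bv * 10
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z) * 10  # nm -> Angstrom
    ln <- bl + 1L
  }
  if (!length(frames)) stop(path, ": no frames found")
  coords <- array(unlist(frames), dim = c(length(name), 3, length(frames)))
  top <- if (is.null(topology)) {
    .topology_from_names(resname, name, resid, coords[, 3, 1])
  } else topology
  synthetic_traj(top, coords, box)
}

# Fixed-column PDB parsing (ATOM/HETATM records, MODEL/ENDMDL frames,
# CRYST1 box).
.read_pdb <- function(path, topology, box) {
  lines <- readLines(path)
  cl <- grep("^CRYST1", lines)
  if (length(cl)) {
    l <- lines[cl[1]]
    box <- .num_or_stop(c(substr(l, 7, 15), substr(l, 16, 24),
                          substr(l, 25, 33)), path, cl[1], "CRYST1 record")
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_end <- grepl("^(ENDMDL|END($|\\s))", lines)
  frames <- list(); cur <- integer()
  name <- resname <- NULL; resid <- NULL
  flush <- function(rows) {
    al <- lines[rows]
    x <- .num_or_stop(substr(al, 31, 38), path, rows[1], "x coordinate")
    y <- .num_or_stop(substr(al, 39, 46), path, rows[1], "y coordinate")
    z <- .num_or_stop(substr(al, 47, 54), path, rows[1], "z coordinate")
    if (is.null(name)) {
      name <<- trimws(substr(al, 13, 16))
      resname <<- trimws(substr(al, 18, 21))
      resid <<- as.integer(.num_or_stop(substr(al, 23, 26), path, rows[1],
                                        "residue number"))
    }
    frames[[length(frames) + 1L]] <<- cbind(x, y, z)
  }
  for (ln in seq_along(lines)) {
    if (is_atom[ln]) {
      cur <- c(cur, ln)
    } else if (is_end[ln] && length(cur)) {
      flush(cur); cur <- integer()
    }
  }
  if (length(cur)) flush(cur)
  if (!length(frames)) stop(path, ": no ATOM records found")
  nat <- vapply(frames, nrow, 0L)
  if (any(nat != nat[1])) {
    stop(path, ": models have differing atom counts")
  }
  coords <- array(unlist(frames), dim = c(nat[1], 3, length(frames)))
  if (is.null(box)) {
    box <- apply(coords, 2, function(m) max(m) - min(m)) + 1
    warning("PDB file carries no CRYST1 record; box inferred from extents")
  }
  top <- if (is.null(topology)) {
    .topology_from_names(resname, name, resid, coords[, 3, 1])
  } else topology
  synthetic_traj(top, coords, box)
}

.read_xyz <- function(path, topology, box) {
  lines <- readLines(path)
  frames <- list(); name <- NULL; ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln])) && ln == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1) {
      stop(sprintf("%s: malformed atom count at line %d", path, ln))
    }
    if (ln + 1L + nat > length(lines)) {
      stop(sprintf("%s: truncated frame starting at line %d", path, ln))
    }
    al <- lines[(ln + 2L):(ln + 1L + nat)]
    tok <- strsplit(trimws(al), "\\s+")
    badn <- which(vapply(tok, length, 0L) < 4)
    if (length(badn)) {
      stop(sprintf("%s: malformed atom record at line %d",
                   path, ln + 1L + badn[1]))
    }
    nm <- vapply(tok, `[[`, "", 1)
    xyz <- t(vapply(tok, function(t)
      .num_or_stop(t[2:4], path, ln, "coordinate"), numeric(3)))
    if (is.null(name)) name <- nm
    frames[[length(frames) + 1L]] <- xyz
    ln <- ln + 2L + nat
  }
  if (!length(frames)) stop(path, ": no frames found")
  coords <- array(unlist(frames), dim = c(length(name), 3, length(frames)))
  if (is.null(box)) {
    box <- apply(coords, 2, function(m) max(m) - min(m)) + 1
    warning("XYZ carries no box; inferred from coordinate extents")
  }
  top <- if (is.null(topology)) {
    data.frame(name = name, group = name, species = "XYZ", resname = "XYZ",
               resid = seq_along(name), leaflet = "upper", mol = seq_along(name),
               mass = 1, dye_off = 0, peroxide_position = NA,
               stringsAsFactors = FALSE)
  } else topology
  synthetic_traj(top, coords, box)
}
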