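#' Read a PDB file as topology plus one frame
#'
#' Parsing is delegated to [bio3d::read.pdb()]. Occupancy and B-factor are
#' ignored. Element (hence mass) is inferred from the atom name following PDB
#' v3.3 conventions unless the record carries an element symbol. Role tags,
#' charges and donor/acceptor flags are not part of PDB; supply them with a
#' sidecar table ([read_sidecar()], [apply_sidecar()]). PDB serials are mapped
#' to 1-based atom indices on read. Box lengths come from the CRYST1 record
#' unless overridden.
#'
#' @param path PDB file path.
#' @param box optional length-3 box override (angstrom).
#' @return list with `topology` (`SystemTopology`) and `frame` (`ParticleFrame`).
#' @export
read_pdb_topology <- function(path, box = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem)) elem <- rep("", nrow(at))
  miss <- is.na(elem) | elem == ""
  if (any(miss))   # fall back to the atom-name convention
    elem[miss] <- suppressWarnings(bio3d::atom2ele(pdb))[miss]
  mass <- element_mass(elem)
  mol <- at$resno  # one molecule per residue number unless a sidecar overrides
  top <- system_topology(
    mass = mass, charge = rep(0, length(mass)),
    molecule_id = as.integer(mol),
    residue_name = as.character(at$resid),
    role = rep("solvent", length(mass)),
    atom_name = as.character(at$elety)
  )
  if (is.null(box)) {
    cl <- grep("^CRYST1", readLines(path), value = TRUE)
    if (length(cl)) {
      v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                        substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
      if (any(abs(v[4:6] - 90) > 1e-3))
        stop("unsupported: triclinic cell in CRYST1 (orthorhombic boxes only)")
      box <- v[1:3]
    }
    if (is.null(box) || any(!is.finite(box)) || any(box <= 0))
      stop("PDB has no usable CRYST1 box; pass `box` explicitly")
  }
  frame <- particle_frame(cbind(at$x, at$y, at$z), box = box, time = 0, index = 0L)
  list(topology = top, frame = frame)
}

# masses (amu) for the elements the package's systems contain
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                  S = 32.06, CL = 35.45, NA. = 22.990, K = 39.098, X = 12.011)

element_mass <- function(elem) {
  key <- toupper(trimws(elem))
  key[key == "NA"] <- "NA."
  m <- ELEMENT_MASS[key]
  m[is.na(m)] <- ELEMENT_MASS[["X"]]
  unname(m)
}

#' Write topology + frame as a PDB file
#'
#' Fixed-width PDB v3.3 ATOM records (residue name in columns 18-21, the
#' common 4-character extension; element symbol in 77-78 from the atomic
#' mass) plus a CRYST1 record carrying the orthorhombic box.
#' @param topology,frame the system to write.
#' @param path output path.
#' @export
write_pdb_frame <- function(topology, frame, path) {
  a <- topology$atoms
  nm <- if (!is.null(a$atom_name)) a$atom_name else rep("C", nrow(a))
  elem <- mass_to_element(a$mass)
  n <- nrow(a)
  lines <- sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(n) %% 100000L, substr(nm, 1, 4),
                   substr(a$residue_name, 1, 4), "A",
                   a$molecule_id %% 10000L,
                   frame$coords[, 1], frame$coords[, 2], frame$coords[, 3],
                   1, 0, elem)
  cry <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                 frame$box[1], frame$box[2], frame$box[3], 90, 90, 90)
  writeLines(c(cry, lines, "END"), path)
  invisible(path)
}

mass_to_element <- function(mass) {
  ref <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)
  names(ref)[apply(abs(outer(mass, ref, "-")), 1, which.min)]
}

#' Read/write the sidecar atom-annotation table
#'
#' CSV columns: `atom_index` (1-based), `role`, `charge`, `is_donor_heavy`,
#' `is_polar_hydrogen`, `is_acceptor`, `donor_of` (1-based index of the donor
#' heavy atom for a polar hydrogen, empty otherwise). Optional columns
#' `mass` and `molecule_id` override values inferred from the structure file.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sidecar <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("atom_index", "role", "charge", "is_donor_heavy",
            "is_polar_hydrogen", "is_acceptor", "donor_of")
  miss <- setdiff(need, names(sc))
  if (length(miss)) stop("sidecar missing column(s): ", paste(miss, collapse = ", "))
  sc
}

#' @rdname read_sidecar
#' @param topology topology to annotate.
#' @param sidecar data.frame from [read_sidecar()].
#' @return annotated `SystemTopology`.
#' @export
apply_sidecar <- function(topology, sidecar) {
  a <- topology$atoms
  i <- as.integer(sidecar$atom_index)
  if (any(i < 1L | i > nrow(a))) stop("sidecar atom_index out of range")
  a$role[i] <- as.character(sidecar$role)
  a$charge[i] <- as.numeric(sidecar$charge)
  a$is_donor_heavy[i] <- as.logical(sidecar$is_donor_heavy)
  a$is_polar_hydrogen[i] <- as.logical(sidecar$is_polar_hydrogen)
  a$is_acceptor[i] <- as.logical(sidecar$is_acceptor)
  a$donor_of[i] <- suppressWarnings(as.integer(sidecar$donor_of))
  if (!is.null(sidecar$mass)) a$mass[i] <- as.numeric(sidecar$mass)
  if (!is.null(sidecar$molecule_id)) a$molecule_id[i] <- as.integer(sidecar$molecule_id)
  do.call(system_topology, c(as.list(a[setdiff(names(a), "atom_name")]),
                             if (!is.null(a$atom_name)) list(atom_name = a$atom_name)))
}

#' @rdname read_sidecar
#' @export
write_sidecar <- function(topology, path) {
  a <- topology$atoms
  utils::write.csv(data.frame(
    atom_index = seq_len(nrow(a)), role = a$role, charge = a$charge,
    is_donor_heavy = a$is_donor_heavy, is_polar_hydrogen = a$is_polar_hydrogen,
    is_acceptor = a$is_acceptor, donor_of = a$donor_of,
    mass = a$mass, molecule_id = a$molecule_id
  ), path, row.names = FALSE)
  invisible(path)
}

#' Extended-XYZ multi-frame trajectory I/O
#'
#' The comment line of each frame carries the box and time stamp in the
#' extended-XYZ convention:
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz" Time=<ns> Frame=<index>`.
#' Only orthorhombic lattices are accepted.
#'
#' @param path file path.
#' @param topology topology the coordinates bind to (atom counts must match).
#' @return [md_trajectory()] for the reader; the writer returns `path`.
#' @export
read_xyz_trajectory <- function(path, topology) {
  lines <- readLines(path)
  frames <- list(); i <- 1L; fi <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- as.integer(trimws(lines[i]))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i)
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lat) < 2L) stop("XYZ comment line lacks Lattice=\"...\"")
    cell <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    if (length(cell) != 9L) stop("Lattice must have 9 numbers")
    off <- cell[c(2, 3, 4, 6, 7, 8)]
    if (any(abs(off) > 1e-8)) stop("unsupported: non-orthorhombic Lattice")
    box <- cell[c(1, 5, 9)]
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    tm <- if (length(tm) >= 2L) as.numeric(tm[2]) else fi
    body <- lines[(i + 2L):(i + 1L + nat)]
    co <- matrix(NA_real_, nat, 3L)
    sp <- strsplit(trimws(body), "\\s+")
    for (j in seq_len(nat)) co[j, ] <- as.numeric(sp[[j]][2:4])
    frames[[length(frames) + 1L]] <- particle_frame(co, box, time = tm, index = fi)
    fi <- fi + 1L
    i <- i + 2L + nat
  }
  md_trajectory(topology, frames)
}

#' @rdname read_xyz_trajectory
#' @param traj an `md_trajectory` to write.
#' @export
write_xyz_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  sym <- if (!is.null(a$atom_name)) substr(a$atom_name, 1, 2) else rep("C", nrow(a))
  con <- file(path, "w"); on.exit(close(con))
  for (f in traj$frames) {
    writeLines(as.character(nrow(f$coords)), con)
    writeLines(sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" Time=%g Frame=%d Properties=species:S:1:pos:R:3',
                       f$box[1], f$box[2], f$box[3], f$time, f$index), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", sym, f$coords[, 1], f$coords[, 2],
                       f$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a DCD coordinate trajectory bound to an existing topology
#'
#' Uses [bio3d::read.dcd()]. DCD carries no box for all variants; frames take
#' the per-frame unit cell when present, else `box`.
#'
#' @param path DCD path.
#' @param topology binding topology.
#' @param box fallback length-3 box (angstrom).
#' @param dt time step between stored frames (ns) for the time stamps.
#' @return [md_trajectory()].
#' @export
read_dcd_trajectory <- function(path, topology, box, dt = 1) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nat <- ncol(xyz) / 3L
  if (nat != n_atoms(topology))
    stop("DCD atom count (", nat, ") does not match topology (", n_atoms(topology), ")")
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    particle_frame(matrix(xyz[i, ], ncol = 3L, byrow = TRUE), box = box,
                   time = (i - 1L) * dt, index = i - 1L)
  })
  md_trajectory(topology, frames)
}

# Minimal CHARMM/NAMD-style DCD writer (no unit cell), used to produce
# round-trip fixtures at test time; not part of the public API.
write_dcd_minimal <- function(traj, path) {
  con <- file(path, "wb"); on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4L, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4L, endian = "little")
  }
  nfrm <- length(traj$frames); nat <- n_atoms(traj$topology)
  rec(function() {
    writeChar("CORD", con, 4L, eos = NULL)
    icntrl <- integer(20L); icntrl[1] <- nfrm; icntrl[2] <- 1L; icntrl[3] <- 1L
    icntrl[4] <- nfrm; icntrl[20] <- 24L
    writeBin(icntrl, con, size = 4L, endian = "little")
  }, 84L)
  rec(function() {
    writeBin(1L, con, size = 4L, endian = "little")
    writeChar(formatC("created by nanomem", width = 80L, flag = "-"), con, 80L, eos = NULL)
  }, 84L)
  rec(function() writeBin(as.integer(nat), con, size = 4L, endian = "little"), 4L)
  for (f in traj$frames) for (k in 1:3)
    rec(function() writeBin(as.numeric(f$coords[, k]), con, size = 4L, endian = "little"),
        4L * nat)
  invisible(path)
}
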