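#' System topology: per-atom metadata
#'
#' Holds per-atom mass, partial charge, molecule id, residue label, a role
#' tag, and hydrogen-bond donor/acceptor annotation. Role tags (rather than
#' force-field chemistry) drive every selection in the package, keeping the
#' analyses engine-agnostic.
#'
#' @param mass numeric, amu per atom (> 0).
#' @param charge numeric, partial charge in elementary charges.
#' @param molecule_id integer molecule id per atom.
#' @param residue_name character residue label per atom.
#' @param role character per atom: drug, peptide, linker, lipid_head,
#'   lipid_tail, solvent, or ion.
#' @param is_donor_heavy,is_polar_hydrogen,is_acceptor logical flags per atom.
#' @param donor_of integer per atom: for a polar hydrogen, the 1-based index
#'   of its covalently bound donor heavy atom; `NA` otherwise.
#' @param atom_name optional character atom names.
#' @return object of class `SystemTopology` (a list with data.frame `atoms`).
#' @export
system_topology <- function(mass, charge = rep(0, length(mass)),
                            molecule_id = rep(1L, length(mass)),
                            residue_name = rep("MOL", length(mass)),
                            role = rep("solvent", length(mass)),
                            is_donor_heavy = rep(FALSE, length(mass)),
                            is_polar_hydrogen = rep(FALSE, length(mass)),
                            is_acceptor = rep(FALSE, length(mass)),
                            donor_of = rep(NA_integer_, length(mass)),
                            atom_name = NULL) {
  n <- length(mass)
  if (n == 0L) stop("topology needs at least one atom")
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("masses must be positive")
  role <- as.character(role)
  bad <- setdiff(unique(role), ROLE_LEVELS)
  if (length(bad)) stop("unknown role tag(s): ", paste(bad, collapse = ", "))
  donor_of <- as.integer(donor_of)
  hyd <- which(as.logical(is_polar_hydrogen))
  if (any(is.na(donor_of[hyd])))
    stop("every polar hydrogen must map to exactly one donor heavy atom")
  if (length(hyd) && any(!as.logical(is_donor_heavy)[donor_of[hyd]]))
    stop("donor_of must point at atoms flagged is_donor_heavy")
  atoms <- data.frame(
    mass = as.numeric(mass),
    charge = as.numeric(charge),
    molecule_id = as.integer(molecule_id),
    residue_name = as.character(residue_name),
    role = role,
    is_donor_heavy = as.logical(is_donor_heavy),
    is_polar_hydrogen = as.logical(is_polar_hydrogen),
    is_acceptor = as.logical(is_acceptor),
    donor_of = donor_of,
    stringsAsFactors = FALSE
  )
  if (!is.null(atom_name)) atoms$atom_name <- as.character(atom_name)
  structure(list(atoms = atoms), class = "SystemTopology")
}

#' Recognised role tags
#' @export
ROLE_LEVELS <- c("drug", "peptide", "linker", "lipid_head", "lipid_tail",
                 "solvent", "ion")

#' Number of atoms in a topology
#' @param topology a `SystemTopology`.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' @export
print.SystemTopology <- function(x, ...) {
  cat(sprintf("SystemTopology: %d atoms, %d molecules\n",
              n_atoms(x), length(unique(x$atoms$molecule_id))))
  print(table(x$atoms$role))
  invisible(x)
}

#' One trajectory frame
#'
#' @param coords numeric n x 3 matrix of coordinates (angstrom).
#' @param box length-3 orthorhombic box edge lengths (angstrom).
#' @param time time stamp in ns.
#' @param index integer frame index.
#' @return object of class `ParticleFrame`.
#' @export
particle_frame <- function(coords, box, time = 0, index = 0L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  check_box(box)
  structure(list(coords = coords, box = as.numeric(box),
                 time = as.numeric(time), index = as.integer(index)),
            class = "ParticleFrame")
}

#' @export
print.ParticleFrame <- function(x, ...) {
  cat(sprintf("ParticleFrame %d (t = %g ns): %d atoms, box %.2f x %.2f x %.2f A\n",
              x$index, x$time, nrow(x$coords), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Trajectory container
#'
#' @param topology a `SystemTopology` shared by all frames.
#' @param frames list of `ParticleFrame`s, each with coordinate count equal to
#'   the topology atom count.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames) {
  if (!inherits(topology, "SystemTopology")) stop("need a SystemTopology")
  if (!length(frames)) stop("need at least one frame")
  for (f in frames) {
    if (!inherits(f, "ParticleFrame")) stop("frames must be ParticleFrame objects")
    if (nrow(f$coords) != n_atoms(topology))
      stop("frame coordinate count does not match topology atom count")
  }
  structure(list(topology = topology, frames = frames), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms\n",
              length(x$frames), n_atoms(x$topology)))
  invisible(x)
}

#' @export
length.md_trajectory <- function(x) length(x$frames)

#' Resolve an atom selection
#'
#' Deterministic for a fixed topology: returns sorted 1-based atom indices.
#' Criteria combine with AND; vectors of allowed values combine with OR
#' within a criterion. A custom `predicate` over the atom table may be given
#' instead of (or in addition to) the keyword filters.
#'
#' @param topology a `SystemTopology`.
#' @param role allowed role tag(s), e.g. `"drug"` or `c("lipid_head","lipid_tail")`.
#' @param residue allowed residue label(s).
#' @param molecule allowed molecule id(s).
#' @param heavy_only if TRUE, drop hydrogens (mass < 1.5 amu).
#' @param predicate optional function(atoms_data_frame) -> logical vector.
#' @return sorted integer vector of atom indices.
#' @examples
#' ## drug heavy atoms: select_atoms(top, role = "drug", heavy_only = TRUE)
#' @export
select_atoms <- function(topology, role = NULL, residue = NULL, molecule = NULL,
                         heavy_only = FALSE, predicate = NULL) {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(residue)) keep <- keep & a$residue_name %in% residue
  if (!is.null(molecule)) keep <- keep & a$molecule_id %in% molecule
  if (heavy_only) keep <- keep & a$mass >= 1.5
  if (!is.null(predicate)) keep <- keep & as.logical(predicate(a))
  which(keep)
}
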