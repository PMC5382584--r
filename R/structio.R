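# Structure / trajectory / parameter-table I-O.
# The reference interchange format is multi-model PDB (one MODEL per frame);
# bio3d does the fixed-column parsing and writing.

WATER_RESNAMES <- c("HOH", "WAT", "SOL")
WATER_OXYGEN_NAMES <- c("O", "OW", "OH2")
BACKBONE_NAMES <- c("N", "CA", "C", "O")

# standard atomic masses (Da) for the elements the toolkit encounters
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098, MG = 24.305,
  FE = 55.845, ZN = 65.38
)

.element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .ELEMENT_MASS[key]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon-like
  unname(m)
}

.guess_element <- function(name) {
  # first alphabetic character of the atom name, two-letter ions recognized
  nm <- toupper(trimws(name))
  two <- substr(nm, 1L, 2L)
  el <- ifelse(two %in% c("NA", "CL", "MG", "FE", "ZN"),
               two, substr(gsub("[^A-Z]", "", nm), 1L, 1L))
  el[el == ""] <- "C"
  el
}

#' Construct a Topology
#'
#' A Topology holds the per-atom identity and parameters of the system plus
#' named atom groups. Groups `carrier`, `ligand` and `solvent` partition the
#' system: water residues (HOH/WAT/SOL) are always solvent, the designated
#' ligand chain is the bound transmembrane helix, and everything else is the
#' carrier protein.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_id`, `chain_id`, `mass`, `charge`, `lj_sigma`,
#'   `lj_epsilon`, `born_radius`.
#' @param groups named list of integer index vectors into `atoms`.
#' @return An object of class `Topology`.
#' @export
topology <- function(atoms, groups = list()) {
  req <- c("serial", "name", "element", "res_name", "res_id", "chain_id",
           "mass", "charge", "lj_sigma", "lj_epsilon", "born_radius")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("empty topology: zero atoms")
  if (any(atoms$mass <= 0)) stop("all atom masses must be > 0")
  if (any(atoms$lj_sigma < 0) || any(atoms$lj_epsilon < 0) ||
      any(atoms$born_radius < 0)) {
    stop("LJ and Born parameters must be non-negative")
  }
  n <- nrow(atoms)
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) && (any(idx < 1L) || any(idx > n))) {
      stop("group '", g, "' has out-of-range indices")
    }
    groups[[g]] <- sort(unique(as.integer(idx)))
  }
  all_idx <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop("groups must be disjoint")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, groups = groups), class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d chains; groups: %s\n",
              nrow(x$atoms), length(unique(x$atoms$chain_id)),
              paste(sprintf("%s(%d)", names(x$groups),
                            lengths(x$groups)), collapse = ", ")))
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

.default_groups <- function(atoms, ligand_chain) {
  solvent <- which(atoms$res_name %in% WATER_RESNAMES |
                   atoms$res_name %in% c("NA", "CL", "NA+", "CL-"))
  ligand <- setdiff(which(atoms$chain_id == ligand_chain), solvent)
  carrier <- setdiff(seq_len(nrow(atoms)), c(solvent, ligand))
  list(carrier = carrier, ligand = ligand, solvent = solvent)
}

#' Construct a Trajectory
#'
#' @param frames list of `n_atoms x 3` coordinate matrices (Angstrom).
#' @param times frame times in ns, strictly increasing; defaults to
#'   `(0:(n-1)) * dt`.
#' @param box optional orthorhombic box lengths: a length-3 vector applied to
#'   all frames, or an `n_frames x 3` matrix.
#' @param dt frame spacing in ns used when `times` is not given (default 0.1).
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(frames, times = NULL, box = NULL, dt = 0.1) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  nat <- nrow(frames[[1L]])
  ok <- vapply(frames, function(f) is.matrix(f) && ncol(f) == 3L &&
                 nrow(f) == nat, logical(1L))
  if (!all(ok)) stop("inconsistent atom counts across frames")
  if (is.null(times)) times <- (seq_along(frames) - 1) * dt
  if (length(times) != length(frames)) stop("times/frames length mismatch")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = length(frames),
                                         ncol = 3L, byrow = TRUE)
    if (nrow(box) != length(frames) || ncol(box) != 3L) {
      stop("box must be a length-3 vector or n_frames x 3 matrix")
    }
  }
  structure(list(frames = frames, times = as.numeric(times), box = box),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = [%g, %g] ns%s\n",
              length(x$frames), nrow(x$frames[[1L]]),
              min(x$times), max(x$times),
              if (is.null(x$box)) "" else
                sprintf(", box %s A", paste(signif(x$box[1L, ], 4),
                                            collapse = " x "))))
  invisible(x)
}

n_frames <- function(trajectory) length(trajectory$frames)

frame_box <- function(trajectory, f) {
  if (is.null(trajectory$box)) NULL else trajectory$box[f, ]
}

#' Read a multi-model PDB as (Topology, Trajectory)
#'
#' Each MODEL record becomes one frame; a file without MODEL records is a
#' single-frame trajectory. Charges and LJ/Born parameters default to 0 until
#' a parameter table is applied with [apply_param_table()]. Frame times are
#' `frame index * dt`; an optional CRYST1 record supplies an orthorhombic box.
#'
#' @param path PDB file path.
#' @param ligand_chain chain id of the bound helix used for default group
#'   assignment (default `"L"`).
#' @param dt frame spacing in ns (default 0.1).
#' @return list with elements `topology` and `trajectory`.
#' @export
read_pdb_models <- function(path, ligand_chain = "L", dt = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
                  error = function(e) stop("PDB format error: ",
                                           conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L) stop("zero atoms in ", path)
  a <- pdb$atom
  element <- ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                    .guess_element(a$elety), toupper(trimws(a$elesy)))
  atoms <- data.frame(
    serial = a$eleno, name = trimws(a$elety), element = element,
    res_name = trimws(a$resid), res_id = a$resno,
    chain_id = ifelse(is.na(a$chain), " ", a$chain),
    mass = .element_mass(element),
    charge = 0, lj_sigma = 0, lj_epsilon = 0, born_radius = 0,
    stringsAsFactors = FALSE
  )
  nat <- nrow(atoms)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nat) {
    stop("PDB format error: inconsistent atom counts across models")
  }
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  })
  box <- .read_cryst1(path)
  topo <- topology(atoms, .default_groups(atoms, ligand_chain))
  traj <- trajectory(frames, dt = dt,
                     box = if (is.null(box)) NULL else box)
  list(topology = topo, trajectory = traj)
}

.read_cryst1 <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  while (length(line <- readLines(con, n = 1L))) {
    if (startsWith(line, "CRYST1")) {
      v <- suppressWarnings(as.numeric(c(substr(line, 7, 15),
                                         substr(line, 16, 24),
                                         substr(line, 25, 33))))
      if (!anyNA(v) && all(v > 0)) return(v)
      return(NULL)
    }
    if (startsWith(line, "ATOM") || startsWith(line, "MODEL")) return(NULL)
  }
  NULL
}

#' Write a (Topology, Trajectory) pair as multi-model PDB
#'
#' Coordinates are written at PDB fixed precision (3 decimals), one
#' MODEL/ENDMDL block per frame, with a CRYST1 record when the trajectory
#' carries a box.
#'
#' @param topology a [topology()].
#' @param trajectory a [trajectory()]; atom count must match.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(topology, trajectory, path) {
  stopifnot(inherits(topology, "Topology"), inherits(trajectory, "Trajectory"))
  if (n_frames(trajectory) == 0L) stop("cannot write a 0-frame trajectory")
  if (nrow(trajectory$frames[[1L]]) != n_atoms(topology)) {
    stop("trajectory atom count does not match topology")
  }
  crds <- unlist(lapply(trajectory$frames, function(f) as.vector(t(f))))
  if (any(!is.finite(crds))) stop("non-finite coordinate")
  a <- topology$atoms
  xyz <- do.call(rbind, lapply(trajectory$frames,
                               function(f) as.vector(t(f))))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name, resid = a$res_name,
                   chain = a$chain_id, resno = a$res_id, elesy = a$element)
  if (!is.null(trajectory$box)) {
    b <- trajectory$box[1L, ]
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1L], b[2L], b[3L], 90, 90, 90)
    writeLines(c(cryst, readLines(path)), path)
  }
  invisible(path)
}

#' Read a per-atom parameter table
#'
#' The table is TSV with header columns `res_name`, `atom_name`, `charge`
#' (elementary charges), `lj_sigma` (Angstrom), `lj_epsilon` (kcal/mol),
#' `born_radius` (Angstrom) and `mass` (Da), keyed by (residue name,
#' atom name).
#'
#' @param path TSV file path.
#' @return An object of class `ParamTable` (a data.frame).
#' @export
read_param_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("res_name", "atom_name", "charge", "lj_sigma", "lj_epsilon",
           "born_radius", "mass")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("parameter table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(d$res_name, d$atom_name)
  if (anyDuplicated(key)) {
    stop("parameter table format error: duplicate key ",
         key[anyDuplicated(key)][1L])
  }
  class(d) <- c("ParamTable", "data.frame")
  d
}

#' Write a parameter table as TSV
#'
#' @param params a `ParamTable` (see [read_param_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(params, path) {
  utils::write.table(as.data.frame(params), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a parameter table to a Topology
#'
#' Sets `charge`, `lj_sigma`, `lj_epsilon`, `born_radius` and `mass` on every
#' atom whose (residue name, atom name) pair appears in the table. The
#' operation is idempotent.
#'
#' @param topology a [topology()].
#' @param params a `ParamTable`.
#' @return list with elements `topology` (updated) and `unmatched` (integer
#'   indices of atoms with no table entry).
#' @export
apply_param_table <- function(topology, params) {
  stopifnot(inherits(topology, "Topology"))
  a <- topology$atoms
  key_atoms <- paste(a$res_name, a$name)
  key_tab <- paste(params$res_name, params$atom_name)
  idx <- match(key_atoms, key_tab)
  hit <- !is.na(idx)
  a$charge[hit] <- params$charge[idx[hit]]
  a$lj_sigma[hit] <- params$lj_sigma[idx[hit]]
  a$lj_epsilon[hit] <- params$lj_epsilon[idx[hit]]
  a$born_radius[hit] <- params$born_radius[idx[hit]]
  a$mass[hit] <- params$mass[idx[hit]]
  topology$atoms <- a
  list(topology = topology, unmatched = which(!hit))
}
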