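#' @importFrom stats rnorm setNames
#' @importFrom utils write.table read.table
NULL

# Standard amino-acid residue names, including common MD protonation-state
# variants of histidine (HSD/HSE neutral, HSP/HIP protonated).
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "HSD", "HSE", "HSP", "HID", "HIE", "HIP",
                 "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
                 "TRP", "TYR", "VAL")

#' Construct a trajectory object
#'
#' Internal constructor for the `cc_trajectory` class: per-frame Cartesian
#' coordinates (Angstrom) for a fixed atom set, plus per-atom metadata.
#' Coordinates follow the frames x 3N layout (columns x1, y1, z1, x2, ...)
#' used by bio3d.
#'
#' @param xyz numeric matrix, n_frames rows, 3 * n_atoms columns.
#' @param atoms data.frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_id`, `chain_id`, `protein_tag`.
#' @param frame_stride_ps time between frames in picoseconds, or `NA`.
#' @return object of class `cc_trajectory`.
#' @keywords internal
new_trajectory <- function(xyz, atoms, frame_stride_ps = NA_real_) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(ncol(xyz) == 3L * nrow(atoms))
  if (!all(is.finite(xyz))) stop("trajectory coordinates must be finite")
  atoms$atom_name <- as.character(atoms$atom_name)
  if (any(!nzchar(atoms$atom_name))) stop("atom_name must be nonempty")
  structure(
    list(xyz = xyz, atoms = atoms, n_frames = nrow(xyz),
         frame_stride_ps = frame_stride_ps),
    class = "cc_trajectory")
}

#' @export
print.cc_trajectory <- function(x, ...) {
  cat(sprintf("<cc_trajectory> %d frames, %d atoms (%d protein1 / %d protein2)\n",
              x$n_frames, nrow(x$atoms),
              sum(x$atoms$protein_tag == "protein1"),
              sum(x$atoms$protein_tag == "protein2")))
  invisible(x)
}

# Column indices of atom i in the frames x 3N coordinate matrix.
xyz_cols <- function(i) as.vector(rbind(3L * i - 2L, 3L * i - 1L, 3L * i))

# One frame as an n_atoms x 3 matrix.
frame_coords <- function(traj, frame) {
  matrix(traj$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Residue labels of the form "chain:resid:resname"
#'
#' @param atoms atom metadata data.frame.
#' @return character vector, one label per atom row.
#' @keywords internal
atom_residue_label <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_id, atoms$residue_name, sep = ":")
}

#' Parse a selection expression
#'
#' Mini-language of `and`-joined terms: `chain <id>` and
#' `resid <a>-<b>` (or a space-separated list of residue ids), e.g.
#' `"chain B and resid 330-530"`.
#'
#' @param expr selection expression string.
#' @param atoms atom metadata data.frame.
#' @return logical vector over atom rows.
#' @export
parse_selection <- function(expr, atoms) {
  terms <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  sel <- rep(TRUE, nrow(atoms))
  for (term in terms) {
    tok <- strsplit(trimws(term), "\\s+")[[1]]
    if (length(tok) < 2L)
      stop(sprintf("cannot parse selection term '%s' in '%s'", term, expr))
    key <- tolower(tok[1])
    if (key == "chain") {
      sel <- sel & atoms$chain_id %in% tok[-1]
    } else if (key == "resid") {
      ids <- integer(0)
      for (piece in tok[-1]) {
        if (grepl("^-?[0-9]+--?[0-9]+$", piece) || grepl("^[0-9]+-[0-9]+$", piece)) {
          ab <- as.integer(strsplit(piece, "(?<=[0-9])-", perl = TRUE)[[1]])
          ids <- c(ids, seq(ab[1], ab[2]))
        } else {
          ids <- c(ids, as.integer(piece))
        }
      }
      sel <- sel & atoms$residue_id %in% ids
    } else {
      stop(sprintf("unknown selection keyword '%s' in '%s'", key, expr))
    }
  }
  sel
}

# Derive the element symbol from a PDB v3 atom name when the file omits it.
guess_element <- function(atom_name) {
  first <- substr(gsub("^[0-9]+", "", atom_name), 1L, 1L)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, "C")
}

#' Load an MD trajectory with two protein selections
#'
#' Reads a PDB topology (multi-model PDB files are treated as trajectory
#' frames) and, optionally, a separate DCD coordinate file. Resolves the
#' two selection expressions, tags every selected atom as `protein1` or
#' `protein2`, and returns the combined trajectory in file atom order.
#' Alternate-location variants other than the primary (altloc `A` or blank)
#' are dropped with a message.
#'
#' @param topology_path path to a PDB file.
#' @param coords_path optional path to a DCD file (or a multi-model PDB);
#'   if `NULL`, coordinates come from the topology's MODEL records. XTC is
#'   not supported; convert to DCD or multi-model PDB first.
#' @param selection1,selection2 selection expressions (see
#'   [parse_selection()]); must be non-empty and disjoint.
#' @param frame_stride_ps time between frames (ps), if known.
#' @return a `cc_trajectory`.
#' @export
load_trajectory <- function(topology_path, coords_path = NULL,
                            selection1, selection2,
                            frame_stride_ps = NA_real_) {
  if (!file.exists(topology_path))
    stop(sprintf("cannot read topology file '%s'", topology_path))
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)

  at <- pdb$atom
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  if (any(!keep_alt)) {
    message(sprintf("dropping %d alternate-location atoms (keeping altloc A/blank)",
                    sum(!keep_alt)))
  }

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (!is.null(coords_path)) {
    if (!file.exists(coords_path))
      stop(sprintf("cannot read coordinate file '%s'", coords_path))
    ext <- tolower(tools::file_ext(coords_path))
    if (ext == "dcd") {
      xyz <- bio3d::read.dcd(coords_path, verbose = FALSE)
    } else if (ext == "xtc") {
      stop("XTC reading is not supported; convert the trajectory to DCD or multi-model PDB")
    } else if (ext %in% c("pdb", "ent")) {
      cp <- bio3d::read.pdb(coords_path, multi = TRUE, verbose = FALSE)
      xyz <- cp$xyz
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    } else {
      stop(sprintf("unsupported coordinate format '%s'", ext))
    }
    if (ncol(xyz) != 3L * nrow(at))
      stop("coordinate file atom count does not match topology")
  }

  atoms <- data.frame(
    atom_name    = at$elety,
    element      = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                          guess_element(at$elety), trimws(at$elesy)),
    residue_name = at$resid,
    residue_id   = at$resno,
    chain_id     = ifelse(is.na(at$chain), "", at$chain),
    stringsAsFactors = FALSE)

  sel1 <- parse_selection(selection1, atoms) & keep_alt
  sel2 <- parse_selection(selection2, atoms) & keep_alt
  if (!any(sel1))
    stop(sprintf("selection '%s' matched no atoms", selection1))
  if (!any(sel2))
    stop(sprintf("selection '%s' matched no atoms", selection2))
  if (any(sel1 & sel2))
    stop(sprintf("selections '%s' and '%s' overlap (%d atoms in both)",
                 selection1, selection2, sum(sel1 & sel2)))

  keep <- which(sel1 | sel2)  # file order
  atoms <- atoms[keep, , drop = FALSE]
  atoms$protein_tag <- ifelse(sel1[keep], "protein1", "protein2")
  rownames(atoms) <- NULL
  new_trajectory(xyz[, xyz_cols(keep), drop = FALSE], atoms, frame_stride_ps)
}

#' Restrict a trajectory to a coarse-grained representation
#'
#' `calpha` keeps exactly one CA atom per standard amino-acid residue
#' (residues lacking a CA are dropped with a warning), `backbone` keeps
#' N/CA/C/O, `allatom` is the identity.
#'
#' @param traj a `cc_trajectory`.
#' @param mode one of `"calpha"`, `"backbone"`, `"allatom"`.
#' @return a `cc_trajectory` restricted to the chosen atoms.
#' @export
select_representation <- function(traj, mode = c("calpha", "backbone", "allatom")) {
  mode <- match.arg(mode)
  if (mode == "allatom") return(traj)
  at <- traj$atoms
  if (mode == "backbone") {
    keep <- which(at$atom_name %in% c("N", "CA", "C", "O"))
  } else {
    aa <- at$residue_name %in% STANDARD_AA
    keep <- which(aa & at$atom_name == "CA")
    # report amino-acid residues that carry no CA atom
    reskey <- paste(at$chain_id, at$residue_id)
    aa_res <- unique(reskey[aa])
    ca_res <- unique(reskey[keep])
    missing <- setdiff(aa_res, ca_res)
    if (length(missing))
      warning(sprintf("dropping %d residue(s) without a CA atom: %s",
                      length(missing), paste(missing, collapse = ", ")))
  }
  if (!length(keep)) stop(sprintf("no atoms match representation '%s'", mode))
  new_trajectory(traj$xyz[, xyz_cols(keep), drop = FALSE],
                 traj$atoms[keep, , drop = FALSE],
                 traj$frame_stride_ps)
}

#' Remove rigid-body motion of the whole complex
#'
#' Least-squares superposes every frame onto an iteratively refined mean
#' structure of the full atom set (both proteins together), removing global
#' translation and rotation while preserving internal and inter-protein
#' relative motion.
#'
#' @param traj a `cc_trajectory` with at least 3 atoms.
#' @param max_iter maximum refinement iterations.
#' @param tol stop when the mean structure moves less than this RMS (Angstrom).
#' @return superposed `cc_trajectory`.
#' @export
superpose_trajectory <- function(traj, max_iter = 5L, tol = 1e-6) {
  if (nrow(traj$atoms) < 3L) {
    # a rigid-body fit is underdetermined below 3 atoms, and removing the
    # centroid alone would delete the shared motion a 2-bead system carries
    warning("fewer than 3 atoms: rigid-body superposition skipped")
    return(traj)
  }
  inds <- seq_len(ncol(traj$xyz))
  ref <- traj$xyz[1L, ]
  xyz <- traj$xyz
  for (it in seq_len(max_iter)) {
    fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                             fixed.inds = inds, mobile.inds = inds)
    m <- colMeans(fitted)
    if (sqrt(mean((m - ref)^2)) < tol) { xyz <- fitted; break }
    ref <- m
    xyz <- fitted
  }
  out <- traj
  out$xyz <- unclass(xyz)
  out
}

#' Trajectory-averaged structure
#'
#' Arithmetic per-atom mean of the frames, optionally after rigid-body
#' superposition of every frame onto an iteratively refined mean of the
#' whole complex. The default removes global drift, which would otherwise
#' inflate both the covariance and the averaged inter-residue distances.
#'
#' @param traj a `cc_trajectory` with `n_frames >= 2`.
#' @param superpose superpose frames before averaging (default `TRUE`).
#' @return object of class `cc_avg_structure` with `mean_coords`
#'   (n_atoms x 3), `source_n_frames` and the atom table.
#' @export
compute_average_structure <- function(traj, superpose = TRUE) {
  if (traj$n_frames < 2L) stop("averaging requires at least 2 frames")
  if (superpose) traj <- superpose_trajectory(traj)
  m <- colMeans(traj$xyz)
  structure(
    list(mean_coords = matrix(m, ncol = 3L, byrow = TRUE),
         source_n_frames = traj$n_frames,
         atoms = traj$atoms),
    class = "cc_avg_structure")
}

#' @export
print.cc_avg_structure <- function(x, ...) {
  cat(sprintf("<cc_avg_structure> %d atoms averaged over %d frames\n",
              nrow(x$mean_coords), x$source_n_frames))
  invisible(x)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at PDB precision (0.001 Angstrom), one MODEL
#' record per frame. Frequencies or other per-atom scores can be placed in
#' the B-factor column.
#'
#' @param traj a `cc_trajectory`.
#' @param path output file path.
#' @param b optional per-atom B-factor vector (e.g. frequencies).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, b = NULL) {
  at <- traj$atoms
  if (is.null(b)) b <- rep(0, nrow(at))
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = at$residue_id, resid = at$residue_name,
                   elety = at$atom_name, chain = at$chain_id,
                   b = b)
  invisible(path)
}
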