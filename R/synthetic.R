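# Synthetic trajectory generators. Coupled Gaussian bead (C-alpha level)
# trajectories with known cross-correlation structure, and toy all-atom
# residue-pair fixtures whose interaction criteria are satisfied in a
# controlled fraction of frames. These define the testbed for every stage
# of the workflow; they are not force-field dynamics.

#' Specification for a coupled-bead trajectory
#'
#' Describes two bead proteins (one bead per residue) whose per-frame
#' displacements are multivariate Gaussian: each planted pair (i, j)
#' has normalized 3D cross-covariance exactly `rho` in expectation
#' (isotropic: the same correlation on each axis), and residues not
#' connected through any planted pair move independently.
#'
#' @param n_res1,n_res2 residue counts of protein 1 and 2.
#' @param pairs data.frame with columns `i` (protein-1 residue index),
#'   `j` (protein-2 residue index), `rho` in [-1, 1] and
#'   `equilibrium_distance_A`.
#' @param sigma_A per-axis wobble standard deviation (Angstrom, > 0).
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed; identical seeds give bit-identical trajectories.
#' @return object of class `cc_coupling_spec`.
#' @export
coupling_spec <- function(n_res1, n_res2, pairs, sigma_A = 0.5,
                          n_frames = 1000L, seed = 1L) {
  stopifnot(n_res1 >= 1, n_res2 >= 1, sigma_A > 0, n_frames >= 2)
  pairs <- as.data.frame(pairs)
  need <- c("i", "j", "rho", "equilibrium_distance_A")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns i, j, rho, equilibrium_distance_A")
  if (any(abs(pairs$rho) > 1)) stop("|rho| must be <= 1")
  if (any(pairs$i < 1 | pairs$i > n_res1) || any(pairs$j < 1 | pairs$j > n_res2))
    stop("pair indices out of range")
  if (anyDuplicated(pairs[, c("i", "j")])) stop("duplicate planted pair")
  structure(list(n_res1 = n_res1, n_res2 = n_res2, pairs = pairs,
                 sigma_A = sigma_A, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "cc_coupling_spec")
}

# union-find over integer nodes
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

# Partition nodes 1..(n1+n2) into connected components of the pair graph.
pair_components <- function(n1, n2, pairs) {
  n <- n1 + n2
  parent <- seq_len(n)
  for (k in seq_len(nrow(pairs))) {
    a <- uf_find(parent, as.integer(pairs$i[k]))
    b <- uf_find(parent, as.integer(n1 + pairs$j[k]))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), function(x) uf_find(parent, x), integer(1))
  match(roots, unique(roots))
}

# Factor-model loadings realizing the planted correlations. Each
# connected component of the rho != 0 graph gets one latent factor;
# residue loadings are sqrt(|rho|) with signs assigned by 2-colouring so
# that sign(a_i a_j) = sign(rho_ij). Mixed |rho| within one component or
# sign-inconsistent cycles cannot be realized this way and raise the
# infeasibility error.
coupling_loadings <- function(spec) {
  n1 <- spec$n_res1; n <- n1 + spec$n_res2
  active <- spec$pairs[spec$pairs$rho != 0, , drop = FALSE]
  comp <- pair_components(n1, spec$n_res2,
                          if (nrow(active)) active else spec$pairs[0, ])
  a <- numeric(n); s <- rep(1, n)
  if (nrow(active)) {
    for (cid in unique(comp[c(active$i, n1 + active$j)])) {
      edges <- active[comp[active$i] == cid, , drop = FALSE]
      rhos <- abs(edges$rho)
      if (diff(range(rhos)) > 1e-12)
        stop("infeasible correlation pattern: residues sharing a coupled ",
             "component must use a single |rho| (matrix not realizable)")
      members <- which(comp == cid)
      a[members] <- sqrt(rhos[1])
      # 2-colour signs over the edge graph
      colour <- rep(NA_integer_, n)
      queue <- members[1]; colour[queue] <- 1L
      while (length(queue)) {
        x <- queue[1]; queue <- queue[-1]
        for (k in seq_len(nrow(edges))) {
          u <- edges$i[k]; v <- n1 + edges$j[k]
          other <- if (u == x) v else if (v == x) u else next
          want <- if (edges$rho[k] > 0) colour[x] else -colour[x]
          if (is.na(colour[other])) {
            colour[other] <- want
            queue <- c(queue, other)
          } else if (colour[other] != want) {
            stop("infeasible correlation pattern: inconsistent signs around ",
                 "a coupling cycle (matrix not positive semidefinite)")
          }
        }
      }
      s[members] <- colour[members]
    }
  }
  list(a = a, s = s, comp = comp)
}

# Default interface layout: each component of the pair graph (all listed
# pairs, including rho = 0) is placed on a coarse grid with 60 A between
# component centers; protein-1 members sit on a tight 1.2 A sub-grid,
# protein-2 members on the same sub-grid displaced along x by the
# component's mean equilibrium distance. Disjoint pairs therefore sit at
# exactly their equilibrium distance; clustered pairs within ~0.7 A of it.
auto_interface_layout <- function(spec) {
  n1 <- spec$n_res1; n2 <- spec$n_res2; n <- n1 + n2
  comp <- pair_components(n1, n2, spec$pairs)
  coords <- matrix(0, n, 3)
  cids <- unique(comp)
  g <- ceiling(sqrt(length(cids)))
  for (ci in seq_along(cids)) {
    members <- which(comp == cids[ci])
    edges <- spec$pairs[comp[spec$pairs$i] == cids[ci], , drop = FALSE]
    d <- if (nrow(edges)) mean(edges$equilibrium_distance_A) else 0
    center <- c(0, 60 * ((ci - 1) %% g), 60 * ((ci - 1) %/% g))
    place <- function(idx, xoff) {
      k <- length(idx)
      gg <- ceiling(sqrt(k))
      off_y <- 1.2 * (((seq_len(k) - 1) %% gg) - (gg - 1) / 2)
      off_z <- 1.2 * (((seq_len(k) - 1) %/% gg) - (gg - 1) / 2)
      cbind(center[1] + xoff, center[2] + off_y, center[3] + off_z)
    }
    m1 <- members[members <= n1]; m2 <- members[members > n1]
    if (length(m1)) coords[m1, ] <- place(m1, 0)
    if (length(m2)) coords[m2, ] <- place(m2, d)
  }
  coords
}

#' Generate a coupled Gaussian bead trajectory
#'
#' Per-frame bead displacements are drawn from a multivariate Gaussian
#' realized through per-component latent factors: every planted pair has
#' cross-correlation `rho` on each axis (so the normalized 3D covariance
#' equals `rho` in expectation), and unrelated residues are independent.
#' Note that within one coupled component all cross pairs acquire the
#' component's correlation; use complete bipartite components when exact
#' planted-pair counts matter.
#'
#' @param spec a `cc_coupling_spec`.
#' @param layout optional (n_res1 + n_res2) x 3 matrix of equilibrium bead
#'   positions (protein-1 rows first); default places components on a
#'   coarse grid honoring the pair equilibrium distances, with everything
#'   else far apart (> 13 A).
#' @return a C-alpha-level `cc_trajectory` (protein 1 = chain A, protein 2
#'   = chain B) with the ground truth attached as attribute
#'   `"ground_truth"`.
#' @export
generate_coupled_trajectory <- function(spec, layout = NULL) {
  stopifnot(inherits(spec, "cc_coupling_spec"))
  n1 <- spec$n_res1; n2 <- spec$n_res2; n <- n1 + n2
  if (is.null(layout)) layout <- auto_interface_layout(spec)
  if (!is.matrix(layout) || nrow(layout) != n || ncol(layout) != 3)
    stop("layout must be a (n_res1 + n_res2) x 3 coordinate matrix")

  ld <- coupling_loadings(spec)
  noise_sd <- sqrt(pmax(0, 1 - ld$a^2))
  comps <- unique(ld$comp[ld$a > 0])

  set.seed(spec$seed)
  nf <- spec$n_frames
  xyz <- matrix(0, nf, 3 * n)
  for (axis in 1:3) {
    FF <- if (length(comps)) matrix(stats::rnorm(nf * length(comps)), nf) else NULL
    E <- matrix(stats::rnorm(nf * n), nf)
    disp <- sweep(E, 2, noise_sd, `*`)
    if (length(comps)) {
      fac_idx <- match(ld$comp, comps)
      load <- ld$s * ld$a
      for (r in which(ld$a > 0))
        disp[, r] <- disp[, r] + load[r] * FF[, fac_idx[r]]
    }
    disp <- spec$sigma_A * disp
    xyz[, seq(axis, 3 * n, by = 3)] <- sweep(disp, 2, layout[, axis], `+`)
  }

  atoms <- data.frame(
    atom_name = "CA", element = "C", residue_name = "ALA",
    residue_id = c(seq_len(n1), seq_len(n2)),
    chain_id = rep(c("A", "B"), c(n1, n2)),
    protein_tag = rep(c("protein1", "protein2"), c(n1, n2)),
    stringsAsFactors = FALSE)

  traj <- new_trajectory(xyz, atoms)
  dvec <- sqrt(rowSums((layout[spec$pairs$i, , drop = FALSE] -
                        layout[n1 + spec$pairs$j, , drop = FALSE])^2))
  gt <- spec$pairs
  gt$layout_distance_A <- dvec
  attr(traj, "ground_truth") <- list(pairs = gt, layout = layout, spec = spec)
  traj
}

# ---------------------------------------------------------------------------
# Toy all-atom residues. Idealized internal geometry (PDB v3 atom names,
# explicit polar hydrogens), side chain extended along +z with the
# criterion-bearing tip atoms near z = 3; not chemically accurate bond
# geometry, which the distance/angle classifiers do not require.

TOY_TEMPLATES <- list(
  LYS = rbind(
    N = c(-1.2, 0.8, 0), H = c(-1.2, 1.75, 0), CA = c(0, 0, 0),
    C = c(1.2, 0.8, 0), O = c(1.2, 2.0, 0),
    CB = c(0, 0, 1.0), CG = c(0, 0.4, 1.7), CD = c(0, 0, 2.3),
    CE = c(0, 0.4, 2.7), NZ = c(0, 0, 3.0), HZ1 = c(0, 0, 3.95),
    HZ2 = c(0.8, 0, 3.3), HZ3 = c(-0.8, 0, 3.3)),
  GLU = rbind(
    N = c(-1.2, 0.8, 0), H = c(-1.2, 1.75, 0), CA = c(0, 0, 0),
    C = c(1.2, 0.8, 0), O = c(1.2, 2.0, 0),
    CB = c(0, 0, 1.0), CG = c(0, 0.4, 1.8), CD = c(0, 0, 2.5),
    OE1 = c(0, 0.6, 3.0), OE2 = c(0, -0.6, 3.0)),
  SER = rbind(
    N = c(-1.2, 0.8, 0), H = c(-1.2, 1.75, 0), CA = c(0, 0, 0),
    C = c(1.2, 0.8, 0), O = c(1.2, 2.0, 0),
    CB = c(0, 0, 1.5), OG = c(0, 0, 3.0), HG = c(0, 0, 3.95)),
  ASN = rbind(
    N = c(-1.2, 0.8, 0), H = c(-1.2, 1.75, 0), CA = c(0, 0, 0),
    C = c(1.2, 0.8, 0), O = c(1.2, 2.0, 0),
    CB = c(0, 0, 1.0), CG = c(0, 0, 2.2), OD1 = c(0, 0, 3.0),
    ND2 = c(0, 1.1, 2.5), HD21 = c(0, 1.5, 3.3), HD22 = c(0, 1.9, 2.0)),
  LEU = rbind(
    N = c(-1.2, 0.8, 0), H = c(-1.2, 1.75, 0), CA = c(0, 0, 0),
    C = c(1.2, 0.8, 0), O = c(1.2, 2.0, 0),
    CB = c(0, 0, 1.0), CG = c(0, 0, 1.8),
    CD1 = c(0, 0.6, 2.6), CD2 = c(0, -0.6, 2.6)),
  VAL = rbind(
    N = c(-1.2, 0.8, 0), H = c(-1.2, 1.75, 0), CA = c(0, 0, 0),
    C = c(1.2, 0.8, 0), O = c(1.2, 2.0, 0),
    CB = c(0, 0, 1.4), CG1 = c(0, 0.6, 3.0), CG2 = c(0, -0.6, 3.0)),
  ARG = rbind(
    N = c(-1.2, 0.8, 0), H = c(-1.2, 1.75, 0), CA = c(0, 0, 0),
    C = c(1.2, 0.8, 0), O = c(1.2, 2.0, 0),
    CB = c(0, 0, 1.0), CG = c(0, 0, 1.6), CD = c(0, 0, 2.1),
    NE = c(0, 0, 2.4), HE = c(0, 0.9, 2.4), CZ = c(0, 0, 2.7),
    NH1 = c(0, 0.6, 3.0), NH2 = c(0, -0.6, 3.0),
    HH11 = c(0, 1.0, 3.6), HH12 = c(0, 1.4, 2.7),
    HH21 = c(0, -1.0, 3.6), HH22 = c(0, -1.4, 2.7)))

#' Toy residue template
#'
#' Idealized synthetic residue geometry (side chain along +z, tip atoms
#' near z = 3 A, explicit polar hydrogens) used by the all-atom fixture
#' generator and handy for constructing classifier test geometries.
#'
#' @param resname one of LYS, GLU, SER, ASN, LEU, VAL, ARG.
#' @return k x 3 coordinate matrix with atom-name rownames.
#' @export
toy_residue <- function(resname) {
  tpl <- TOY_TEMPLATES[[resname]]
  if (is.null(tpl)) stop(sprintf("no toy template for residue '%s'", resname))
  tpl
}

BACKBONE_NAMES <- c("N", "H", "CA", "C", "O")

# motif geometry: residue names, CA-CA separation, side-chain retraction
# that switches the criterion off, and the covariance sign to plant
MOTIF_TABLE <- list(
  salt_bridge = list(res1 = "LYS", res2 = "GLU", d_ca = 9, off = 4, sign = 1),
  hbond = list(res1 = "SER", res2 = "ASN", d_ca = 9, off = 2.5, sign = 1),
  hydrophobic = list(res1 = "LEU", res2 = "VAL", d_ca = 9, off = 6, sign = 1),
  same_charge_clash = list(res1 = "LYS", res2 = "ARG", d_ca = 12, off = 8,
                           sign = -1),
  hydrophobic_polar_clash = list(res1 = "LEU", res2 = "LYS", d_ca = 12,
                                 off = 8, sign = -1))

MOTIF_ITYPE <- c(salt_bridge = "salt_bridge", hbond = "hydrogen_bond",
                 hydrophobic = "hydrophobic",
                 same_charge_clash = "repulsion_same_charge",
                 hydrophobic_polar_clash = "repulsion_hydrophobic_polar")

#' Generate a toy all-atom interface with planted interaction motifs
#'
#' Builds one residue pair per requested motif (60 A apart from the
#' others), positioned so the motif's detection criterion is satisfied in
#' exactly `round(occupancy * n_frames)` frames (the leading frames) and
#' violated elsewhere; the toggle rigidly retracts the partner residue's
#' side chain while both C-alpha atoms stay in contact range. Each pair
#' additionally wobbles: attractive motifs with a common random
#' translation (planting strongly positive C-alpha correlation), clash
#' motifs with an anticorrelated in-plane push-pull (strongly negative
#' correlation that leaves the separation axis untouched), plus a small
#' independent per-residue jitter.
#'
#' @param motifs character vector from `salt_bridge`, `hbond`,
#'   `hydrophobic`, `same_charge_clash`, `hydrophobic_polar_clash`.
#' @param occupancy scalar or per-motif vector in [0, 1].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param wobble_sigma_A common-motion standard deviation per axis.
#' @param jitter_sigma_A independent rigid per-residue jitter.
#' @return an all-atom `cc_trajectory` (chain A / chain B) with attribute
#'   `"ground_truth"`: a data.frame of motif, interaction type, residue
#'   labels, occupancy and the per-frame on/off pattern (list column).
#' @export
generate_allatom_interface <- function(motifs, occupancy = 1, n_frames = 100L,
                                       seed = 1L, wobble_sigma_A = 0.3,
                                       jitter_sigma_A = 0.02) {
  motifs <- as.character(motifs)
  bad <- setdiff(motifs, names(MOTIF_TABLE))
  if (length(bad)) stop(sprintf("unknown motif(s): %s", paste(bad, collapse = ", ")))
  occupancy <- rep_len(occupancy, length(motifs))
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must be in [0, 1]")
  n_frames <- as.integer(n_frames)

  set.seed(seed)
  atom_rows <- list()
  coord_blocks <- list()
  gt <- list()
  for (k in seq_along(motifs)) {
    mt <- MOTIF_TABLE[[motifs[k]]]
    t1 <- toy_residue(mt$res1)
    t2 <- toy_residue(mt$res2)
    origin <- c(0, 60 * (k - 1), 0)
    g1 <- sweep(t1, 2, origin, `+`)
    # partner: rotate pi about x (side chain points -z), CA at z = d_ca
    g2 <- cbind(t2[, 1], -t2[, 2], mt$d_ca - t2[, 3])
    g2 <- sweep(g2, 2, origin, `+`)
    sidechain2 <- !(rownames(t2) %in% BACKBONE_NAMES)

    n_on <- round(occupancy[k] * n_frames)
    on <- seq_len(n_frames) <= n_on

    wob <- matrix(stats::rnorm(n_frames * 3, sd = wobble_sigma_A), n_frames)
    if (mt$sign < 0) wob[, 3] <- 0   # keep the separation axis quiet
    j1 <- matrix(stats::rnorm(n_frames * 3, sd = jitter_sigma_A), n_frames)
    j2 <- matrix(stats::rnorm(n_frames * 3, sd = jitter_sigma_A), n_frames)

    n1 <- nrow(g1); n2 <- nrow(g2)
    blk <- matrix(0, n_frames, 3 * (n1 + n2))
    for (axis in 1:3) {
      d1 <- wob[, axis] + j1[, axis]
      d2 <- mt$sign * wob[, axis] + j2[, axis]
      blk[, seq(axis, 3 * n1, 3)] <-
        outer(d1, g1[, axis], `+`)
      off_shift <- if (axis == 3) ifelse(on, 0, mt$off) else 0
      base2 <- outer(d2, g2[, axis], `+`)
      base2[, sidechain2] <- base2[, sidechain2] + off_shift
      blk[, 3 * n1 + seq(axis, 3 * n2, 3)] <- base2
    }

    atom_rows[[k]] <- data.frame(
      atom_name = c(rownames(t1), rownames(t2)),
      element = guess_element(c(rownames(t1), rownames(t2))),
      residue_name = rep(c(mt$res1, mt$res2), c(n1, n2)),
      residue_id = k,
      chain_id = rep(c("A", "B"), c(n1, n2)),
      protein_tag = rep(c("protein1", "protein2"), c(n1, n2)),
      stringsAsFactors = FALSE)
    coord_blocks[[k]] <- blk
    gt[[k]] <- data.frame(
      motif = motifs[k], itype = unname(MOTIF_ITYPE[motifs[k]]),
      res_i = sprintf("A:%d:%s", k, mt$res1),
      res_j = sprintf("B:%d:%s", k, mt$res2),
      occupancy = occupancy[k], n_on = n_on, sign = mt$sign,
      stringsAsFactors = FALSE)
    gt[[k]]$on <- list(on)
  }

  atoms <- do.call(rbind, atom_rows)
  rownames(atoms) <- NULL
  traj <- new_trajectory(do.call(cbind, coord_blocks), atoms)
  attr(traj, "ground_truth") <- do.call(rbind, gt)
  traj
}
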