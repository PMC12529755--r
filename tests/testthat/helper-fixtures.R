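# Shared fixture builders. Everything is generated in code; no data files.

# Two single-bead proteins with prescribed per-frame displacement series
# (n x 3 matrices), protein 2 offset by base_dist along x.
two_bead_traj <- function(disp1, disp2, base_dist = 9) {
  stopifnot(nrow(disp1) == nrow(disp2))
  n <- nrow(disp1)
  xyz <- cbind(disp1, sweep(disp2, 2, c(base_dist, 0, 0), `+`))
  atoms <- data.frame(
    atom_name = "CA", element = "C", residue_name = "ALA",
    residue_id = c(1L, 1L), chain_id = c("A", "B"),
    protein_tag = c("protein1", "protein2"), stringsAsFactors = FALSE)
  covcontact:::new_trajectory(xyz, atoms)
}

# A deterministic zero-mean displacement series (no RNG needed).
sinusoid_series <- function(n = 100) {
  t <- seq_len(n)
  d <- sin(2 * pi * t / 17)
  cbind(d - mean(d), 0 * t, 0 * t)
}

# Random bead trajectory: n1 x n2 beads scattered on a grid, iid Gaussian
# wobble, for filter/prefilter oracle fixtures.
random_bead_traj <- function(n1, n2, n_frames = 40, sigma = 0.5, seed = 1,
                             spread = 6) {
  set.seed(seed)
  n <- n1 + n2
  base <- cbind(runif(n, 0, spread * sqrt(n)), runif(n, 0, spread * sqrt(n)),
                runif(n, 0, 6))
  xyz <- matrix(rnorm(n_frames * 3 * n, sd = sigma), n_frames)
  xyz <- xyz + matrix(rep(t(base), each = n_frames), n_frames)
  atoms <- data.frame(
    atom_name = "CA", element = "C", residue_name = "ALA",
    residue_id = c(seq_len(n1), seq_len(n2)),
    chain_id = rep(c("A", "B"), c(n1, n2)),
    protein_tag = rep(c("protein1", "protein2"), c(n1, n2)),
    stringsAsFactors = FALSE)
  covcontact:::new_trajectory(xyz, atoms)
}

# Minimal residue view for the single-frame classifiers.
res_view <- function(resname, ...) {
  atoms <- list(...)
  coords <- do.call(rbind, atoms)
  rownames(coords) <- names(atoms)
  list(resname = resname, atom_names = names(atoms), coords = coords)
}

# The 20 x 25 interface with 80 planted coupled-and-close pairs among 500:
# four complete-bipartite 5 x 4 clusters (three positive at 9 A, one
# negative at 12 A); nine protein-2 residues left unpaired and far away.
planted_interface_spec <- function(n_frames = 5000, seed = 42) {
  pairs <- do.call(rbind, lapply(1:4, function(cl) {
    expand.grid(i = (cl - 1) * 5 + 1:5, j = (cl - 1) * 4 + 1:4)
  }))
  pairs$rho <- rep(c(0.5, 0.5, 0.5, -0.5), each = 20)
  pairs$equilibrium_distance_A <- rep(c(9, 9, 9, 12), each = 20)
  coupling_spec(20, 25, pairs, sigma_A = 0.5, n_frames = n_frames,
                seed = seed)
}

ALL_MOTIFS <- c("salt_bridge", "hbond", "hydrophobic", "same_charge_clash",
                "hydrophobic_polar_clash")
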