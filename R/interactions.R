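# Step IIIA: per-frame geometric classification of close-contact residue
# pairs into attractive (salt bridge, hydrogen bond, hydrophobic) and
# repulsive (same-charge, hydrophobic-polar) interaction types, and the
# percentage occupancy of each across the trajectory.

INTERACTION_TYPES <- c("salt_bridge", "hydrogen_bond", "hydrophobic",
                       "repulsion_same_charge", "repulsion_hydrophobic_polar")
ATTRACTIVE_TYPES <- c("salt_bridge", "hydrogen_bond", "hydrophobic")
REPULSIVE_TYPES <- c("repulsion_same_charge", "repulsion_hydrophobic_polar")

#' Default interaction distance/angle cutoffs
#'
#' Salt bridge: basic side-chain N to acidic side-chain O within 6 A.
#' Hydrogen bond: donor-acceptor distance <= 3.5 A and deviation of the
#' D-H...A arrangement from linearity <= 30 degrees. Hydrophobic:
#' side-chain carbon pair within 8 A. Repulsion: like-charge atom pairs,
#' or aliphatic-hydrophobic side-chain carbons against charged/polar
#' side-chain heteroatoms, within 12 A.
#'
#' @param salt_bridge_A,hbond_dist_A,hbond_angle_deg,hydrophobic_A,repulsion_A
#'   override individual cutoffs.
#' @return named list of cutoffs.
#' @export
interaction_cutoffs <- function(salt_bridge_A = 6, hbond_dist_A = 3.5,
                                hbond_angle_deg = 30, hydrophobic_A = 8,
                                repulsion_A = 12) {
  stopifnot(salt_bridge_A > 0, hbond_dist_A > 0, hbond_angle_deg > 0,
            hydrophobic_A > 0, repulsion_A > 0)
  list(salt_bridge_A = salt_bridge_A, hbond_dist_A = hbond_dist_A,
       hbond_angle_deg = hbond_angle_deg, hydrophobic_A = hydrophobic_A,
       repulsion_A = repulsion_A)
}

#' Extract one residue from one trajectory frame
#'
#' @param traj a `cc_trajectory`.
#' @param frame frame index.
#' @param label residue label "chain:resid:resname".
#' @return a residue view: list with `resname`, `atom_names`, `coords`
#'   (k x 3, rows named by atom).
#' @export
residue_frame <- function(traj, frame, label) {
  idx <- which(atom_residue_label(traj$atoms) == label)
  if (!length(idx)) stop(sprintf("residue '%s' not found in trajectory", label))
  coords <- frame_coords(traj, frame)[idx, , drop = FALSE]
  rownames(coords) <- traj$atoms$atom_name[idx]
  list(resname = traj$atoms$residue_name[idx[1]],
       atom_names = traj$atoms$atom_name[idx],
       coords = coords)
}

min_cross_dist <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(Inf)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

res_atoms <- function(res, names_wanted) {
  res$coords[res$atom_names %in% names_wanted, , drop = FALSE]
}

#' Detect a salt bridge in one frame
#'
#' True iff one residue is basic and the other acidic and any basic
#' side-chain nitrogen lies within `cutoff_A` of an acidic side-chain
#' oxygen. Pairs without a basic/acidic partnering return `FALSE`; listed
#' side-chain atoms missing from the coordinates (truncated side chains)
#' skip the pair with a warning.
#'
#' @param res_i,res_j residue views from [residue_frame()].
#' @param cutoff_A distance cutoff (default 6 A).
#' @param chem chemistry table from [residue_chemistry()].
#' @return logical.
#' @export
detect_salt_bridge <- function(res_i, res_j, cutoff_A = 6,
                               chem = residue_chemistry()) {
  for (ord in list(c(1, 2), c(2, 1))) {
    rb <- list(res_i, res_j)[[ord[1]]]
    ra <- list(res_i, res_j)[[ord[2]]]
    bn <- chem[[rb$resname]]$basic_nitrogens
    ao <- chem[[ra$resname]]$acidic_oxygens
    if (!length(bn) || !length(ao)) next
    B <- res_atoms(rb, bn); A <- res_atoms(ra, ao)
    if (!nrow(B) || !nrow(A)) {
      warning(sprintf("salt bridge %s/%s: named side-chain atoms missing; pair skipped",
                      rb$resname, ra$resname))
      return(FALSE)
    }
    if (min_cross_dist(B, A) <= cutoff_A) return(TRUE)
  }
  FALSE
}

# deviation from linearity of D-H...A in degrees: 180 - angle at H
hbond_deviation <- function(D, H, A) {
  u <- D - H; v <- A - H
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Detect a hydrogen bond in one frame
#'
#' True iff some donor heavy atom D of either residue has an acceptor A
#' on the other residue with `d(D, A) <= dist_cutoff_A` and a donor
#' hydrogen for which the D-H...A arrangement deviates from linearity by
#' at most `angle_cutoff_deg`. Donors whose hydrogens are absent from the
#' topology are skipped with a warning.
#'
#' @inheritParams detect_salt_bridge
#' @param dist_cutoff_A donor-acceptor heavy-atom cutoff (default 3.5 A).
#' @param angle_cutoff_deg maximum deviation from linearity (default 30).
#' @return logical.
#' @export
detect_hbond <- function(res_i, res_j, dist_cutoff_A = 3.5,
                         angle_cutoff_deg = 30, chem = residue_chemistry()) {
  for (ord in list(c(1, 2), c(2, 1))) {
    rd <- list(res_i, res_j)[[ord[1]]]
    ra <- list(res_i, res_j)[[ord[2]]]
    donors <- chem[[rd$resname]]$hbond_donors
    accs <- res_atoms(ra, chem[[ra$resname]]$hbond_acceptors)
    if (!length(donors) || !nrow(accs)) next
    for (dheavy in names(donors)) {
      if (!dheavy %in% rd$atom_names) next
      D <- rd$coords[match(dheavy, rd$atom_names), ]
      H <- res_atoms(rd, donors[[dheavy]])
      if (!nrow(H)) {
        warning(sprintf("hydrogen bond: donor %s of %s has no hydrogens in topology; skipped",
                        dheavy, rd$resname))
        next
      }
      for (ai in seq_len(nrow(accs))) {
        A <- accs[ai, ]
        if (sqrt(sum((D - A)^2)) > dist_cutoff_A) next
        devs <- apply(H, 1L, function(h) hbond_deviation(D, h, A))
        if (min(devs) <= angle_cutoff_deg) return(TRUE)
      }
    }
  }
  FALSE
}

#' Detect a hydrophobic contact in one frame
#'
#' True iff any side-chain carbon of one residue lies within `cutoff_A`
#' of a side-chain carbon of the other. Glycine (no side-chain carbon)
#' yields `FALSE`.
#'
#' @inheritParams detect_salt_bridge
#' @param cutoff_A distance cutoff (default 8 A).
#' @return logical.
#' @export
detect_hydrophobic <- function(res_i, res_j, cutoff_A = 8,
                               chem = residue_chemistry()) {
  Ci <- res_atoms(res_i, chem[[res_i$resname]]$sidechain_carbons)
  Cj <- res_atoms(res_j, chem[[res_j$resname]]$sidechain_carbons)
  if (!nrow(Ci) || !nrow(Cj)) return(FALSE)
  min_cross_dist(Ci, Cj) <= cutoff_A
}

#' Detect a repulsive interaction in one frame
#'
#' `"same_charge"` if two basic side-chain nitrogens or two acidic
#' side-chain oxygens are within `cutoff_A`; otherwise
#' `"hydrophobic_polar"` if one residue is aliphatic hydrophobic and the
#' other charged or polar, with a side-chain carbon within `cutoff_A` of
#' a charged/polar side-chain heteroatom; otherwise `"none"`.
#'
#' @inheritParams detect_salt_bridge
#' @param cutoff_A distance cutoff (default 12 A).
#' @return one of `"none"`, `"same_charge"`, `"hydrophobic_polar"`.
#' @export
detect_repulsion <- function(res_i, res_j, cutoff_A = 12,
                             chem = residue_chemistry()) {
  ci <- chem[[res_i$resname]]; cj <- chem[[res_j$resname]]
  Bi <- res_atoms(res_i, ci$basic_nitrogens)
  Bj <- res_atoms(res_j, cj$basic_nitrogens)
  Ai <- res_atoms(res_i, ci$acidic_oxygens)
  Aj <- res_atoms(res_j, cj$acidic_oxygens)
  if (min_cross_dist(Bi, Bj) <= cutoff_A || min_cross_dist(Ai, Aj) <= cutoff_A)
    return("same_charge")
  for (ord in list(list(res_i, res_j), list(res_j, res_i))) {
    rh <- ord[[1]]; rp <- ord[[2]]
    if (!is_aliphatic_hydrophobic(rh$resname, chem) ||
        !is_charged_or_polar(rp$resname, chem)) next
    Ch <- res_atoms(rh, chem[[rh$resname]]$sidechain_carbons)
    P <- res_atoms(rp, chem[[rp$resname]]$polar_anchor)
    if (min_cross_dist(Ch, P) <= cutoff_A) return("hydrophobic_polar")
  }
  "none"
}

# ---------------------------------------------------------------------------
# Vectorized per-pair evaluation across all frames. The same geometric
# rules as the single-frame detectors, applied column-wise on the
# frames x 3N coordinate matrix; a test asserts frame-by-frame agreement
# with the detectors above.

# squared distance series between atom (global index) a and b
dist2_series <- function(xyz, a, b) {
  (xyz[, 3 * a - 2] - xyz[, 3 * b - 2])^2 +
    (xyz[, 3 * a - 1] - xyz[, 3 * b - 1])^2 +
    (xyz[, 3 * a] - xyz[, 3 * b])^2
}

# per-frame minimum distance over the cross product of two atom index sets
min_dist2_over_pairs <- function(xyz, ia, ib) {
  if (!length(ia) || !length(ib))
    return(rep(Inf, nrow(xyz)))
  best <- rep(Inf, nrow(xyz))
  for (a in ia) for (b in ib) best <- pmin(best, dist2_series(xyz, a, b))
  best
}

# Per-pair evaluation context: atom indices of both residues, resolved once.
pair_context <- function(traj, label_i, label_j) {
  labs <- atom_residue_label(traj$atoms)
  ii <- which(labs == label_i)
  jj <- which(labs == label_j)
  if (!length(ii)) stop(sprintf("residue '%s' not found in topology", label_i))
  if (!length(jj)) stop(sprintf("residue '%s' not found in topology", label_j))
  list(
    i = ii, j = jj,
    resname_i = traj$atoms$residue_name[ii[1]],
    resname_j = traj$atoms$residue_name[jj[1]],
    names_i = traj$atoms$atom_name[ii],
    names_j = traj$atoms$atom_name[jj])
}

named_idx <- function(ctx, side, wanted) {
  if (side == "i") ctx$i[ctx$names_i %in% wanted] else ctx$j[ctx$names_j %in% wanted]
}

series_salt_bridge <- function(xyz, ctx, cutoff_A, chem) {
  out <- rep(FALSE, nrow(xyz))
  for (ord in list(c("i", "j"), c("j", "i"))) {
    rn_b <- if (ord[1] == "i") ctx$resname_i else ctx$resname_j
    rn_a <- if (ord[2] == "i") ctx$resname_i else ctx$resname_j
    bn <- chem[[rn_b]]$basic_nitrogens
    ao <- chem[[rn_a]]$acidic_oxygens
    if (!length(bn) || !length(ao)) next
    ib <- named_idx(ctx, ord[1], bn)
    ia <- named_idx(ctx, ord[2], ao)
    if (!length(ib) || !length(ia)) {
      warning(sprintf("salt bridge %s/%s: named side-chain atoms missing; pair skipped",
                      rn_b, rn_a))
      return(out)
    }
    out <- out | (min_dist2_over_pairs(xyz, ib, ia) <= cutoff_A^2)
  }
  out
}

series_hbond <- function(xyz, ctx, dist_cutoff_A, angle_cutoff_deg, chem) {
  out <- rep(FALSE, nrow(xyz))
  cosmin <- cos((180 - angle_cutoff_deg) * pi / 180)  # at H, angle >= 150 deg
  for (ord in list(c("i", "j"), c("j", "i"))) {
    rn_d <- if (ord[1] == "i") ctx$resname_i else ctx$resname_j
    rn_a <- if (ord[2] == "i") ctx$resname_i else ctx$resname_j
    donors <- chem[[rn_d]]$hbond_donors
    iacc <- named_idx(ctx, ord[2], chem[[rn_a]]$hbond_acceptors)
    if (!length(donors) || !length(iacc)) next
    for (dheavy in names(donors)) {
      idh <- named_idx(ctx, ord[1], dheavy)
      if (!length(idh)) next
      ihyd <- named_idx(ctx, ord[1], donors[[dheavy]])
      if (!length(ihyd)) {
        warning(sprintf("hydrogen bond: donor %s of %s has no hydrogens in topology; skipped",
                        dheavy, rn_d))
        next
      }
      for (a in iacc) {
        dda <- dist2_series(xyz, idh, a)
        close <- dda <= dist_cutoff_A^2
        if (!any(close)) next
        angok <- rep(FALSE, nrow(xyz))
        for (h in ihyd) {
          ux <- xyz[, 3 * idh - 2] - xyz[, 3 * h - 2]
          uy <- xyz[, 3 * idh - 1] - xyz[, 3 * h - 1]
          uz <- xyz[, 3 * idh] - xyz[, 3 * h]
          vx <- xyz[, 3 * a - 2] - xyz[, 3 * h - 2]
          vy <- xyz[, 3 * a - 1] - xyz[, 3 * h - 1]
          vz <- xyz[, 3 * a] - xyz[, 3 * h]
          cosang <- (ux * vx + uy * vy + uz * vz) /
            sqrt((ux^2 + uy^2 + uz^2) * (vx^2 + vy^2 + vz^2))
          # deviation <= cutoff  <=>  angle at H >= 180 - cutoff
          angok <- angok | (cosang <= cosmin)
        }
        out <- out | (close & angok)
      }
    }
  }
  out
}

series_hydrophobic <- function(xyz, ctx, cutoff_A, chem) {
  ic <- named_idx(ctx, "i", chem[[ctx$resname_i]]$sidechain_carbons)
  jc <- named_idx(ctx, "j", chem[[ctx$resname_j]]$sidechain_carbons)
  min_dist2_over_pairs(xyz, ic, jc) <= cutoff_A^2
}

series_repulsion_same_charge <- function(xyz, ctx, cutoff_A, chem) {
  bi <- named_idx(ctx, "i", chem[[ctx$resname_i]]$basic_nitrogens)
  bj <- named_idx(ctx, "j", chem[[ctx$resname_j]]$basic_nitrogens)
  ai <- named_idx(ctx, "i", chem[[ctx$resname_i]]$acidic_oxygens)
  aj <- named_idx(ctx, "j", chem[[ctx$resname_j]]$acidic_oxygens)
  (min_dist2_over_pairs(xyz, bi, bj) <= cutoff_A^2) |
    (min_dist2_over_pairs(xyz, ai, aj) <= cutoff_A^2)
}

series_repulsion_hp <- function(xyz, ctx, cutoff_A, chem) {
  out <- rep(FALSE, nrow(xyz))
  for (ord in list(c("i", "j"), c("j", "i"))) {
    rn_h <- if (ord[1] == "i") ctx$resname_i else ctx$resname_j
    rn_p <- if (ord[2] == "i") ctx$resname_i else ctx$resname_j
    if (!is_aliphatic_hydrophobic(rn_h, chem) ||
        !is_charged_or_polar(rn_p, chem)) next
    ih <- named_idx(ctx, ord[1], chem[[rn_h]]$sidechain_carbons)
    ip <- named_idx(ctx, ord[2], chem[[rn_p]]$polar_anchor)
    out <- out | (min_dist2_over_pairs(xyz, ih, ip) <= cutoff_A^2)
  }
  out
}

evaluate_type_series <- function(xyz, ctx, itype, cutoffs, chem) {
  switch(itype,
    salt_bridge = series_salt_bridge(xyz, ctx, cutoffs$salt_bridge_A, chem),
    hydrogen_bond = series_hbond(xyz, ctx, cutoffs$hbond_dist_A,
                                 cutoffs$hbond_angle_deg, chem),
    hydrophobic = series_hydrophobic(xyz, ctx, cutoffs$hydrophobic_A, chem),
    repulsion_same_charge = series_repulsion_same_charge(
      xyz, ctx, cutoffs$repulsion_A, chem),
    repulsion_hydrophobic_polar = series_repulsion_hp(
      xyz, ctx, cutoffs$repulsion_A, chem),
    stop(sprintf("unknown interaction type '%s'", itype)))
}

# residue labels per protein, in topology order
protein_residue_labels <- function(traj) {
  at <- traj$atoms
  labs <- atom_residue_label(at)
  list(p1 = unique(labs[at$protein_tag == "protein1"]),
       p2 = unique(labs[at$protein_tag == "protein2"]))
}

build_frequency_map <- function(records, row_labels, col_labels) {
  per_type <- lapply(stats::setNames(INTERACTION_TYPES, INTERACTION_TYPES),
                     function(t) {
    m <- matrix(0, length(row_labels), length(col_labels),
                dimnames = list(row_labels, col_labels))
    sub <- records[records$itype == t & records$frequency_pct > 0, , drop = FALSE]
    if (nrow(sub)) m[cbind(match(sub$res_i, row_labels),
                           match(sub$res_j, col_labels))] <- sub$frequency_pct
    m
  })
  combined <- Reduce(pmax, per_type)
  structure(list(per_type = per_type, combined = combined,
                 row_labels = row_labels, col_labels = col_labels),
            class = "cc_frequency_map")
}

#' @export
print.cc_frequency_map <- function(x, ...) {
  cat(sprintf("<cc_frequency_map> %d x %d residues, %d nonzero combined entries\n",
              nrow(x$combined), ncol(x$combined), sum(x$combined > 0)))
  invisible(x)
}

# shared engine behind compute_frequencies and brute_force_scan
evaluate_pairs <- function(traj, pair_table, cutoffs, chem, stride) {
  frames <- seq(1L, traj$n_frames, by = stride)
  xyz <- traj$xyz[frames, , drop = FALSE]
  records <- list()
  per_frame <- list()
  for (k in seq_len(nrow(pair_table))) {
    ctx <- pair_context(traj, pair_table$res_i[k], pair_table$res_j[k])
    for (itype in strsplit(pair_table$types[k], ",", fixed = TRUE)[[1]]) {
      series <- evaluate_type_series(xyz, ctx, itype, cutoffs, chem)
      key <- paste(pair_table$res_i[k], pair_table$res_j[k], itype, sep = "|")
      per_frame[[key]] <- series
      records[[key]] <- data.frame(
        res_i = pair_table$res_i[k], res_j = pair_table$res_j[k],
        itype = itype, C = pair_table$C[k],
        n_true = sum(series), n_frames = length(series),
        frequency_pct = 100 * sum(series) / length(series),
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(records)) do.call(rbind, c(records, make.row.names = FALSE))
             else data.frame(res_i = character(0), res_j = character(0),
                             itype = character(0), C = numeric(0),
                             n_true = integer(0), n_frames = integer(0),
                             frequency_pct = numeric(0))
  list(records = records, per_frame = per_frame, frames = frames)
}

#' Interaction frequencies for close-contact pairs
#'
#' Evaluates the applicable interaction classifiers on every frame for
#' each close-contact pair and reports percentage occupancies. By default
#' attractive types are evaluated for positively correlated pairs and
#' repulsive types for negatively correlated pairs, following the sign of
#' the close-contact covariance; `all_types = TRUE` cross-evaluates every
#' type (mismatched detections are kept, with a warning).
#'
#' @param traj the trajectory to evaluate on (typically all-atom, with
#'   hydrogens for hydrogen-bond detection).
#' @param pairs pair data.frame from [enumerate_contact_pairs()]
#'   (columns `res_i`, `res_j`, `C`).
#' @param chem chemistry table.
#' @param cutoffs cutoff list from [interaction_cutoffs()].
#' @param all_types evaluate every type regardless of correlation sign.
#' @param stride evaluate every `stride`-th frame; frequencies are defined
#'   over the evaluated frames.
#' @return list with `records` (one row per pair and type: occupancy
#'   percentage and counts), `map` (a `cc_frequency_map`: per-type and
#'   combined matrices) and `per_frame` (named logical series).
#' @export
compute_frequencies <- function(traj, pairs, chem = residue_chemistry(),
                                cutoffs = interaction_cutoffs(),
                                all_types = FALSE, stride = 1L) {
  labs <- protein_residue_labels(traj)
  if (nrow(pairs)) {
    types <- if (all_types) {
      rep(paste(INTERACTION_TYPES, collapse = ","), nrow(pairs))
    } else {
      ifelse(pairs$C > 0, paste(ATTRACTIVE_TYPES, collapse = ","),
             paste(REPULSIVE_TYPES, collapse = ","))
    }
    pt <- data.frame(res_i = pairs$res_i, res_j = pairs$res_j, C = pairs$C,
                     types = types, stringsAsFactors = FALSE)
  } else {
    pt <- data.frame(res_i = character(0), res_j = character(0),
                     C = numeric(0), types = character(0))
  }
  ev <- evaluate_pairs(traj, pt, cutoffs, chem, stride)
  r <- ev$records
  if (all_types && nrow(r)) {
    mism <- (r$itype %in% ATTRACTIVE_TYPES & r$C < 0 & r$frequency_pct > 0) |
            (r$itype %in% REPULSIVE_TYPES & r$C > 0 & r$frequency_pct > 0)
    if (any(mism))
      warning(sprintf("%d detection(s) with type opposite to the correlation sign (kept)",
                      sum(mism)))
  }
  list(records = r, map = build_frequency_map(r, labs$p1, labs$p2),
       per_frame = ev$per_frame)
}

#' Exhaustive brute-force interaction scan
#'
#' Applies every interaction classifier to every interprotein residue
#' pair on every frame, with no covariance filtering. Quadratic in
#' interface size; intended for small systems and as the correctness
#' oracle for the filtered workflow.
#'
#' @inheritParams compute_frequencies
#' @return same structure as [compute_frequencies()] (records carry
#'   `C = NA`).
#' @export
brute_force_scan <- function(traj, chem = residue_chemistry(),
                             cutoffs = interaction_cutoffs(), stride = 1L) {
  labs <- protein_residue_labels(traj)
  if (!length(labs$p1) || !length(labs$p2)) {
    r <- data.frame(res_i = character(0), res_j = character(0),
                    itype = character(0), C = numeric(0),
                    n_true = integer(0), n_frames = integer(0),
                    frequency_pct = numeric(0))
    return(list(records = r, map = build_frequency_map(r, labs$p1, labs$p2),
                per_frame = list()))
  }
  grid <- expand.grid(res_i = labs$p1, res_j = labs$p2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pt <- data.frame(grid, C = NA_real_,
                   types = paste(INTERACTION_TYPES, collapse = ","),
                   stringsAsFactors = FALSE)
  ev <- evaluate_pairs(traj, pt, cutoffs, chem, stride)
  list(records = ev$records,
       map = build_frequency_map(ev$records, labs$p1, labs$p2),
       per_frame = ev$per_frame)
}
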