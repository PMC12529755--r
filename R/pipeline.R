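# End-to-end orchestration: covariance -> close-contact filter ->
# interaction frequencies, with labeled exports and a run manifest.

#' Build a validated pipeline configuration
#'
#' Collects the file paths, selections and all tunable cutoffs of the
#' three-step workflow. Defaults are the workflow's standard parameters:
#' contact cutoffs 11/13 A, significance thresholds -0.08/0.1, salt
#' bridge 6 A, hydrogen bond 3.5 A / 30 deg, hydrophobic 8 A,
#' repulsion 12 A.
#'
#' @param topology_path PDB topology (multi-model PDB doubles as frames).
#' @param coords_path optional DCD / multi-model PDB coordinate file.
#' @param selection1,selection2 the two protein selections.
#' @param representation covariance representation (default `"calpha"`).
#' @param superpose remove global rigid-body motion first (default TRUE).
#' @param pos_cutoff_A,neg_cutoff_A close-contact cutoffs.
#' @param neg_thresh,pos_thresh significance thresholds on normalized C.
#' @param cutoffs interaction cutoffs from [interaction_cutoffs()].
#' @param prefilter_cutoff_A optional static-structure prefilter distance;
#'   `NULL` computes the full matrix.
#' @param all_types cross-evaluate every interaction type.
#' @param stride frame stride for interaction frequencies.
#' @param out_dir output directory.
#' @return a `cc_run_config` list.
#' @export
run_config <- function(topology_path = NULL, coords_path = NULL,
                       selection1 = "chain A", selection2 = "chain B",
                       representation = "calpha", superpose = TRUE,
                       pos_cutoff_A = 11, neg_cutoff_A = 13,
                       neg_thresh = -0.08, pos_thresh = 0.1,
                       cutoffs = interaction_cutoffs(),
                       prefilter_cutoff_A = NULL,
                       all_types = FALSE, stride = 1L,
                       out_dir = "covcontact_out") {
  stopifnot(pos_cutoff_A > 0, neg_cutoff_A > 0, stride >= 1)
  if (!is.null(prefilter_cutoff_A) && prefilter_cutoff_A <= 0)
    stop("prefilter_cutoff_A must be > 0")
  structure(list(
    topology_path = topology_path, coords_path = coords_path,
    selection1 = selection1, selection2 = selection2,
    representation = representation, superpose = superpose,
    pos_cutoff_A = pos_cutoff_A, neg_cutoff_A = neg_cutoff_A,
    neg_thresh = neg_thresh, pos_thresh = pos_thresh,
    cutoffs = cutoffs, prefilter_cutoff_A = prefilter_cutoff_A,
    all_types = all_types, stride = as.integer(stride),
    out_dir = out_dir), class = "cc_run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full covariance-to-frequencies workflow
#'
#' Loads the trajectory, computes the normalized interprotein covariance
#' on the chosen representation (optionally after a static-structure
#' prefilter), applies the sign-dependent close-contact filter,
#' classifies the surviving pairs on every frame, and writes the labeled
#' covariance matrix, close-contact matrix, pair list, per-type and
#' combined frequency maps, and a run manifest echoing every parameter.
#'
#' @param config a `cc_run_config`.
#' @param traj optionally, an in-memory `cc_trajectory` to analyse
#'   instead of reading the configured files.
#' @return invisibly, a list with the intermediate objects (`trajectory`,
#'   `covariance`, `close_contact`, `pairs`, `frequencies`) and the
#'   written `paths`.
#' @export
run_pipeline <- function(config, traj = NULL) {
  stopifnot(inherits(config, "cc_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(traj)) {
    if (is.null(config$topology_path))
      stop("[trajectory_io] no topology path configured and no trajectory supplied")
    traj <- stage("trajectory_io", load_trajectory(
      config$topology_path, config$coords_path,
      config$selection1, config$selection2))
  }
  rep_traj <- stage("representation",
                    select_representation(traj, config$representation))

  mask <- NULL
  if (!is.null(config$prefilter_cutoff_A)) {
    avg0 <- stage("prefilter", compute_average_structure(
      rep_traj, superpose = config$superpose))
    mask <- build_prefilter_mask(avg0, config$prefilter_cutoff_A)
  }
  raw <- stage("covariance", compute_covariance(
    rep_traj, mask = mask, superpose = config$superpose))
  ncov <- stage("covariance", normalize_covariance(raw))
  ccm <- stage("contact_filter", apply_close_contact_filter(
    ncov, pos_cutoff_A = config$pos_cutoff_A,
    neg_cutoff_A = config$neg_cutoff_A))
  pairs <- enumerate_contact_pairs(ccm)
  freq <- stage("interaction_analysis", compute_frequencies(
    traj, pairs, cutoffs = config$cutoffs,
    all_types = config$all_types, stride = config$stride))

  paths <- list(
    covariance = file.path(config$out_dir, "covariance_normalized.csv"),
    close_contact = file.path(config$out_dir, "close_contact.csv"),
    pairs = file.path(config$out_dir, "contact_pairs.tsv"),
    combined = file.path(config$out_dir, "frequency_combined.csv"),
    manifest = file.path(config$out_dir, "manifest.txt"))
  write_matrix_csv(ncov$values, paths$covariance)
  write_matrix_csv(ccm$values, paths$close_contact)
  write_pairs_tsv(pairs, paths$pairs)
  write_matrix_csv(freq$map$combined, paths$combined)
  for (t in INTERACTION_TYPES) {
    p <- file.path(config$out_dir, sprintf("frequency_%s.csv", t))
    write_matrix_csv(freq$map$per_type[[t]], p)
    paths[[paste0("freq_", t)]] <- p
  }
  rec_path <- file.path(config$out_dir, "interaction_records.tsv")
  utils::write.table(freq$records, rec_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths$records <- rec_path

  n_sig <- count_significant_elements(ncov, config$neg_thresh, config$pos_thresh)
  manifest <- c(
    "covcontact run manifest",
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("covcontact"))),
    sprintf("topology: %s", config$topology_path %||% "(in-memory)"),
    sprintf("coords: %s", config$coords_path %||% "(none)"),
    sprintf("selection1: %s", config$selection1),
    sprintf("selection2: %s", config$selection2),
    sprintf("representation: %s", config$representation),
    sprintf("superpose: %s", config$superpose),
    sprintf("prefilter_cutoff_A: %s", config$prefilter_cutoff_A %||% "(none)"),
    sprintf("pos_cutoff_A: %g", config$pos_cutoff_A),
    sprintf("neg_cutoff_A: %g", config$neg_cutoff_A),
    sprintf("significance_thresholds: %g / %g",
            config$neg_thresh, config$pos_thresh),
    sprintf("interaction_cutoffs: salt %g A, hbond %g A / %g deg, hydrophobic %g A, repulsion %g A",
            config$cutoffs$salt_bridge_A, config$cutoffs$hbond_dist_A,
            config$cutoffs$hbond_angle_deg, config$cutoffs$hydrophobic_A,
            config$cutoffs$repulsion_A),
    sprintf("all_types: %s", config$all_types),
    sprintf("stride: %d", config$stride),
    sprintf("n_frames: %d", traj$n_frames),
    sprintf("n_residues: %d x %d", length(ncov$row_labels),
            length(ncov$col_labels)),
    sprintf("n_significant_elements: %d", n_sig),
    sprintf("n_retained_pairs: %d", nrow(pairs)),
    "distance_reference: trajectory-averaged structure, representative-atom distances",
    "notes: attractive classifiers gated to positive-C pairs, repulsive to negative-C pairs unless all_types")
  writeLines(manifest, paths$manifest)

  invisible(list(trajectory = traj, covariance = ncov, close_contact = ccm,
                 pairs = pairs, frequencies = freq, paths = paths,
                 n_significant = n_sig))
}

#' Export viewer selections and a B-factor-annotated structure
#'
#' Writes a plain-text VMD-style selection/coloring script naming the
#' interacting residues grouped by interaction type, and a PDB of the
#' first frame whose B-factor column carries each residue's maximum
#' interaction frequency (percent), for coloring in any molecular viewer.
#'
#' @param ccm a `cc_close_contact`.
#' @param fmap a `cc_frequency_map`.
#' @param traj the trajectory supplying the structure.
#' @param out_prefix output path prefix; writes `<prefix>_selections.tcl`
#'   and `<prefix>_annotated.pdb`.
#' @return invisibly, the two paths.
#' @export
export_visualization <- function(ccm, fmap, traj, out_prefix) {
  script <- c("# covcontact viewer selections",
              "# one selection per interacting residue, grouped by type")
  any_pairs <- FALSE
  for (t in names(fmap$per_type)) {
    m <- fmap$per_type[[t]]
    nz <- which(m > 0, arr.ind = TRUE)
    if (!nrow(nz)) next
    any_pairs <- TRUE
    script <- c(script, sprintf("# %s", t))
    labels <- unique(c(rownames(m)[nz[, 1]], colnames(m)[nz[, 2]]))
    for (lab in labels) {
      f <- strsplit(lab, ":", fixed = TRUE)[[1]]
      script <- c(script, sprintf(
        "atomselect top \"chain %s and resid %s\"  ;# %s %s", f[1], f[2],
        f[3], t))
    }
  }
  if (!any_pairs) warning("frequency map is empty; writing header-only script")

  sel_path <- paste0(out_prefix, "_selections.tcl")
  writeLines(script, sel_path)

  # per-residue max frequency -> B-factor
  resfreq <- c(apply(fmap$combined, 1, max), apply(fmap$combined, 2, max))
  names(resfreq) <- c(rownames(fmap$combined), colnames(fmap$combined))
  labs <- atom_residue_label(traj$atoms)
  b <- unname(resfreq[labs])
  b[is.na(b)] <- 0
  pdb_path <- paste0(out_prefix, "_annotated.pdb")
  frame1 <- traj
  frame1$xyz <- traj$xyz[1L, , drop = FALSE]
  frame1$n_frames <- 1L
  write_trajectory_pdb(frame1, pdb_path, b = b)
  invisible(list(script = sel_path, pdb = pdb_path))
}

#' Heatmaps of the covariance, close-contact and frequency matrices
#'
#' Writes three PNG heatmaps with residue-labeled axes: normalized
#' covariance and close-contact matrices on a symmetric diverging
#' blue-white-red palette (blue negative, red positive), and the combined
#' frequency map on a white-to-violet scale.
#'
#' @param cov a normalized `cc_covariance`.
#' @param ccm a `cc_close_contact`.
#' @param fmap a `cc_frequency_map`.
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
plot_maps <- function(cov, ccm, fmap, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  diverging <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  seqpal <- grDevices::colorRampPalette(c("white", "#5E3C99"))(101)

  draw <- function(values, path, palette, zlim, title) {
    grDevices::png(path, width = 900, height = 760)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(7, 7, 3, 2))
    graphics::image(seq_len(nrow(values)), seq_len(ncol(values)), values,
                    col = palette, zlim = zlim, axes = FALSE,
                    xlab = "", ylab = "", main = title)
    graphics::axis(1, at = seq_len(nrow(values)), labels = rownames(values),
                   las = 2, cex.axis = 0.6)
    graphics::axis(2, at = seq_len(ncol(values)), labels = colnames(values),
                   las = 2, cex.axis = 0.6)
    graphics::box()
  }

  lim <- max(abs(cov$values), 1e-12)
  paths <- list(
    covariance = file.path(out_dir, "map_covariance.png"),
    close_contact = file.path(out_dir, "map_close_contact.png"),
    frequency = file.path(out_dir, "map_frequency.png"))
  draw(cov$values, paths$covariance, diverging, c(-lim, lim),
       "Normalized interprotein covariance")
  lim2 <- max(abs(ccm$values), 1e-12)
  draw(ccm$values, paths$close_contact, diverging, c(-lim2, lim2),
       "Close-contact covariance")
  draw(fmap$combined, paths$frequency, seqpal, c(0, 100),
       "Interaction frequency (%)")
  invisible(paths)
}

#' Export per-pair distance time series
#'
#' Minimum criterion-atom distance per frame for chosen pairs, as a plain
#' TSV (frame column plus one column per pair), e.g. to inspect whether a
#' pair holds a stable separation (attractive) or fluctuates (repulsive).
#'
#' @param traj a `cc_trajectory`.
#' @param pairs data.frame with `res_i`, `res_j` labels.
#' @param path output TSV path.
#' @param atoms_i,atoms_j optional atom-name subsets; default all atoms.
#' @return invisibly, the data.frame written.
#' @export
export_distance_traces <- function(traj, pairs, path,
                                   atoms_i = NULL, atoms_j = NULL) {
  out <- data.frame(frame = seq_len(traj$n_frames))
  for (k in seq_len(nrow(pairs))) {
    ctx <- pair_context(traj, pairs$res_i[k], pairs$res_j[k])
    ia <- if (is.null(atoms_i)) ctx$i else ctx$i[ctx$names_i %in% atoms_i]
    ib <- if (is.null(atoms_j)) ctx$j else ctx$j[ctx$names_j %in% atoms_j]
    d <- sqrt(min_dist2_over_pairs(traj$xyz, ia, ib))
    out[[paste(pairs$res_i[k], pairs$res_j[k], sep = "--")]] <- d
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
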