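#' Full electrode localization pipeline
#'
#' Runs threshold extraction, 3D Hough line detection, Gaussian-mixture
#' clustering, and per-electrode contact segmentation on a skull-stripped
#' volume, then computes the geometric QC metrics.
#'
#' @param volume A [seeg_volume], skull-stripped and co-registered.
#' @param config A [seeg_config]; all stage parameters come from here.
#' @return A list of class `seeg_localization`: `contact_sets` (list of
#'   `seeg_contact_set`, mm coordinates, deepest contact first), `qc`
#'   ([geometry_qc] result), `clusters`, `lines`, `cloud`, and the `config`
#'   used.
#' @examples
#' \donttest{
#' sv <- synth_volume(electrode_spec(n_electrodes = 3), seed = 7)
#' loc <- locate_electrodes(sv$volume)
#' length(loc$contact_sets)
#' }
#' @export
locate_electrodes <- function(volume, config = seeg_config()) {
  stopifnot(inherits(config, "seeg_config"))
  volume <- smooth_volume(volume, config$presmooth_sigma_mm)
  cloud <- extract_bright_voxels(volume, config$threshold_rule)
  lines <- hough_lines_3d(cloud,
                          direction_granularity = config$direction_granularity,
                          distance_bin = config$distance_bin,
                          min_votes = if (is.na(config$min_votes)) NA
                                      else config$min_votes,
                          inlier_radius = config$inlier_radius_mm /
                            min(voxel_size(volume)),
                          max_lines = if (is.na(config$n_electrodes)) NA
                                      else config$n_electrodes)
  if (length(lines) == 0L)
    stop_seeg("no_lines", "Hough transform found no line-shaped structure")
  seeg_log(length(lines), " electrode shaft(s) detected")
  clusters <- cluster_electrodes(cloud, lines, seed = config$gmm_seed)
  contact_sets <- lapply(clusters, function(cl)
    segment_contacts(volume, cl, cloud,
                     pitch_mm = config$pitch_mm,
                     max_contacts = config$max_contacts,
                     cube_mm = config$cube_mm,
                     com_max_iter = config$com_max_iter,
                     com_tol_voxel = config$com_tol_voxel))
  seeg_log(sum(vapply(contact_sets, function(cs) nrow(cs$contacts),
                      integer(1))), " contacts segmented")
  structure(list(contact_sets = contact_sets, qc = geometry_qc(contact_sets),
                 clusters = clusters, lines = lines, cloud = cloud,
                 config = config),
            class = "seeg_localization")
}

#' @export
print.seeg_localization <- function(x, ...) {
  cat("<seeg_localization> ", length(x$contact_sets), " electrodes, ",
      nrow(x$qc$contacts), " contacts\n", sep = "")
  print(x$qc)
  invisible(x)
}

#' Write localization results as TSV
#'
#' Writes the contact table (`electrode`, `contact_index`, `x_mm`, `y_mm`,
#' `z_mm`) and, optionally, the QC tables. Every file starts with a `#`
#' comment line echoing the configuration, so results are reproducible from
#' the output alone.
#'
#' @param localization A `seeg_localization` from [locate_electrodes].
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_localization <- function(localization, dir) {
  stopifnot(inherits(localization, "seeg_localization"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# config ", config_echo(localization$config))
  contacts <- do.call(rbind, lapply(localization$contact_sets, function(cs)
    data.frame(electrode = cs$electrode_label,
               contact_index = seq_len(nrow(cs$contacts)),
               x_mm = cs$contacts[, 1], y_mm = cs$contacts[, 2],
               z_mm = cs$contacts[, 3])))
  paths <- c(contacts = file.path(dir, "contacts.tsv"),
             qc_contacts = file.path(dir, "qc_axis_distance.tsv"),
             qc_pairs = file.path(dir, "qc_adjacent_distance.tsv"))
  write_tsv_with_header <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  write_tsv_with_header(contacts, paths["contacts"])
  write_tsv_with_header(localization$qc$contacts, paths["qc_contacts"])
  write_tsv_with_header(localization$qc$pairs, paths["qc_pairs"])
  invisible(paths)
}
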