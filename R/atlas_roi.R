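#' Integer-labelled atlas volume
#'
#' @param data integer array of region labels; 0 is background.
#' @param geometry a [volume_geometry()].
#' @param labels data.frame with columns `id`, `name`; every nonzero label in
#'   `data` must be present.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(data, geometry, labels) {
  data <- array(as.integer(round(data)), geometry$shape)
  labels <- as.data.frame(labels)
  if (!all(c("id", "name") %in% names(labels)))
    stop("label table needs columns id, name")
  present <- setdiff(unique(as.integer(data)), 0L)
  if (!all(present %in% labels$id))
    stop("labels present in the volume are missing from the table")
  structure(list(data = data, geometry = geometry, labels = labels),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", format(x$geometry), ",",
      length(setdiff(unique(as.integer(x$data)), 0L)), "labels\n")
  invisible(x)
}

#' Named groupings of atlas labels
#'
#' A region set maps reporting-region names to sets of label ids — e.g. the
#' 14 cortical, subcortical and white-matter reporting regions, the
#' cerebellar gray matter (CGM) reference, and the subcortical white matter
#' (SWM).  The whole-brain gray matter summary (WBGM) is the unweighted mean
#' of the gray-region means, so the set also records which regions count as
#' gray matter.
#'
#' @param groups named list; each element an integer vector of label ids.
#' @param gray_regions character vector naming the gray-matter groups
#'   averaged into WBGM.
#' @return Object of class `region_set`.
#' @export
region_set <- function(groups, gray_regions = setdiff(names(groups), "SWM")) {
  if (!length(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  if (any(!vapply(groups, length, 1L))) stop("groups must be non-empty")
  if (!all(gray_regions %in% names(groups)))
    stop("gray_regions must name existing groups")
  structure(list(groups = lapply(groups, as.integer),
                 gray_regions = gray_regions),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", length(x$groups), "groups (",
      length(x$gray_regions), "gray )\n")
  invisible(x)
}

#' Read / write a region set as TSV
#'
#' Columns `region`, `label_ids` (comma-separated), `gray` (0/1), so real
#' atlas id lists can be dropped in.
#'
#' @param path TSV file.
#' @return A [region_set()].
#' @export
load_region_set <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character")
  groups <- lapply(tab$label_ids, function(s)
    as.integer(strsplit(s, ",")[[1]]))
  names(groups) <- tab$region
  region_set(groups, gray_regions = tab$region[tab$gray == "1"])
}

#' @rdname load_region_set
#' @param regions a [region_set()].
#' @export
save_region_set <- function(regions, path) {
  tab <- data.frame(
    region = names(regions$groups),
    label_ids = vapply(regions$groups, paste, "", collapse = ","),
    gray = as.integer(names(regions$groups) %in% regions$gray_regions))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Propagate atlas labels through a transform chain
#'
#' Nearest-neighbor pull-back of an integer atlas onto a target grid; the
#' label table travels with the volume and no new labels can appear.
#'
#' @param atlas a [label_volume()].
#' @param chain a transform (or list chain) mapping the target grid into the
#'   atlas grid.
#' @param target_geometry output [volume_geometry()].
#' @return A [label_volume()] on the target grid.
#' @export
propagate_labels <- function(atlas, chain, target_geometry) {
  if (inherits(chain, c("deformation_field", "rigid_transform")))
    chain <- list(chain)
  comp <- compose_chain(chain, target_geometry)
  if (!identical(comp$geometry$shape, target_geometry$shape))
    stop("transform chain does not produce the target geometry")
  warped <- warp_image(atlas$data, comp, interp = "nearest")
  label_volume(warped, target_geometry, atlas$labels)
}

group_mask <- function(labels, ids) array(labels$data %in% ids, labels$geometry$shape)

#' Extract a region-averaged time-activity curve
#'
#' Per-frame unweighted mean over all voxels carrying one of the group's
#' labels; fit weights follow the frame durations.
#'
#' @param img a [dynamic_image()].
#' @param labels a [label_volume()] aligned with `img`.
#' @param group integer label ids (or a group name looked up in `regions`).
#' @param regions optional [region_set()] for name lookup.
#' @return A [tissue_curve()].
#' @export
region_tac <- function(img, labels, group, regions = NULL) {
  if (is.character(group)) {
    if (is.null(regions)) stop("need a region_set to resolve a group name")
    group <- regions$groups[[group]]
  }
  sel <- group_mask(labels, group)
  if (!any(sel)) stop("region group has no voxels")
  Fn <- n_frames(img)
  Y <- matrix(img$data, ncol = Fn)[which(sel), , drop = FALSE]
  tissue_curve(frame_mid_times(img$schedule), colMeans(Y),
               weight = img$schedule$duration_s / 60)
}

#' Per-region statistics of a parametric map
#'
#' Mean, SD (n-1 denominator) and voxel count per reporting region, plus the
#' whole-brain gray matter summary `WBGM` computed as the unweighted mean of
#' the gray-matter region means.  Empty regions are reported with `n = 0` and
#' `NA` statistics, never silently as zero.
#'
#' @param map a [parametric_map()].
#' @param labels a [label_volume()] aligned with the map.
#' @param regions a [region_set()].
#' @return data.frame of class `region_stats`: region, n, mean, sd, units.
#' @export
region_statistics <- function(map, labels, regions) {
  stopifnot_same_geometry(map$geometry, labels$geometry)
  rows <- lapply(names(regions$groups), function(nm) {
    sel <- group_mask(labels, regions$groups[[nm]]) & is.finite(map$data)
    v <- map$data[sel]
    data.frame(region = nm, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else if (length(v)) 0 else NA_real_)
  })
  out <- do.call(rbind, rows)
  gm <- out$mean[match(regions$gray_regions, out$region)]
  out <- rbind(out, data.frame(region = "WBGM", n = sum(out$n[match(regions$gray_regions, out$region)]),
                               mean = mean(gm), sd = stats::sd(gm)))
  out$units <- map$units
  class(out) <- c("region_stats", "data.frame")
  out
}

#' @export
print.region_stats <- function(x, ...) {
  cat("region_stats [", x$units[1], "]\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write region statistics as TSV
#'
#' @param stats a `region_stats` data.frame.
#' @param path output TSV.
#' @export
save_region_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
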