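#' Label table: map from structure roles to parcellation labels
#'
#' The simulator needs to resolve a handful of anatomical roles from an
#' integer parcellation: background, brainstem, cerebellum, per-hemisphere
#' cortical gray matter, per-hemisphere structure sets, and ventricles.
#'
#' @param background,brainstem,cerebellum,ventricles Integer label vectors.
#' @param gm_left,gm_right Cortical gray matter labels per hemisphere.
#' @param hemisphere_left,hemisphere_right All structure labels belonging to
#'   each hemisphere (midline structures such as brainstem may belong to
#'   neither).
#' @return A `label_table`.
#' @export
label_table <- function(background, brainstem, cerebellum,
                        gm_left, gm_right,
                        hemisphere_left, hemisphere_right, ventricles) {
  tab <- list(background = as.integer(background),
              brainstem = as.integer(brainstem),
              cerebellum = as.integer(cerebellum),
              gm_left = as.integer(gm_left),
              gm_right = as.integer(gm_right),
              hemisphere_left = as.integer(hemisphere_left),
              hemisphere_right = as.integer(hemisphere_right),
              ventricles = as.integer(ventricles))
  for (nm in names(tab))
    if (length(tab[[nm]]) == 0L || anyNA(tab[[nm]]))
      stop_resectr(sprintf("label table role '%s' is empty or invalid", nm),
                   "resectr_role_missing")
  if (length(intersect(tab$hemisphere_left, tab$hemisphere_right)) > 0L)
    stop_resectr("left and right hemisphere labels overlap",
                 "resectr_bad_label_table")
  if (length(intersect(tab$background,
                       unlist(tab[setdiff(names(tab), "background")]))) > 0L)
    stop_resectr("background label overlaps tissue labels",
                 "resectr_bad_label_table")
  structure(tab, class = "label_table")
}

#' Read / write a label table as plain-text key = value lines
#'
#' Each line has the form `role = l1, l2, ...` with integer labels.
#' @param path File path.
#' @return A `label_table` (for `read_label_table`).
#' @export
read_label_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  roles <- lapply(kv, function(x)
    as.integer(strsplit(trimws(x[2]), ",")[[1]]))
  names(roles) <- trimws(vapply(kv, `[`, "", 1))
  do.call(label_table, roles)
}

#' @rdname read_label_table
#' @param table A `label_table` (for `write_label_table`).
#' @export
write_label_table <- function(table, path) {
  lines <- vapply(names(unclass(table)), function(nm)
    sprintf("%s = %s", nm, paste(table[[nm]], collapse = ", ")), "")
  writeLines(lines, path)
  invisible(path)
}

roles_for <- function(P) {
  if (is.null(P$label_table))
    stop_resectr("parcellation has no label table", "resectr_role_missing")
  P$label_table
}

#' Pick a hemisphere at random
#'
#' Left or right with equal probability, using R's global random number
#' stream (so `set.seed()` makes the draw reproducible).
#' @return `"left"` or `"right"`.
#' @export
choose_hemisphere <- function() {
  c("left", "right")[1L + (stats::runif(1) >= 0.5)]
}

#' Complement of a hemisphere
#' @param h `"left"` or `"right"`.
#' @return The opposite hemisphere.
#' @export
other_hemisphere <- function(h) {
  h <- match.arg(h, c("left", "right"))
  if (h == "left") "right" else "left"
}

mask_from_labels <- function(P, labels) {
  binary_mask(array(as.integer(P$values %in% labels), dim = P$grid$shape),
              P$grid)
}

#' Cortical gray matter mask for one hemisphere
#' @param P A `label_volume` with a label table.
#' @param h `"left"` or `"right"`.
#' @return A `binary_mask`.
#' @export
gray_matter_mask <- function(P, h) {
  h <- match.arg(h, c("left", "right"))
  tab <- roles_for(P)
  role <- if (h == "left") "gm_left" else "gm_right"
  labels <- tab[[role]]
  if (!any(P$values %in% labels))
    stop_resectr(sprintf("no voxels carry the '%s' labels", role),
                 "resectr_role_missing")
  mask_from_labels(P, labels)
}

sphere_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  g <- g[g$i^2 + g$j^2 + g$k^2 <= radius^2, ]
  as.matrix(g)
}

morph <- function(mask, offsets, dilate) {
  v <- binary_morph_cpp(as.logical(mask$values), mask$grid$shape,
                        offsets, dilate)
  binary_mask(array(as.integer(v), dim = mask$grid$shape), mask$grid)
}

#' Binary closing then opening with a spherical element
#'
#' @param mask A `binary_mask`.
#' @param radius Structuring element radius in voxels.
#' @return The smoothed `binary_mask`.
#' @export
smooth_mask <- function(mask, radius = 3) {
  if (radius <= 0) return(mask)
  off <- sphere_offsets(radius)
  closed <- morph(morph(mask, off, TRUE), off, FALSE)
  morph(morph(closed, off, FALSE), off, TRUE)
}

#' Resectable hemisphere mask
#'
#' A voxel is resectable iff its label is not background, brainstem,
#' cerebellum or contralateral hemisphere. The raw mask is then smoothed by
#' binary morphological closing followed by opening with a spherical
#' structuring element, filling sulcal gaps and removing spurs.
#'
#' @param P A `label_volume` with a label table.
#' @param h Hemisphere being resected.
#' @param smooth_radius Structuring element radius in voxels; 0 disables
#'   smoothing.
#' @return A `binary_mask`.
#' @export
resectable_mask <- function(P, h, smooth_radius = 3) {
  h <- match.arg(h, c("left", "right"))
  tab <- roles_for(P)
  contra <- if (h == "left") tab$hemisphere_right else tab$hemisphere_left
  excluded <- unique(c(tab$background, tab$brainstem, tab$cerebellum, contra))
  raw <- binary_mask(array(as.integer(!(P$values %in% excluded)),
                           dim = P$grid$shape), P$grid)
  smooth_mask(raw, smooth_radius)
}

#' Ventricle mask
#' @param P A `label_volume` with a label table.
#' @return A `binary_mask` of the ventricle labels.
#' @export
ventricle_mask <- function(P) {
  tab <- roles_for(P)
  if (!any(P$values %in% tab$ventricles))
    stop_resectr("no voxels carry the ventricle labels", "resectr_role_missing")
  mask_from_labels(P, tab$ventricles)
}

#' Sample a seed voxel uniformly from a mask
#'
#' @param mask A non-empty `binary_mask`.
#' @return 0-based voxel index (length-3 integer vector) with attribute
#'   `"mm"` giving the physical position of the voxel centre.
#' @export
sample_seed_voxel <- function(mask) {
  pos <- which(mask$values == 1L)
  if (length(pos) == 0L)
    stop_resectr("no candidate seed: mask is empty", "resectr_empty_mask")
  pick <- pos[sample.int(length(pos), 1L)]
  idx <- arrayInd(pick, mask$grid$shape) - 1L
  structure(as.integer(idx), mm = as.numeric(voxel_to_mm(mask$grid, idx)))
}
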